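#' Contingency table of two residue masks
#'
#' Classifies every residue of the protein into four classes: beta in both
#' the prediction and the experiment (`bte`), beta in the prediction only
#' (`bt0`), beta in the experiment only (`b0e`), beta in neither (`b00`).
#' The four counts sum to the protein length `l`.
#'
#' @param pred,exp logical masks of equal length (prediction and
#'   experiment; NA counts as non-beta).
#' @return An object of class `contingency_table`: list with `bte`, `bt0`,
#'   `b0e`, `b00`, `l`.
#' @examples
#' p <- segments_to_mask(segment_set(c(15, 31), c(21, 42)), 42)
#' e <- segments_to_mask(segment_set(c(12, 31), c(21, 42)), 42)
#' build_contingency(p, e)
#' @export
build_contingency <- function(pred, exp) {
  if (length(pred) != length(exp))
    stop("masks differ in length (", length(pred), " vs ", length(exp), ")")
  pred <- !is.na(pred) & pred
  exp <- !is.na(exp) & exp
  contingency_table(sum(pred & exp), sum(pred & !exp),
                    sum(!pred & exp), sum(!pred & !exp))
}

#' @rdname build_contingency
#' @param bte,bt0,b0e,b00 non-negative integer counts.
#' @export
contingency_table <- function(bte, bt0, b0e, b00) {
  counts <- as.integer(c(bte, bt0, b0e, b00))
  if (any(is.na(counts)) || any(counts < 0L))
    stop("counts must be non-negative integers")
  structure(list(bte = counts[1L], bt0 = counts[2L], b0e = counts[3L],
                 b00 = counts[4L], l = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$bte, x$b0e, x$bt0, x$b00), 2L,
              dimnames = list(c("pred beta", "pred non-beta"),
                              c("exp beta", "exp non-beta")))
  print(m)
  invisible(x)
}

#' Cohen's kappa of a contingency table
#'
#' Chance-corrected agreement between the two binary classifications:
#' \deqn{\kappa = \frac{2(b_{te} b_{00} - b_{t0} b_{0e})}
#'   {(b_{te}+b_{t0})(b_{t0}+b_{00}) + (b_{te}+b_{0e})(b_{0e}+b_{00})}}
#' The statistic is symmetric in the two raters (transposing the table
#' leaves it unchanged) and, for fixed margins, strictly increasing in the
#' concordant count. Degenerate tables where both masks are all-true or
#' both all-false have a vanishing denominator; kappa is then undefined
#' and reported as `NA`.
#'
#' @param t a [contingency_table()].
#' @return kappa in `[-1, 1]`, or `NA` for degenerate tables.
#' @examples
#' cohen_kappa(contingency_table(19, 0, 3, 20))  # 0.858
#' @export
cohen_kappa <- function(t) {
  den <- (t$bte + t$bt0) * (t$bt0 + t$b00) +
         (t$bte + t$b0e) * (t$b0e + t$b00)
  if (den == 0) return(NA_real_)
  2 * (t$bte * t$b00 - t$bt0 * t$b0e) / den
}

# hypergeometric point log-probability of a table with the margins of t
# and concordant count b, via log-factorials
.lpoint <- function(b, rowt, cole, l) {
  lfactorial(cole) + lfactorial(l - cole) +
    lfactorial(rowt) + lfactorial(l - rowt) - lfactorial(l) -
    (lfactorial(b) + lfactorial(cole - b) + lfactorial(rowt - b) +
       lfactorial(l - rowt - cole + b))
}

#' One-tail Fisher's exact test of a contingency table
#'
#' Under the null that the predictor assigns residues to beta at random,
#' the probability of the observed table is the hypergeometric point
#' probability at fixed margins. The one-tail P sums this point
#' probability with those of every same-margin table showing *higher*
#' agreement, i.e. a larger concordant count `bte` (with the margins
#' fixed, a larger `bte` forces a larger `b00`, so the two readings of
#' "higher agreement" coincide). Computed in log-factorial space; always
#' in `(0, 1]`, and equal to 1 when `bte` is already the smallest value
#' the margins allow.
#'
#' @param t a [contingency_table()].
#' @return the one-tail P value.
#' @examples
#' fisher_one_tail(contingency_table(2, 0, 0, 2))  # 1/6
#' @export
fisher_one_tail <- function(t) {
  rowt <- t$bte + t$bt0    # residues beta in the prediction
  cole <- t$bte + t$b0e    # residues beta in the experiment
  support <- max(0L, rowt + cole - t$l):min(rowt, cole)
  tail <- support[support >= t$bte]
  min(1, sum(exp(.lpoint(tail, rowt, cole, t$l))))
}

#' Classify agreement strength and significance
#'
#' Maps a kappa value and a one-tail P to the conventional labels:
#' significance `***` (P < 0.001), `**` (P < 0.01), `*` (P < 0.05) or
#' `ns`; kappa class `none` (kappa <= 0), `scarce` (0, 0.2\], `fair`
#' (0.2, 0.4\], `good` (0.4, 0.6\], `very good` (0.6, 0.8\] or
#' `extremely good` (0.8, 1\].
#'
#' @param kappa numeric kappa (NA allowed).
#' @param p one-tail P value.
#' @return list with `significance` and `kappa_class` character scalars.
#' @export
classify_agreement <- function(kappa, p) {
  significance <- if (is.na(p)) NA_character_
    else if (p < 0.001) "***"
    else if (p < 0.01) "**"
    else if (p < 0.05) "*"
    else "ns"
  kappa_class <- if (is.na(kappa)) NA_character_
    else if (kappa <= 0) "none"
    else if (kappa <= 0.2) "scarce"
    else if (kappa <= 0.4) "fair"
    else if (kappa <= 0.6) "good"
    else if (kappa <= 0.8) "very good"
    else "extremely good"
  list(significance = significance, kappa_class = kappa_class)
}

#' Full agreement result for two masks
#'
#' Convenience wrapper: contingency table, kappa, one-tail Fisher P and
#' the class labels in one object.
#'
#' @inheritParams build_contingency
#' @return An object of class `agreement_result`.
#' @export
agreement <- function(pred, exp) {
  t <- build_contingency(pred, exp)
  kappa <- cohen_kappa(t)
  p <- fisher_one_tail(t)
  cls <- classify_agreement(kappa, p)
  structure(c(list(table = t, kappa = kappa, p = p), cls),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement> kappa = %.3f (%s), one-tail P = %.3g (%s)\n",
    x$kappa, x$kappa_class, x$p, x$significance))
  cat(sprintf("  counts: bte=%d bt0=%d b0e=%d b00=%d (l=%d)\n",
              x$table$bte, x$table$bt0, x$table$b0e, x$table$b00,
              x$table$l))
  invisible(x)
}

#' Per-structure agreement against a prediction
#'
#' Compares every element (molecule conformation) of a database with one
#' predicted hot-spot segment set: each element's annotation becomes a
#' full-length mask (residues outside the construct's coverage score
#' non-beta over the full protein length) after bridging and strand-length
#' filtering, and kappa / one-tail Fisher P are computed against the
#' prediction mask. The summary quartiles support box-plot style views of
#' the kappa distribution across polymorphs.
#'
#' @param db a [fibril_database()].
#' @param pred_segments a [segment_set()] of predicted hot spots.
#' @param lbeta_min strand-length regime for the element masks.
#' @param bridge apply the protein's bridging rule first.
#' @return data frame with one row per element (`entry_id`,
#'   `molecule_index`, the four counts, `kappa`, `p`, `significance`,
#'   `class`) and a `summary` attribute with median and quartiles of
#'   kappa.
#' @export
per_structure_agreement <- function(db, pred_segments, lbeta_min = 4L,
                                    bridge = TRUE) {
  l <- db$protein$length
  pred <- segments_to_mask(pred_segments, l)
  db <- db_annotate(db, bridge = bridge, lbeta_min = lbeta_min)
  rows <- do.call(rbind, lapply(db$entries, function(e)
    do.call(rbind, lapply(e$molecules, function(m) {
      a <- agreement(pred, annotation_mask(m, l))
      data.frame(entry_id = e$entry_id,
                 molecule_index = m$molecule_index,
                 bte = a$table$bte, bt0 = a$table$bt0,
                 b0e = a$table$b0e, b00 = a$table$b00,
                 kappa = a$kappa, p = a$p,
                 significance = a$significance,
                 class = a$kappa_class,
                 stringsAsFactors = FALSE)
    }))))
  rownames(rows) <- NULL
  q <- stats::quantile(rows$kappa, c(0.25, 0.5, 0.75), na.rm = TRUE,
                       names = FALSE)
  attr(rows, "summary") <- c(q1 = q[1L], median = q[2L], q3 = q[3L])
  rows
}
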