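#' Per-entry beta fraction at one residue
#'
#' For a single structure, the fraction of its molecules that place residue
#' `n` in a beta strand, among the molecules whose construct contains `n`.
#' An entry with two molecules where only one has the residue in beta
#' contributes 0.5; an entry not covering the residue contributes nothing
#' (`NA`).
#'
#' @param entry a [fibril_entry()].
#' @param n residue number (full-length numbering); may be a vector.
#' @return numeric in `[0, 1]`, or `NA` where no molecule covers `n`.
#' @export
entry_fraction <- function(entry, n) {
  vapply(n, function(ni) {
    flags <- unlist(lapply(entry$molecules, beta_at, n = ni))
    flags <- flags[!is.na(flags)]
    if (!length(flags)) NA_real_ else mean(flags)
  }, numeric(1))
}

#' Structure-based beta-sheet preference profile
#'
#' For every residue `n`, the percent of database entries placing `n` in a
#' beta strand: multi-molecule entries contribute their molecule fraction
#' (see [entry_fraction()]), and the denominator counts only entries whose
#' construct contains `n` -- so a residue present in 21 of 30 constructs is
#' normalised to 21. Residues contained in no entry are reported `NA`.
#'
#' The strand-length regime is applied here: with `lbeta_min = 4` every
#' annotation is passed through [filter_strand_length()] before counting
#' (`lbeta_min = 1` counts annotations as-is). The returned profile has an
#' empty `smoothed` column; fill it with [window_average()].
#'
#' @param db a [fibril_database()].
#' @param lbeta_min minimum strand length applied before counting.
#' @return A `beta_profile`: data frame with columns `residue`, `aa`,
#'   `raw`, `smoothed`, `denominator`, plus attributes `lbeta_min`,
#'   `window` and `protein`.
#' @export
compute_profile <- function(db, lbeta_min = 1L) {
  stopifnot(inherits(db, "fibril_database"), length(db$entries) >= 1L)
  db <- db_annotate(db, lbeta_min = lbeta_min)
  l <- db$protein$length
  fr <- vapply(db$entries, entry_fraction, numeric(l), n = seq_len(l))
  fr <- matrix(fr, nrow = l)    # l x n_entries
  denom <- rowSums(!is.na(fr))
  raw <- ifelse(denom > 0L, 100 * rowMeans(fr, na.rm = TRUE), NA_real_)
  aa <- if (is.null(db$protein$sequence)) NA_character_
        else strsplit(db$protein$sequence, "")[[1L]]
  structure(data.frame(residue = seq_len(l), aa = aa, raw = raw,
                       smoothed = NA_real_, denominator = as.integer(denom)),
            lbeta_min = as.integer(lbeta_min), window = NA_integer_,
            protein = db$protein$name,
            class = c("beta_profile", "data.frame"))
}

#' Sliding-window average of a profile
#'
#' Replaces the `smoothed` column with the mean of `raw` over a centred
#' window of `w` residues (default 7, the conventional width for
#' aggregation-propensity profiles). Windows truncate at the termini
#' rather than padding, and positions with undefined raw values are
#' excluded from the mean; a window with no defined positions yields `NA`.
#'
#' @param profile a `beta_profile` from [compute_profile()].
#' @param w odd positive window width; `w = 1` copies `raw`.
#' @return the profile with `smoothed` filled and the `window` attribute
#'   set.
#' @export
window_average <- function(profile, w = 7L) {
  w <- as.integer(w)
  stopifnot(w >= 1L, w %% 2L == 1L)
  raw <- profile$raw
  l <- length(raw)
  h <- (w - 1L) %/% 2L
  sm <- vapply(seq_len(l), function(n) {
    win <- raw[max(1L, n - h):min(l, n + h)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else mean(win)
  }, numeric(1))
  profile$smoothed <- sm
  attr(profile, "window") <- w
  profile
}

#' Extract high-preference segments from a profile
#'
#' Maximal runs of residues whose profile value passes the threshold become
#' intervals. By default the smoothed profile is thresholded (peaks are
#' conventionally read off the window-averaged plot) with the inclusive
#' comparison `>=`; both are configurable. Undefined values never pass.
#'
#' @param profile a `beta_profile`.
#' @param threshold percent in `[0, 100]`.
#' @param use_smoothed use the `smoothed` column (must be filled) rather
#'   than `raw`.
#' @param op comparison function, default `>=`.
#' @return a [segment_set()] labelled `experimental_lb<lbeta_min>`.
#' @export
extract_segments <- function(profile, threshold, use_smoothed = TRUE,
                             op = `>=`) {
  stopifnot(threshold >= 0, threshold <= 100)
  vals <- if (use_smoothed) profile$smoothed else profile$raw
  if (use_smoothed && all(is.na(vals)))
    stop("smoothed profile is empty; run window_average() first")
  pass <- !is.na(vals) & op(vals, threshold)
  mask_to_segments(pass,
                   source = paste0("experimental_lb",
                                   attr(profile, "lbeta_min")),
                   threshold = threshold)
}

#' @export
print.beta_profile <- function(x, ...) {
  cat("<beta_profile> ", attr(x, "protein"), ", L_beta >= ",
      attr(x, "lbeta_min"), ", ", nrow(x), " residues",
      if (!is.na(attr(x, "window")))
        paste0(", smoothed (w = ", attr(x, "window"), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Write a profile as TSV
#'
#' Columns: `residue`, `aa`, `raw_percent`, `smoothed_percent`,
#' `denominator`.
#'
#' @param profile a `beta_profile`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, file) {
  out <- data.frame(residue = profile$residue, aa = profile$aa,
                    raw_percent = round(profile$raw, 4),
                    smoothed_percent = round(profile$smoothed, 4),
                    denominator = profile$denominator)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Plot a preference profile
#'
#' Base-graphics rendering of the raw and smoothed profile with an
#' optional threshold line and shaded predicted segments, mirroring the
#' usual experimental-vs-predicted comparison layout.
#'
#' @param x a `beta_profile`.
#' @param threshold optional horizontal cut-off line (percent).
#' @param segments optional [segment_set()] shaded in the background.
#' @param ... passed to [graphics::plot()].
#' @export
plot.beta_profile <- function(x, threshold = NULL, segments = NULL, ...) {
  graphics::plot(x$residue, x$raw, type = "n", ylim = c(0, 100),
                 xlab = "residue", ylab = "F_beta(n) [%]", ...)
  if (!is.null(segments))
    for (i in seq_len(nrow(segments)))
      graphics::rect(segments$start[i] - 0.5, 0, segments$end[i] + 0.5,
                     100, col = "grey90", border = NA)
  graphics::lines(x$residue, x$raw, col = "grey50")
  if (!all(is.na(x$smoothed)))
    graphics::lines(x$residue, x$smoothed, col = "darkorange", lwd = 2)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
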