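#' Per-molecule beta annotation
#'
#' A `beta_annotation` records, for one molecule of one structure, a binary
#' beta / non-beta call per residue over the coverage range of the
#' construct. Residues outside coverage are simply absent (they do not
#' enter profile denominators); residues inside coverage that are
#' unresolved or non-beta are `FALSE`.
#'
#' @param entry_id structure accession.
#' @param molecule_index integer >= 1; distinct conformers within one
#'   entry get distinct indices.
#' @param coverage integer vector `c(first, last)` residue range present in
#'   the construct (full-length numbering).
#' @param beta logical vector of length `coverage[2] - coverage[1] + 1`.
#' @return An object of class `beta_annotation`.
#' @export
beta_annotation <- function(entry_id, molecule_index = 1L,
                            coverage, beta) {
  coverage <- as.integer(coverage)
  stopifnot(length(coverage) == 2L, coverage[1L] <= coverage[2L],
            coverage[1L] >= 1L)
  beta <- as.logical(beta)
  if (length(beta) != coverage[2L] - coverage[1L] + 1L)
    stop("beta flags must cover exactly the coverage range")
  beta[is.na(beta)] <- FALSE
  structure(list(entry_id = as.character(entry_id),
                 molecule_index = as.integer(molecule_index),
                 coverage = coverage, beta = beta),
            class = "beta_annotation")
}

#' @export
print.beta_annotation <- function(x, ...) {
  runs <- annotation_segments(x)
  cat("<beta_annotation> ", x$entry_id, " molecule ", x$molecule_index,
      ", coverage ", x$coverage[1L], "-", x$coverage[2L], "\n  strands: ",
      sep = "")
  if (!nrow(runs)) cat("(none)\n")
  else cat(paste0(runs$start, "-", runs$end, collapse = ", "), "\n")
  invisible(x)
}

# beta flag at residue n (full-length numbering); NA outside coverage
beta_at <- function(ann, n) {
  out <- rep(NA, length(n))
  inside <- n >= ann$coverage[1L] & n <= ann$coverage[2L]
  out[inside] <- ann$beta[n[inside] - ann$coverage[1L] + 1L]
  out
}

#' Beta strands of an annotation as a segment set
#' @param ann a [beta_annotation()].
#' @return a [segment_set()] of maximal beta runs in residue numbering.
#' @export
annotation_segments <- function(ann) {
  s <- mask_to_segments(ann$beta, source = ann$entry_id)
  segment_set(s$start + ann$coverage[1L] - 1L,
              s$end + ann$coverage[1L] - 1L,
              source = attr(s, "source"))
}

#' Full-length binary mask of an annotation
#' @param ann a [beta_annotation()].
#' @param l protein length; residues outside coverage score non-beta.
#' @return logical vector of length `l`.
#' @export
annotation_mask <- function(ann, l) {
  m <- logical(l)
  m[ann$coverage[1L]:ann$coverage[2L]] <- ann$beta
  m
}

in_beta_region <- function(phi, psi, region) {
  ok <- rep(FALSE, length(phi))
  for (r in seq_len(nrow(region)))
    ok <- ok | (phi >= region$phi_min[r] & phi <= region$phi_max[r] &
                psi >= region$psi_min[r] & psi <= region$psi_max[r])
  ok & !is.na(phi) & !is.na(psi)
}

#' Assign beta conformation from backbone dihedrals
#'
#' A residue is called beta when both its phi and psi are defined and the
#' pair falls inside the configured Ramachandran beta region (any of the
#' region's rectangles). Undefined dihedrals -- termini, chain breaks,
#' incomplete backbones -- are non-beta.
#'
#' @param dihedrals data frame from [compute_dihedrals()].
#' @param region rectangle set as returned by [default_beta_region()].
#' @param entry_id,molecule_index recorded on the annotation.
#' @return a [beta_annotation()] covering the residue range of `dihedrals`.
#' @export
assign_beta <- function(dihedrals, region = default_beta_region(),
                        entry_id = "structure", molecule_index = 1L) {
  stopifnot(nrow(dihedrals) >= 1L)
  idx <- dihedrals$index
  coverage <- c(min(idx), max(idx))
  beta <- rep(FALSE, coverage[2L] - coverage[1L] + 1L)
  hit <- dihedrals$defined &
    in_beta_region(dihedrals$phi, dihedrals$psi, region)
  beta[idx[hit] - coverage[1L] + 1L] <- TRUE
  beta_annotation(entry_id, molecule_index, coverage, beta)
}

#' Promote conformationally flexible residues adjacent to a strand
#'
#' Glycine-rich positions (e.g. Gly37-Gly38 of the amyloid-beta peptide,
#' Gly67-Gly68 and Gly84-Ala85-Gly86 of alpha-synuclein) have high backbone
#' freedom and often sit just outside the Ramachandran beta region while
#' being structurally aligned with the strand that starts immediately
#' after them. The rule promotes a configured flexible residue to beta
#' exactly when the immediately following residue is beta; promotion
#' cascades right-to-left across consecutive flexible positions, so an
#' upstream glycine can be promoted through an already-promoted neighbour.
#' Beta flags are never removed and no position outside the configured
#' list is ever changed.
#'
#' @param annotation a [beta_annotation()].
#' @param flexible_positions integer residue numbers eligible for
#'   promotion; positions outside coverage are ignored with a warning.
#' @return the updated annotation.
#' @export
apply_bridging_rule <- function(annotation, flexible_positions) {
  flexible_positions <- as.integer(flexible_positions)
  if (!length(flexible_positions)) return(annotation)
  cov <- annotation$coverage
  outside <- flexible_positions < cov[1L] | flexible_positions > cov[2L]
  if (any(outside)) {
    warning("flexible position(s) outside coverage ignored: ",
            paste(flexible_positions[outside], collapse = ", "))
    flexible_positions <- flexible_positions[!outside]
  }
  beta <- annotation$beta
  # right-to-left so promotions can cascade through consecutive positions
  for (p in sort(flexible_positions, decreasing = TRUE)) {
    i <- p - cov[1L] + 1L
    if (i < length(beta) && beta[i + 1L]) beta[i] <- TRUE
  }
  annotation$beta <- beta
  annotation
}

#' Drop beta strands shorter than a minimum length
#'
#' Maximal runs of beta flags shorter than `lbeta_min` residues are reset
#' to non-beta. The analysis is conventionally run twice, with
#' `lbeta_min = 1` (identity) and `lbeta_min = 4`, mirroring the two
#' strand-length regimes of the profile.
#'
#' @param annotation a [beta_annotation()].
#' @param lbeta_min positive integer minimum strand length.
#' @return the filtered annotation.
#' @export
filter_strand_length <- function(annotation, lbeta_min) {
  lbeta_min <- as.integer(lbeta_min)
  stopifnot(lbeta_min >= 1L)
  if (lbeta_min == 1L) return(annotation)
  r <- rle(annotation$beta)
  r$values[r$values & r$lengths < lbeta_min] <- FALSE
  annotation$beta <- inverse.rle(r)
  annotation
}

#' Load curated strand-interval annotations
#'
#' The canonical ingestion route for reproducing published analyses: a
#' tab-separated table with columns `entry_id`, `molecule_index`,
#' `coverage_start`, `coverage_end`, `strand_start`, `strand_end` (1-based
#' inclusive), one row per strand. A molecule with no strands is a single
#' row with empty/NA strand columns. Overlapping strand intervals are
#' merged with a warning; intervals outside the stated coverage or the
#' protein length are an error.
#'
#' @param file path to the TSV file.
#' @param protein a [protein_def()]; coverages must lie within its length.
#' @return list of [beta_annotation()], one per (entry, molecule) in file
#'   order.
#' @seealso [annotations_to_database()] to assemble the result into a
#'   [fibril_database()].
#' @export
load_strand_annotation <- function(file, protein) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("entry_id", "molecule_index", "coverage_start", "coverage_end",
            "strand_start", "strand_end")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$entry_id, df$molecule_index, sep = "\r")
  lapply(split(df, factor(key, unique(key))), function(d) {
    eid <- d$entry_id[1L]; mi <- d$molecule_index[1L]
    cov <- c(d$coverage_start[1L], d$coverage_end[1L])
    if (any(d$coverage_start != cov[1L]) || any(d$coverage_end != cov[2L]))
      stop("inconsistent coverage for ", eid, " molecule ", mi)
    if (cov[1L] < 1L || cov[2L] > protein$length)
      stop("coverage ", cov[1L], "-", cov[2L], " outside protein [1, ",
           protein$length, "]")
    d <- d[!is.na(d$strand_start) & !is.na(d$strand_end), , drop = FALSE]
    if (nrow(d) &&
        (min(d$strand_start) < cov[1L] || max(d$strand_end) > cov[2L]))
      stop("strand interval outside coverage for ", eid)
    seg <- segment_set(d$strand_start, d$strand_end)
    if (nrow(seg) < nrow(d))
      warning("overlapping strand intervals merged for ", eid,
              " molecule ", mi)
    beta <- rep(FALSE, cov[2L] - cov[1L] + 1L)
    for (i in seq_len(nrow(seg)))
      beta[(seg$start[i]:seg$end[i]) - cov[1L] + 1L] <- TRUE
    beta_annotation(eid, mi, cov, beta)
  }) |> unname()
}
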