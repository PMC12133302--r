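#' Define a protein for profiling
#'
#' A protein definition carries the minimal bookkeeping needed to interpret
#' residue-level data: the protein length (full-length numbering), an
#' optional one-letter sequence, positions with high backbone conformational
#' freedom that are eligible for the glycine bridging rule, and the default
#' segment-extraction thresholds (percent) for the two strand-length regimes.
#'
#' @param name character scalar, protein identifier.
#' @param length integer, number of residues in full-length numbering.
#' @param sequence optional one-letter amino-acid string of length `length`.
#' @param offset integer added when mapping construct numbering to
#'   full-length numbering (0 when the deposited numbering is already
#'   full-length).
#' @param flexible_positions integer vector of residue numbers eligible for
#'   promotion by [apply_bridging_rule()].
#' @param thresholds named numeric vector with elements `lb1` and `lb4`:
#'   default F-beta percent thresholds for strand-length minima 1 and 4.
#' @return An object of class `protein_def`.
#' @examples
#' protein_def("abeta42", 42, flexible_positions = c(37L, 38L))
#' @seealso [builtin_protein()] for the shipped definitions.
#' @export
protein_def <- function(name, length, sequence = NULL, offset = 0L,
                        flexible_positions = integer(0),
                        thresholds = c(lb1 = NA_real_, lb4 = NA_real_)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(length), length >= 1)
  length <- as.integer(length)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match protein length (", length, ")")
  }
  flexible_positions <- sort(unique(as.integer(flexible_positions)))
  if (any(flexible_positions < 1L | flexible_positions > length))
    stop("flexible_positions outside [1, length]")
  structure(list(name = name, length = length, sequence = sequence,
                 offset = as.integer(offset),
                 flexible_positions = flexible_positions,
                 thresholds = thresholds),
            class = "protein_def")
}

#' @export
print.protein_def <- function(x, ...) {
  cat("<protein_def> ", x$name, ": ", x$length, " residues", sep = "")
  if (!is.null(x$sequence)) cat(", sequence attached")
  if (length(x$flexible_positions))
    cat("\n  flexible positions: ",
        paste(x$flexible_positions, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

# Human A-beta 1-42 (numbering 1-42); alpha-synuclein P37840 (1-140);
# 2N4R tau (1-441, sequence not bundled).
.AB42_SEQ <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
.ASYN_SEQ <- paste0(
  "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
  "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
  "DNEAYEMPSEEGYQDYEPEA")

#' Built-in protein definitions
#'
#' Ready-made [protein_def()] objects for the three systems the package is
#' calibrated on: the amyloid-beta peptide (40- and 42-residue forms),
#' alpha-synuclein, and the 2N4R isoform of tau. Flexible positions follow
#' the published bridging conventions (A-beta Gly37-Gly38; alpha-synuclein
#' Gly67-Gly68 and Gly84-Ala85-Gly86); default thresholds are the percent
#' cut-offs used to read peaks off the respective profiles.
#'
#' @param name one of `"abeta40"`, `"abeta42"`, `"asyn"`, `"tau_2n4r"`.
#' @return A `protein_def`.
#' @examples
#' builtin_protein("abeta42")
#' @export
builtin_protein <- function(name = c("abeta42", "abeta40", "asyn",
                                     "tau_2n4r")) {
  name <- match.arg(name)
  switch(name,
    abeta42 = protein_def("abeta42", 42L, sequence = .AB42_SEQ,
                          flexible_positions = c(37L, 38L),
                          thresholds = c(lb1 = 55, lb4 = 40)),
    abeta40 = protein_def("abeta40", 40L,
                          sequence = substr(.AB42_SEQ, 1L, 40L),
                          flexible_positions = c(37L, 38L),
                          thresholds = c(lb1 = 55, lb4 = 40)),
    asyn = protein_def("asyn", 140L, sequence = .ASYN_SEQ,
                       flexible_positions = c(67L, 68L, 84L, 85L, 86L),
                       thresholds = c(lb1 = 70, lb4 = 60)),
    tau_2n4r = protein_def("tau_2n4r", 441L,
                           thresholds = c(lb1 = 70, lb4 = 60)))
}

#' Default Ramachandran beta region
#'
#' The beta/extended basin used by [assign_beta()] when no custom region is
#' supplied: phi in \[-180, -45\] degrees combined with psi in \[45, 180\] or
#' psi in \[-180, -150\] (the latter wraps the upper-left basin across the
#' psi = 180 boundary). Each row of the returned data frame is one rectangle
#' in (phi, psi) space; a residue is beta when it falls inside any rectangle.
#'
#' @return data frame with columns `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max` (degrees).
#' @export
default_beta_region <- function() {
  data.frame(phi_min = c(-180, -180), phi_max = c(-45, -45),
             psi_min = c(45, -180), psi_max = c(180, -150))
}
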