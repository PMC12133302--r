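#' Published decision rules of the supported predictors
#'
#' The package consumes aggregation-propensity predictions, it does not
#' compute them. Each supported predictor has a published rule turning its
#' per-residue score track into hot-spot segments:
#'
#' * `zyggregator`: Z-score profile, hot spot where `Zagg >= 1`;
#' * `aggrescan`: window-averaged a4v scale, hot spot = run of at least 5
#'   residues with `a4v >= 0` containing no proline;
#' * `tango`: beta-aggregation score, hot spot where `score > 0`;
#' * `waltz`: amyloid score with the high-sensitivity cut-off,
#'   `score >= 75`;
#' * `pasta`: best pairing energy, hot spot where `-dG_agg > 5` energy
#'   units (1 unit = 1.192 kcal/mol).
#'
#' @param name predictor name; with no argument the full rule list.
#' @return a rule list with elements `threshold`, `op` (comparison
#'   function), `min_run`, `exclude_proline` -- or the named list of all
#'   rules.
#' @export
predictor_rule <- function(name = NULL) {
  rules <- list(
    zyggregator = list(threshold = 1,  op = `>=`, min_run = 1L,
                       exclude_proline = FALSE),
    aggrescan   = list(threshold = 0,  op = `>=`, min_run = 5L,
                       exclude_proline = TRUE),
    tango       = list(threshold = 0,  op = `>`,  min_run = 1L,
                       exclude_proline = FALSE),
    waltz       = list(threshold = 75, op = `>=`, min_run = 1L,
                       exclude_proline = FALSE),
    pasta       = list(threshold = 5,  op = `>`,  min_run = 1L,
                       exclude_proline = FALSE))
  if (is.null(name)) return(rules)
  if (!name %in% names(rules)) stop("unknown predictor: ", name)
  rules[[name]]
}

#' Load a predictor score track
#'
#' A track is a TSV with columns `residue` and `score`. Residues absent
#' from the file are recorded as missing and never pass any threshold;
#' duplicate residues or residues outside `[1, l]` are an error.
#'
#' @param file path to the TSV.
#' @param protein a [protein_def()].
#' @param predictor name recorded on the track (one of
#'   `names(predictor_rule())` to pick up its default rule, or any label).
#' @return An object of class `predictor_track`: list with `predictor`,
#'   `protein`, and `score` (numeric of length `l`, NA where missing).
#' @export
load_track <- function(file, protein, predictor = "track") {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("residue", "score") %in% names(df)))
    stop("track file must have columns residue, score")
  res <- as.integer(df$residue)
  if (anyDuplicated(res)) stop("duplicated residue row(s) in ", file)
  if (any(res < 1L | res > protein$length))
    stop("residue outside [1, ", protein$length, "] in ", file)
  score <- rep(NA_real_, protein$length)
  score[res] <- as.numeric(df$score)
  structure(list(predictor = predictor, protein = protein$name,
                 score = score),
            class = "predictor_track")
}

#' @export
print.predictor_track <- function(x, ...) {
  cat("<predictor_track> ", x$predictor, " over ", x$protein, " (",
      length(x$score), " residues, ", sum(is.na(x$score)), " missing)\n",
      sep = "")
  invisible(x)
}

#' Threshold a score track into hot-spot segments
#'
#' Residues whose score passes the rule's comparison form candidate runs;
#' runs shorter than `min_run` are dropped, and -- when the rule excludes
#' prolines -- runs containing a proline are dropped entirely. Missing
#' scores never pass.
#'
#' @param track a [load_track()] result.
#' @param rule a rule list; defaults to the track's named predictor rule.
#' @param sequence one-letter sequence, required when the rule excludes
#'   prolines.
#' @return a [segment_set()] labelled with the predictor name.
#' @export
threshold_track <- function(track, rule = NULL, sequence = NULL) {
  if (is.null(rule)) rule <- predictor_rule(track$predictor)
  pass <- !is.na(track$score) & rule$op(track$score, rule$threshold)
  seg <- mask_to_segments(pass, source = track$predictor,
                          threshold = rule$threshold)
  keep <- rep(TRUE, nrow(seg))
  if (rule$min_run > 1L)
    keep <- keep & (seg$end - seg$start + 1L >= rule$min_run)
  if (isTRUE(rule$exclude_proline)) {
    if (is.null(sequence))
      stop("rule excludes prolines: sequence required")
    aa <- strsplit(toupper(sequence), "")[[1L]]
    if (length(aa) != length(track$score))
      stop("sequence length does not match track length")
    keep <- keep & !vapply(seq_len(nrow(seg)), function(i)
      any(aa[seg$start[i]:seg$end[i]] == "P"), logical(1))
  }
  segment_set(seg$start[keep], seg$end[keep], source = track$predictor,
              threshold = rule$threshold)
}
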