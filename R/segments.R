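#' Residue segment sets
#'
#' A `segment_set` is a normalised list of 1-based, inclusive residue
#' intervals: sorted by start, with overlapping or directly adjacent
#' intervals merged, so every residue set has exactly one canonical
#' representation. Segment sets are the common currency for experimental
#' profile peaks and predicted aggregation hot spots.
#'
#' @param start,end integer vectors of equal length (inclusive bounds).
#' @param source character label recording where the segments come from
#'   (e.g. `"experimental_lb4"`, `"zyggregator"`).
#' @param threshold numeric, the decision threshold that produced them (NA
#'   when not applicable).
#' @return An object of class `segment_set`: a data frame with columns
#'   `start` and `end`, plus `source` and `threshold` attributes.
#' @examples
#' segment_set(c(31, 12), c(42, 21))        # sorted on the way in
#' segment_set(c(10, 11), c(12, 14))        # merged to 10-14
#' @export
segment_set <- function(start = integer(0), end = integer(0),
                        source = "segments", threshold = NA_real_) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (any(is.na(start)) || any(is.na(end))) stop("NA interval bounds")
  if (any(end < start)) stop("interval end before start")
  if (length(start)) {
    o <- order(start, end)
    start <- start[o]; end <- end[o]
    # merge overlapping or touching intervals into canonical form
    ks <- ke <- integer(0)
    cs <- start[1L]; ce <- end[1L]
    for (i in seq_along(start)[-1L]) {
      if (start[i] <= ce + 1L) {
        ce <- max(ce, end[i])
      } else {
        ks <- c(ks, cs); ke <- c(ke, ce)
        cs <- start[i]; ce <- end[i]
      }
    }
    start <- c(ks, cs); end <- c(ke, ce)
  }
  structure(data.frame(start = start, end = end),
            source = source, threshold = threshold,
            class = c("segment_set", "data.frame"))
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", attr(x, "source"), ": ", sep = "")
  if (!nrow(x)) cat("(empty)\n")
  else cat(paste0(x$start, "-", x$end, collapse = ", "), "\n")
  invisible(x)
}

#' Total residues covered by a segment set
#' @param x a `segment_set`.
#' @return integer count of residues in the union of intervals.
#' @export
segment_residues <- function(x) {
  if (!nrow(x)) return(0L)
  sum(x$end - x$start + 1L)
}

#' Convert segments to a per-residue binary mask
#'
#' @param segments a [segment_set()].
#' @param l protein length; intervals must lie within `[1, l]`.
#' @return logical vector of length `l`, `TRUE` on the union of intervals.
#' @examples
#' sum(segments_to_mask(segment_set(c(15, 31), c(21, 42)), 42))  # 19
#' @export
segments_to_mask <- function(segments, l) {
  l <- as.integer(l)
  if (nrow(segments) && (min(segments$start) < 1L || max(segments$end) > l))
    stop("segment outside [1, ", l, "]")
  m <- logical(l)
  for (i in seq_len(nrow(segments))) m[segments$start[i]:segments$end[i]] <- TRUE
  m
}

#' Convert a binary mask back to segments
#'
#' Inverse of [segments_to_mask()]: maximal runs of `TRUE` become intervals.
#'
#' @param mask logical vector (NA treated as `FALSE`).
#' @inheritParams segment_set
#' @return a [segment_set()].
#' @export
mask_to_segments <- function(mask, source = "segments",
                             threshold = NA_real_) {
  mask <- !is.na(mask) & mask
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  segment_set(starts[keep], ends[keep], source = source,
              threshold = threshold)
}

#' Read and write BED-like segment tables
#'
#' The on-disk format is a tab-separated table with columns `protein`,
#' `start`, `end`, `source`, `threshold` using 1-based inclusive residue
#' coordinates. Note the deliberate off-by-one versus genomic BED, which is
#' 0-based half-open: residue intervals in this package always match the
#' numbering printed in structure annotations.
#'
#' @param file path to a TSV file.
#' @param source optional; restrict to rows with this `source` label.
#' @param protein optional; restrict to rows with this `protein` label.
#' @return `read_segments()`: a named list of [segment_set()] (one per
#'   source present, in file order), or a single `segment_set` when `source`
#'   is given. `write_segments()`: the file path, invisibly.
#' @export
read_segments <- function(file, source = NULL, protein = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("protein", "start", "end", "source", "threshold")
  if (!all(need %in% names(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  if (!is.null(protein)) df <- df[df$protein == protein, , drop = FALSE]
  if (!is.null(source)) {
    df <- df[df$source == source, , drop = FALSE]
    if (!nrow(df)) stop("no segments with source '", source, "' in ", file)
    return(segment_set(df$start, df$end, source = source,
                       threshold = df$threshold[1L]))
  }
  out <- lapply(split(df, factor(df$source, unique(df$source))), function(d)
    segment_set(d$start, d$end, source = d$source[1L],
                threshold = d$threshold[1L]))
  out
}

#' @rdname read_segments
#' @param x a `segment_set` or named list of them.
#' @param append logical; append to an existing file without a header.
#' @export
write_segments <- function(x, file, protein = "protein", append = FALSE) {
  if (inherits(x, "segment_set")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(s) {
    if (!nrow(s)) return(NULL)
    data.frame(protein = protein, start = s$start, end = s$end,
               source = attr(s, "source"),
               threshold = attr(s, "threshold"))
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(file)
}

#' Packaged segment fixtures
#'
#' The experimental profile peaks and the published predictor hot-spot
#' intervals for the built-in proteins, as shipped in `inst/extdata`.
#' Available sources: `experimental_lb1`, `experimental_lb4` for all three
#' proteins; `zyggregator`, `aggrescan`, `tango`, `waltz`, `pasta`
#' additionally for `abeta42` and `asyn` (the tau predictor intervals are
#' not bundled because they were never published as intervals).
#'
#' @param protein `"abeta42"`, `"asyn"` or `"tau_2n4r"`.
#' @inheritParams read_segments
#' @return as [read_segments()].
#' @examples
#' builtin_segments("abeta42", "zyggregator")
#' @export
builtin_segments <- function(protein = c("abeta42", "asyn", "tau_2n4r"),
                             source = NULL) {
  protein <- match.arg(protein)
  file <- system.file("extdata", paste0(protein, "_segments.tsv"),
                      package = "fibrilbeta", mustWork = TRUE)
  read_segments(file, source = source)
}
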