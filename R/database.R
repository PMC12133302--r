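#' Fibril structure database
#'
#' A `fibril_entry` groups the molecule-level [beta_annotation()]s of one
#' deposited structure; a `fibril_database` groups the entries of one
#' protein. Each molecule conformation is one *element* of the database:
#' entries whose molecules adopt distinct conformations contribute several
#' elements, which is how multi-molecule structures are weighted in the
#' preference profile.
#'
#' @param entry_id structure accession; all molecules must agree with it.
#' @param molecules list of [beta_annotation()] (at least one).
#' @param metadata optional named list (technique, construct label, ...).
#' @return `fibril_entry()`: an object of class `fibril_entry`.
#' @export
fibril_entry <- function(entry_id, molecules, metadata = list()) {
  stopifnot(length(molecules) >= 1L)
  ok <- vapply(molecules, function(m)
    inherits(m, "beta_annotation") && m$entry_id == entry_id, logical(1))
  if (!all(ok)) stop("all molecules must be beta_annotations of ", entry_id)
  structure(list(entry_id = as.character(entry_id), molecules = molecules,
                 metadata = metadata),
            class = "fibril_entry")
}

#' @rdname fibril_entry
#' @param protein a [protein_def()].
#' @param entries list of `fibril_entry`; every coverage must lie within
#'   `[1, protein$length]`.
#' @return `fibril_database()`: an object of class `fibril_database`.
#' @export
fibril_database <- function(protein, entries) {
  stopifnot(inherits(protein, "protein_def"), length(entries) >= 1L)
  for (e in entries) {
    stopifnot(inherits(e, "fibril_entry"))
    for (m in e$molecules)
      if (m$coverage[2L] > protein$length)
        stop("coverage of ", e$entry_id, " exceeds protein length ",
             protein$length)
  }
  structure(list(protein = protein, entries = entries),
            class = "fibril_database")
}

#' @export
print.fibril_database <- function(x, ...) {
  cat("<fibril_database> ", x$protein$name, ": ", length(x$entries),
      " entries, ", count_elements(x), " elements\n", sep = "")
  invisible(x)
}

#' Count database elements
#'
#' One element per molecule conformation: an entry with a single conformer
#' contributes one element, an entry whose molecules differ contributes one
#' element per molecule.
#'
#' @param x a [fibril_database()], or an entry manifest data frame with a
#'   `n_molecules` column (see [read_entry_manifest()]).
#' @return integer element count.
#' @export
count_elements <- function(x) UseMethod("count_elements")

#' @export
count_elements.fibril_database <- function(x)
  sum(vapply(x$entries, function(e) length(e$molecules), integer(1)))

#' @export
count_elements.data.frame <- function(x) {
  if (!"n_molecules" %in% names(x))
    stop("manifest needs a n_molecules column")
  sum(as.integer(x$n_molecules))
}

#' Assemble annotations into a database
#'
#' Groups a flat list of [beta_annotation()]s (e.g. from
#' [load_strand_annotation()] or [parse_structure()]) by `entry_id` into
#' [fibril_entry()]s, ordered by molecule index within each entry.
#'
#' @param annotations list of `beta_annotation`.
#' @param protein a [protein_def()].
#' @return a [fibril_database()].
#' @export
annotations_to_database <- function(annotations, protein) {
  ids <- vapply(annotations, function(a) a$entry_id, character(1))
  entries <- lapply(split(annotations, factor(ids, unique(ids))),
                    function(ms) {
    ms <- ms[order(vapply(ms, function(m) m$molecule_index, integer(1)))]
    fibril_entry(ms[[1L]]$entry_id, ms)
  })
  fibril_database(protein, unname(entries))
}

# apply a per-annotation transform to every molecule of every entry
db_map <- function(db, f) {
  db$entries <- lapply(db$entries, function(e) {
    e$molecules <- lapply(e$molecules, f)
    e
  })
  db
}

#' Apply bridging and strand-length filtering across a database
#'
#' Convenience wrapper running [apply_bridging_rule()] (with the protein's
#' configured flexible positions) and/or [filter_strand_length()] on every
#' molecule.
#'
#' @param db a [fibril_database()].
#' @param bridge logical; apply the bridging rule first.
#' @param lbeta_min minimum strand length (1 leaves annotations unchanged).
#' @return the transformed database.
#' @export
db_annotate <- function(db, bridge = FALSE, lbeta_min = 1L) {
  if (bridge) {
    flex <- db$protein$flexible_positions
    db <- db_map(db, function(m) {
      inside <- flex[flex >= m$coverage[1L] & flex <= m$coverage[2L]]
      apply_bridging_rule(m, inside)
    })
  }
  if (lbeta_min > 1L)
    db <- db_map(db, function(m) filter_strand_length(m, lbeta_min))
  db
}

#' Read an entry manifest
#'
#' A manifest is a TSV with columns `entry_id` and `n_molecules` listing
#' the structures of a protein and how many distinct molecule
#' conformations each contributes. Manifests for the three calibrated
#' proteins ship in `inst/extdata` (`abeta_entries.tsv`,
#' `asyn_entries.tsv`, `tau_entries.tsv`).
#'
#' @param file path to the TSV, or one of the shipped names above.
#' @return data frame with columns `entry_id`, `n_molecules`.
#' @examples
#' count_elements(read_entry_manifest("abeta_entries.tsv"))  # 39
#' @export
read_entry_manifest <- function(file) {
  if (!file.exists(file)) {
    shipped <- system.file("extdata", file, package = "fibrilbeta")
    if (nzchar(shipped)) file <- shipped else stop("cannot read ", file)
  }
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("entry_id", "n_molecules") %in% names(df)))
    stop("manifest must have columns entry_id, n_molecules")
  df$n_molecules <- as.integer(df$n_molecules)
  df
}

#' Write the element manifest of a database
#'
#' @param db a [fibril_database()].
#' @param file output TSV path (element-level: one row per molecule).
#' @return the manifest data frame, invisibly writing it when `file` is
#'   not `NULL`.
#' @export
db_manifest <- function(db, file = NULL) {
  rows <- do.call(rbind, lapply(db$entries, function(e)
    do.call(rbind, lapply(e$molecules, function(m)
      data.frame(entry_id = e$entry_id, molecule_index = m$molecule_index,
                 coverage_start = m$coverage[1L],
                 coverage_end = m$coverage[2L],
                 n_beta = sum(m$beta))))))
  rownames(rows) <- NULL
  if (!is.null(file))
    utils::write.table(rows, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(rows)
}
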