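## Synthetic inputs: ensembles of beta annotations generated from planted
## core segments with i.i.d. per-residue flip noise, and mock backbone
## coordinates realised from specified (phi, psi) angles so the dihedral
## assignment path can be exercised end to end without real structures.

#' Specify a synthetic fibril ensemble
#'
#' The generator's stated world mirrors the shape of a curated amyloid
#' ensemble: ~30 deposited structures of a 42-residue peptide with two
#' planted core segments, most entries contributing a single molecule
#' conformation, a minority two and rarely three (the defaults reproduce
#' the 22:7:1 split over 30 entries seen for the amyloid-beta ensemble),
#' plus an optional C-terminal truncation model emulating the coexistence
#' of 40- and 42-residue constructs.
#'
#' @param l protein length.
#' @param planted a [segment_set()] (or list of `c(start, end)` pairs) of
#'   true beta-core segments within `[1, l]`.
#' @param n_entries number of entries.
#' @param molecule_dist probabilities for 1, 2 and 3 molecules per entry.
#' @param noise per-residue probability in `[0, 0.5)` of flipping the
#'   planted beta state.
#' @param coverage optional truncation model: list with `prob` (fraction
#'   of entries truncated) and `last` (their final residue).
#' @param seed integer seed making [generate_ensemble()] reproducible.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(l = 42L,
                          planted = segment_set(c(12L, 31L), c(21L, 42L),
                                                source = "planted"),
                          n_entries = 30L,
                          molecule_dist = c(22, 7, 1) / 30,
                          noise = 0.05, coverage = NULL, seed = 1L) {
  if (!inherits(planted, "segment_set")) {
    iv <- do.call(rbind, planted)
    planted <- segment_set(iv[, 1L], iv[, 2L], source = "planted")
  }
  stopifnot(l >= 1L, n_entries >= 1L, noise >= 0, noise < 0.5,
            length(molecule_dist) == 3L,
            abs(sum(molecule_dist) - 1) < 1e-8)
  if (nrow(planted) && max(planted$end) > l)
    stop("planted segments outside [1, l]")
  if (!is.null(coverage))
    stopifnot(is.list(coverage), coverage$last >= 1L, coverage$last <= l,
              coverage$prob >= 0, coverage$prob <= 1)
  structure(list(l = as.integer(l), planted = planted,
                 n_entries = as.integer(n_entries),
                 molecule_dist = molecule_dist, noise = noise,
                 coverage = coverage, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# evaluate expr under the spec's seed, leaving the caller's RNG untouched
with_spec_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic fibril database
#'
#' Each entry draws its molecule count from `molecule_dist` and (when a
#' coverage model is set) whether it is C-terminally truncated; each
#' molecule's annotation is the planted beta mask restricted to the
#' entry's coverage with independent per-residue flips at the spec's noise
#' rate. Identical seeds give identical databases. Strand-length
#' filtering is *not* applied here -- downstream code applies it exactly
#' as for real annotations.
#'
#' @param spec an [ensemble_spec()].
#' @return a [fibril_database()] over a synthetic [protein_def()].
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_spec_seed(spec$seed, {
    planted_full <- segments_to_mask(spec$planted, spec$l)
    entries <- lapply(seq_len(spec$n_entries), function(i) {
      nmol <- sample.int(3L, 1L, prob = spec$molecule_dist)
      last <- spec$l
      if (!is.null(spec$coverage) &&
          stats::runif(1) < spec$coverage$prob)
        last <- as.integer(spec$coverage$last)
      truth <- planted_full[seq_len(last)]
      mols <- lapply(seq_len(nmol), function(j) {
        flips <- stats::runif(last) < spec$noise
        beta_annotation(sprintf("SYN%04d", i), j, c(1L, last),
                        xor(truth, flips))
      })
      fibril_entry(sprintf("SYN%04d", i), mols)
    })
    fibril_database(protein_def("synthetic", spec$l), entries)
  })
}

#' Write a database as a strand-annotation TSV
#'
#' Serialises every molecule's beta strands in the format read back by
#' [load_strand_annotation()], closing the synthetic-to-ingestion loop.
#'
#' @param db a [fibril_database()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_strand_annotation <- function(db, file) {
  rows <- do.call(rbind, lapply(db$entries, function(e)
    do.call(rbind, lapply(e$molecules, function(m) {
      seg <- annotation_segments(m)
      if (!nrow(seg))
        seg <- data.frame(start = NA_integer_, end = NA_integer_)
      data.frame(entry_id = e$entry_id,
                 molecule_index = m$molecule_index,
                 coverage_start = m$coverage[1L],
                 coverage_end = m$coverage[2L],
                 strand_start = seg$start, strand_end = seg$end)
    }))))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

## --- backbone construction from internal coordinates -------------------

# ideal backbone geometry (Angstrom, degrees); omega fixed trans
.GEO <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
             a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
             omega = 180)

# natural extension reference frame: place atom d given a, b, c with bond
# |c-d|, angle b-c-d and torsion a-b-c-d (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  # torsion negated so the placed geometry measures back with the IUPAC
  # sign convention used by torsion_angle()
  th <- angle * pi / 180; ch <- -torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / sqrt(sum(nv^2))
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * cos(ch) * mv +
                sin(th) * sin(ch) * nv)
}

#' Build mock backbone coordinates from a beta annotation
#'
#' Realises an N-CA-C backbone chain by sequential internal-coordinate
#' placement with ideal bond lengths and angles and trans peptide bonds,
#' choosing each residue's (phi, psi) from `angle_map` according to its
#' beta state in the annotation, with optional uniform jitter. Recomputed
#' dihedrals match the requested angles to well under half a degree at
#' zero jitter, so the full assignment pipeline round-trips the planted
#' mask exactly when the map's angles sit inside / outside the configured
#' Ramachandran region with margin.
#'
#' @param annotation a [beta_annotation()] providing residue numbering and
#'   the beta mask.
#' @param angle_map list with numeric `beta` and `coil` elements, each
#'   `c(phi, psi)` in degrees. Defaults: beta (-120, 135), coil (-60,
#'   -45).
#' @param jitter half-width (degrees) of uniform noise added to every
#'   placed torsion.
#' @param seed optional seed for the jitter draw.
#' @param file optional path; when given, the chain is written as a
#'   minimal PDB file.
#' @param sequence optional one-letter codes for the covered residues
#'   (defaults to poly-alanine).
#' @param pad_termini add one coil residue beyond each end of the
#'   coverage (the leading pad is skipped when coverage starts at residue
#'   1, which cannot be renumbered below 1). Without padding, the
#'   terminal residues have an undefined phi or psi and can never be
#'   re-assigned beta from coordinates, so planted strands touching a
#'   terminus would not round-trip.
#' @return a [chain_trace()] (invisibly when `file` is given).
#' @export
build_coordinates <- function(annotation,
                              angle_map = list(beta = c(-120, 135),
                                               coil = c(-60, -45)),
                              jitter = 0, seed = NULL, file = NULL,
                              sequence = NULL, pad_termini = TRUE) {
  if (jitter > 0 && !is.null(seed))
    return(with_spec_seed(seed, build_coordinates(
      annotation, angle_map, jitter, seed = NULL, file = file,
      sequence = sequence, pad_termini = pad_termini)))
  beta <- annotation$beta
  cov <- annotation$coverage
  pad_head <- isTRUE(pad_termini) && cov[1L] > 1L
  if (isTRUE(pad_termini)) {
    beta <- c(if (pad_head) FALSE, beta, FALSE)
    cov <- c(cov[1L] - pad_head, cov[2L] + 1L)
    if (!is.null(sequence))
      sequence <- paste0(if (pad_head) "A", sequence, "A")
  }
  nres <- length(beta)
  if (nres < 2L) stop("need at least two residues to build a chain")
  pick <- function(i) if (beta[i]) angle_map$beta else angle_map$coil
  jit <- if (jitter > 0)
    function(x) x + stats::runif(length(x), -jitter, jitter)
  else identity
  g <- .GEO
  N <- CA <- C <- matrix(NA_real_, nres, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres - 1L)) {
    psi_i <- jit(pick(i)[2L])
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                              g$b_c_n, g$a_ca_c_n, psi_i)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                               g$b_n_ca, g$a_c_n_ca, g$omega)
    phi_next <- jit(pick(i + 1L)[1L])
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              g$b_ca_c, g$a_n_ca_c, phi_next)
  }
  if (any(!is.finite(N)) || any(!is.finite(CA)) || any(!is.finite(C)))
    stop("degenerate geometry while building coordinates")
  resno <- cov[1L]:cov[2L]
  aa <- if (is.null(sequence)) rep("A", nres)
        else strsplit(toupper(sequence), "")[[1L]]
  tr <- chain_trace(annotation$entry_id, "A", resno, aa, N, CA, C)
  if (!is.null(file)) {
    write_pdb(tr, file)
    return(invisible(tr))
  }
  tr
}

#' Write a chain trace as a minimal PDB file
#'
#' Backbone-only ATOM records (N, CA, C), single chain, single model.
#'
#' @param chain a [chain_trace()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(chain, file) {
  aa1to3 <- stats::setNames(names(.AA3TO1), .AA3TO1)
  serial <- 0L
  lines <- character(0)
  for (i in seq_along(chain$resno)) {
    res3 <- aa1to3[chain$aa[i]]
    if (is.na(res3)) res3 <- "UNK"
    for (atom in c("N", "CA", "C")) {
      xyz <- switch(atom, N = chain$n[i, ], CA = chain$ca[i, ],
                    C = chain$c[i, ])
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, atom, res3, chain$chain_id, chain$resno[i],
        xyz[1L], xyz[2L], xyz[3L], substr(atom, 1L, 1L)))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
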