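## Coordinate ingestion: minimal backbone readers for PDB and mmCIF, chain
## traces, and phi/psi computation. Only N, CA, C atoms of the first model
## are ever used; side chains, occupancies and B-factors are irrelevant to
## the dihedral-based beta assignment.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa3to1 <- function(x) {
  out <- .AA3TO1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Chain trace: ordered backbone coordinates of one molecule
#'
#' @param entry_id structure accession string.
#' @param chain_id chain identifier.
#' @param resno integer vector of residue numbers, strictly increasing.
#' @param aa one-letter amino-acid codes, same length as `resno`.
#' @param n,ca,c numeric matrices (`length(resno)` x 3) of backbone atom
#'   coordinates in Angstrom; rows with any missing atom are `NA` and the
#'   residue is flagged incomplete.
#' @return An object of class `chain_trace`.
#' @export
chain_trace <- function(entry_id, chain_id, resno, aa, n, ca, c) {
  resno <- as.integer(resno)
  if (is.unsorted(resno, strictly = TRUE))
    stop("residue numbers must be strictly increasing along a chain")
  for (m in list(n, ca, c))
    stopifnot(is.matrix(m), nrow(m) == length(resno), ncol(m) == 3L)
  complete <- stats::complete.cases(n) & stats::complete.cases(ca) &
    stats::complete.cases(c)
  structure(list(entry_id = entry_id, chain_id = chain_id, resno = resno,
                 aa = aa, n = n, ca = ca, c = c, complete = complete),
            class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat("<chain_trace> ", x$entry_id, " chain ", x$chain_id, ": ",
      length(x$resno), " residues (", x$resno[1L], "-",
      x$resno[length(x$resno)], ")\n", sep = "")
  invisible(x)
}

# Reads ATOM/HETATM backbone records from a PDB file; first model only,
# first alternate location only.
read_backbone_pdb <- function(file) {
  lines <- readLines(file, warn = FALSE)
  end <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(end)) lines <- lines[seq_len(end[1L] - 1L)]
  rec <- lines[substr(lines, 1, 4) == "ATOM"]
  if (!length(rec)) stop("no ATOM records in ", file)
  atom <- trimws(substr(rec, 13, 16))
  keep <- atom %in% c("N", "CA", "C")
  alt <- substr(rec, 17, 17)
  keep <- keep & alt %in% c(" ", "", "A")
  rec <- rec[keep]; atom <- atom[keep]
  data.frame(
    chain = substr(rec, 22, 22),
    resno = as.integer(substr(rec, 23, 26)),
    resname = trimws(substr(rec, 18, 20)),
    atom = atom,
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    stringsAsFactors = FALSE)
}

# Minimal mmCIF reader for the atom_site loop. Assumes whitespace-delimited
# data rows (true for coordinate fields) and strips single/double quotes
# from atom names.
read_backbone_cif <- function(file) {
  lines <- readLines(file, warn = FALSE)
  i <- 1L; n <- length(lines)
  fields <- character(0); rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L; fl <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        fl <- c(fl, trimws(lines[j])); j <- j + 1L
      }
      if (any(startsWith(fl, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", fl)
        while (j <= n) {
          ln <- trimws(lines[j])
          if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
              ln == "loop_" || startsWith(ln, "data_")) break
          rows[[length(rows) + 1L]] <- strsplit(ln, "[[:space:]]+")[[1L]]
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("no atom_site loop in ", file)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(opts) {
    hit <- opts[opts %in% fields]
    if (!length(hit)) stop("mmCIF atom_site missing field: ",
                           paste(opts, collapse = "/"))
    m[, hit[1L]]
  }
  atom <- gsub('["\']', "", get(c("label_atom_id", "auth_atom_id")))
  df <- data.frame(
    chain = get(c("auth_asym_id", "label_asym_id")),
    resno = as.integer(get(c("auth_seq_id", "label_seq_id"))),
    resname = get(c("label_comp_id", "auth_comp_id")),
    atom = atom,
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    stringsAsFactors = FALSE)
  grp <- if ("group_PDB" %in% fields) m[, "group_PDB"] else "ATOM"
  mdl <- if ("pdbx_PDB_model_num" %in% fields) m[, "pdbx_PDB_model_num"]
         else "1"
  df <- df[grp == "ATOM" & mdl == mdl[1L] & df$atom %in% c("N", "CA", "C"), ]
  df
}

atoms_to_traces <- function(df, entry_id) {
  lapply(split(df, df$chain), function(d) {
    if (!nrow(d)) return(NULL)
    resno <- sort(unique(d$resno))
    pick <- function(atom) {
      m <- matrix(NA_real_, length(resno), 3L)
      da <- d[d$atom == atom, ]
      da <- da[!duplicated(da$resno), ]
      idx <- match(da$resno, resno)
      m[idx, ] <- as.matrix(da[, c("x", "y", "z")])
      m
    }
    aa <- aa3to1(d$resname[match(resno, d$resno)])
    chain_trace(entry_id, d$chain[1L], resno, aa,
                pick("N"), pick("CA"), pick("C"))
  })
}

#' Parse a fibril coordinate file into per-molecule chain traces
#'
#' Reads a PDB or mmCIF file (first model), extracts one backbone trace per
#' chain and collapses chains that represent stacked copies of the same
#' molecule. Fibrils are built from many symmetry-related layers, so a
#' deposited file typically contains several chains per distinct
#' conformer. Without an explicit `chain_map`, chains are grouped by the
#' beta-annotation they produce after the full assignment pipeline
#' (dihedrals, Ramachandran region, bridging, strand-length filter):
#' identical patterns collapse to one molecule, distinct patterns become
#' separate molecules with increasing `molecule_index`. An explicit
#' `chain_map` (named integer vector, chain id to molecule index) overrides
#' the grouping entirely.
#'
#' @param file path to a `.pdb` or `.cif`/`.mmcif` file (format sniffed
#'   from content when the extension is ambiguous).
#' @param chain_map optional named integer vector mapping chain ids to
#'   molecule indices.
#' @param region Ramachandran beta region passed to [assign_beta()].
#' @param flexible_positions passed to [apply_bridging_rule()].
#' @param lbeta_min passed to [filter_strand_length()].
#' @param entry_id accession recorded on the traces; defaults to the file
#'   base name.
#' @return list of `chain_trace`, one per distinct molecule, each carrying
#'   a `molecule_index` attribute (and a `beta_annotation` attribute with
#'   the annotation used for grouping).
#' @export
parse_structure <- function(file, chain_map = NULL,
                            region = default_beta_region(),
                            flexible_positions = integer(0),
                            lbeta_min = 1L, entry_id = NULL) {
  if (!file.exists(file)) stop("cannot read coordinate file: ", file)
  if (is.null(entry_id))
    entry_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(file),
                    ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", basename(file)))
  df <- if (ext %in% c("cif", "mmcif")) read_backbone_cif(file)
        else if (ext %in% c("pdb", "ent")) read_backbone_pdb(file)
        else if (any(grepl("^_atom_site\\.", readLines(file, n = 200L))))
          read_backbone_cif(file)
        else read_backbone_pdb(file)
  traces <- atoms_to_traces(df, entry_id)
  empty <- vapply(traces, is.null, logical(1))
  if (any(empty)) {
    warning("skipping empty chain(s) in ", basename(file))
    traces <- traces[!empty]
  }
  if (!length(traces)) stop("no usable chains in ", file)
  anns <- lapply(traces, function(tr) {
    a <- assign_beta(compute_dihedrals(tr), region = region,
                     entry_id = entry_id)
    a <- apply_bridging_rule(a, flexible_positions)
    filter_strand_length(a, lbeta_min)
  })
  chains <- vapply(traces, function(tr) tr$chain_id, character(1))
  if (!is.null(chain_map)) {
    missing <- setdiff(chains, names(chain_map))
    if (length(missing))
      stop("chain_map does not cover chain(s): ",
           paste(missing, collapse = ", "))
    idx <- as.integer(chain_map[chains])
    # representative chain per molecule index: smallest chain id, so the
    # result is insensitive to record order in the file
    keep <- vapply(sort(unique(idx)), function(k)
      which(idx == k)[order(chains[idx == k])][1L], integer(1))
    mol_of <- sort(unique(idx))
  } else {
    key <- vapply(anns, function(a)
      paste0(a$coverage[1L], ":", paste(as.integer(a$beta), collapse = "")),
      character(1))
    o <- order(chains)          # canonical order, not file order
    first <- o[!duplicated(key[o])]
    keep <- first[order(match(key[first], key[o][!duplicated(key[o])]))]
    mol_of <- seq_along(keep)
  }
  out <- traces[keep]
  for (i in seq_along(out)) {
    ann <- anns[[keep[i]]]
    ann$molecule_index <- mol_of[i]
    attr(out[[i]], "molecule_index") <- mol_of[i]
    attr(out[[i]], "beta_annotation") <- ann
  }
  unname(out)
}

# Torsion angle (degrees, in (-180, 180]) of four points given as rows.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone dihedral angles of a chain trace
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). An angle is undefined at chain termini, next to
#' residues with incomplete backbones, and across chain breaks, detected as
#' a C(i-1)-N(i) peptide-bond distance exceeding `break_tol`.
#'
#' @param chain a [chain_trace()].
#' @param break_tol maximum C-N distance (Angstrom) for a contiguous
#'   peptide bond; the conventional bond length is 1.33 A.
#' @return data frame with columns `index`, `aa`, `phi`, `psi`, `defined`.
#'   `defined` is `TRUE` only when both angles could be computed; it is the
#'   flag [assign_beta()] consults, so termini and break-adjacent residues
#'   can never be called beta from coordinates alone.
#' @export
compute_dihedrals <- function(chain, break_tol = 2.5) {
  nres <- length(chain$resno)
  phi <- psi <- rep(NA_real_, nres)
  bonded <- function(i, j) {     # peptide bond C(i) -> N(j)
    if (!chain$complete[i] || !chain$complete[j]) return(FALSE)
    sqrt(sum((chain$c[i, ] - chain$n[j, ])^2)) <= break_tol
  }
  for (i in seq_len(nres)) {
    if (!chain$complete[i]) next
    if (i > 1L && bonded(i - 1L, i))
      phi[i] <- torsion_angle(chain$c[i - 1L, ], chain$n[i, ],
                              chain$ca[i, ], chain$c[i, ])
    if (i < nres && bonded(i, i + 1L))
      psi[i] <- torsion_angle(chain$n[i, ], chain$ca[i, ],
                              chain$c[i, ], chain$n[i + 1L, ])
  }
  data.frame(index = chain$resno, aa = chain$aa, phi = phi, psi = psi,
             defined = !is.na(phi) & !is.na(psi))
}
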