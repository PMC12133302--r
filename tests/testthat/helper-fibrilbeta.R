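# shared fixture builders; everything is constructed in code

# logical mask of length l with TRUE on the given c(start, end) intervals
mk_mask <- function(l, ...) {
  ivs <- list(...)
  if (!length(ivs)) return(logical(l))
  iv <- do.call(rbind, ivs)
  segments_to_mask(segment_set(iv[, 1], iv[, 2]), l)
}

# annotation over coverage with beta on the given intervals; interval
# pairs go in ..., bookkeeping arguments must be named
mk_ann <- function(..., entry = "E1", mol = 1L, cov = c(1L, 42L)) {
  full <- mk_mask(cov[2], ...)
  beta_annotation(entry, mol, cov, full[cov[1]:cov[2]])
}

# single-molecule entry wrapper
mk_entry <- function(entry = "E1", cov = c(1L, 42L), ...)
  fibril_entry(entry, list(mk_ann(..., entry = entry, cov = cov)))

# database of single-molecule entries sharing one protein length
mk_db <- function(entries, l = 42L)
  fibril_database(protein_def("toy", l), entries)

# random contingency table with l residues (any margins)
random_table <- function(l) {
  cuts <- sort(sample(0:l, 3L, replace = TRUE))
  contingency_table(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                    l - cuts[3])
}

# independent one-tail oracle: enumerate the full fixed-margin support
# with stats::dhyper point probabilities
fisher_oracle <- function(t) {
  rowt <- t$bte + t$bt0; cole <- t$bte + t$b0e
  b <- max(0, rowt + cole - t$l):min(rowt, cole)
  sum(stats::dhyper(b[b >= t$bte], cole, t$l - cole, rowt))
}

# write a multi-chain PDB: one copy of each trace with the given chain ids
write_multichain_pdb <- function(traces, chain_ids, file) {
  all_lines <- character(0)
  for (i in seq_along(traces)) {
    tmp <- tempfile(fileext = ".pdb")
    write_pdb(traces[[i]], tmp)
    ln <- readLines(tmp)
    ln <- ln[startsWith(ln, "ATOM")]
    substr(ln, 22, 22) <- chain_ids[i]
    all_lines <- c(all_lines, ln)
  }
  writeLines(c(all_lines, "END"), file)
  invisible(file)
}

# write a minimal mmCIF atom_site loop equivalent to a chain trace
write_cif <- function(chain, file) {
  hdr <- c("data_test", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.pdbx_PDB_model_num")
  rows <- character(0); id <- 0L
  for (i in seq_along(chain$resno)) for (atom in c("N", "CA", "C")) {
    xyz <- switch(atom, N = chain$n[i, ], CA = chain$ca[i, ],
                  C = chain$c[i, ])
    id <- id + 1L
    rows <- c(rows, sprintf("ATOM %d %s ALA %s %d %.3f %.3f %.3f 1",
                            id, atom, chain$chain_id, chain$resno[i],
                            xyz[1], xyz[2], xyz[3]))
  }
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}
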