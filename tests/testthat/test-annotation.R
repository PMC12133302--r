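dh_row <- function(index, phi, psi, defined = !is.na(phi) & !is.na(psi))
  data.frame(index = index, aa = "A", phi = phi, psi = psi,
             defined = defined)

test_that("assign_beta follows the Ramachandran region and the defined flag", {
  dh <- rbind(dh_row(1, NA, 140),          # terminus: undefined -> non-beta
              dh_row(2, -120, 135),        # canonical beta
              dh_row(3, -60, -45),         # canonical alpha
              dh_row(4, -150, -170),       # wrapped upper-left basin
              dh_row(5, 60, 40))           # left-handed region
  ann <- assign_beta(dh, entry_id = "x")
  expect_identical(ann$beta, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(ann$coverage, c(1L, 5L))
})

test_that("bridging promotes flexible residues ahead of a strand", {
  # beta from 39, Gly37-Gly38 flexible and initially non-beta
  ann <- mk_ann(cov = c(1L, 42L), c(39, 42), c(18, 26))
  out <- apply_bridging_rule(ann, c(37L, 38L))
  expect_true(all(beta_at(out, 37:38)))           # cascade right-to-left
  expect_identical(sum(out$beta) - sum(ann$beta), 2L)

  # flexible residue followed by non-beta: unchanged
  out2 <- apply_bridging_rule(mk_ann(cov = c(1L, 42L), c(18, 26)),
                              c(37L, 38L))
  expect_false(any(beta_at(out2, 37:38)))

  # empty flexible set is the identity
  expect_identical(apply_bridging_rule(ann, integer(0)), ann)

  # positions outside coverage warn and are ignored
  small <- mk_ann(cov = c(10L, 20L), c(12, 16))
  expect_warning(res <- apply_bridging_rule(small, c(5L, 11L)),
                 "outside coverage")
  expect_true(beta_at(res, 11))
})

test_that("bridging never removes beta and only touches configured positions", {
  set.seed(42)
  for (i in 1:25) {
    beta <- runif(42) < 0.4
    ann <- beta_annotation("r", 1L, c(1L, 42L), beta)
    flex <- sort(sample(1:42, 3L))
    out <- apply_bridging_rule(ann, flex)
    expect_true(all(out$beta[ann$beta]))
    changed <- which(out$beta != ann$beta)
    expect_true(all(changed %in% flex))
  }
})

test_that("strand-length filtering keeps only runs of at least L_beta_min", {
  ann <- mk_ann(cov = c(1L, 30L), c(2, 3), c(10, 14), c(20, 22))
  out <- filter_strand_length(ann, 4L)
  expect_identical(annotation_segments(out)$start, 10L)
  expect_identical(annotation_segments(out)$end, 14L)
  expect_identical(filter_strand_length(ann, 1L), ann)
  allf <- mk_ann(cov = c(1L, 30L))
  expect_identical(filter_strand_length(allf, 4L), allf)
})

test_that("filtering is idempotent and monotone in L_beta_min", {
  set.seed(7)
  for (i in 1:25) {
    ann <- beta_annotation("r", 1L, c(1L, 60L), runif(60) < 0.5)
    f4 <- filter_strand_length(ann, 4L)
    expect_identical(filter_strand_length(f4, 4L), f4)
    f1 <- filter_strand_length(ann, 1L)
    expect_true(all(f1$beta[f4$beta]))   # beta at 4 is a subset of beta at 1
  }
})

test_that("assign -> bridge -> filter lets a bridged residue rescue a strand", {
  # run 39-41 is length 3 and would die at L_beta >= 4; promoting 38 saves it
  ann <- mk_ann(cov = c(1L, 42L), c(39, 41))
  died <- filter_strand_length(ann, 4L)
  expect_identical(nrow(annotation_segments(died)), 0L)
  saved <- filter_strand_length(apply_bridging_rule(ann, 38L), 4L)
  expect_identical(annotation_segments(saved)$start, 38L)
})

test_that("strand-interval ingestion matches the curated fixture", {
  prot <- builtin_protein("abeta42")
  f <- system.file("extdata", "abeta_2beg_strands.tsv",
                   package = "fibrilbeta")
  anns <- load_strand_annotation(f, prot)
  expect_length(anns, 1L)
  expect_identical(sum(anns[[1]]$beta), 21L)  # 18-26 and 31-42
  seg <- annotation_segments(anns[[1]])
  expect_identical(seg$start, c(18L, 31L))
  expect_identical(seg$end, c(26L, 42L))
})

test_that("ingestion validates and merges intervals", {
  prot <- protein_def("toy", 42L)
  write_tsv <- function(df) {
    f <- tempfile(fileext = ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  # empty interval list -> all-false annotation
  f0 <- write_tsv(data.frame(entry_id = "e", molecule_index = 1,
                             coverage_start = 1, coverage_end = 42,
                             strand_start = NA, strand_end = NA))
  a0 <- load_strand_annotation(f0, prot)[[1]]
  expect_false(any(a0$beta))
  # overlapping intervals merge with a warning
  f1 <- write_tsv(data.frame(entry_id = "e", molecule_index = 1,
                             coverage_start = 1, coverage_end = 42,
                             strand_start = c(10, 11),
                             strand_end = c(12, 14)))
  expect_warning(a1 <- load_strand_annotation(f1, prot)[[1]], "merged")
  seg <- annotation_segments(a1)
  expect_identical(c(seg$start, seg$end), c(10L, 14L))
  # interval outside coverage is an error
  f2 <- write_tsv(data.frame(entry_id = "e", molecule_index = 1,
                             coverage_start = 5, coverage_end = 42,
                             strand_start = 2, strand_end = 10))
  expect_error(load_strand_annotation(f2, prot), "outside coverage")
})
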