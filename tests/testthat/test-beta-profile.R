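test_that("entry fractions weight molecules and respect coverage", {
  e <- fibril_entry("5kk3-like", list(
    mk_ann(entry = "5kk3-like", mol = 1L, cov = c(1L, 42L), c(24, 24), c(30, 40)),
    mk_ann(entry = "5kk3-like", mol = 2L, cov = c(1L, 40L), c(30, 40))))
  expect_equal(entry_fraction(e, 24), 0.5)
  expect_equal(entry_fraction(e, 35), 1.0)
  expect_equal(entry_fraction(e, 20), 0.0)
  expect_true(is.na(entry_fraction(
    fibril_entry("x", list(mk_ann(entry = "x", mol = 1L, cov = c(1L, 40L)))), 42)))
})

test_that("profile reproduces the worked normalisations", {
  # residue 6 in beta in 6 of 30 single-molecule entries -> 20 %
  entries <- lapply(1:30, function(i)
    if (i <= 6) mk_entry(paste0("e", i), c(1L, 42L), c(6, 9))
    else mk_entry(paste0("e", i), c(1L, 42L)))
  prof <- compute_profile(mk_db(entries))
  expect_equal(prof$raw[6], 20)
  expect_identical(prof$denominator[6], 30L)

  # residue 41 present only in 21 of 30 entries, beta in all 21
  entries2 <- lapply(1:30, function(i)
    if (i <= 21) mk_entry(paste0("f", i), c(1L, 42L), c(38, 42))
    else mk_entry(paste0("f", i), c(1L, 40L)))
  prof2 <- compute_profile(mk_db(entries2))
  expect_equal(prof2$raw[41], 100)
  expect_identical(prof2$denominator[41], 21L)

  # fractions {1.0, 0.5, 0.0} average to 50 %
  mk2 <- function(id, ...) fibril_entry(id, list(
    mk_ann(..., entry = id, mol = 1L),
    mk_ann(c(24, 24), entry = id, mol = 2L)))
  db3 <- mk_db(list(mk2("a", c(24, 24)), mk2("b"),
                    fibril_entry("c", list(mk_ann(entry = "c", mol = 1L, cov = c(1L, 42L))))))
  expect_equal(compute_profile(db3)$raw[24], 50)
})

test_that("window averaging truncates at termini and handles edge widths", {
  entries <- lapply(1:10, function(i) mk_entry(paste0("e", i), c(1L, 7L),
                                               c(4, 4)))
  prof <- compute_profile(mk_db(entries, l = 7L))
  sm <- window_average(prof, 7L)
  expect_equal(sm$smoothed[4], 100 / 7)
  expect_equal(sm$smoothed[1], 100 / 4)   # truncated window 1:4
  expect_identical(window_average(prof, 1L)$smoothed, prof$raw)
  const <- prof; const$raw <- rep(30, 7)
  expect_equal(window_average(const, 5L)$smoothed, rep(30, 7))
  expect_error(window_average(prof, 4L))
})

test_that("smoothed values stay within the raw range of their window", {
  spec <- ensemble_spec(noise = 0.2, seed = 11L)
  prof <- window_average(compute_profile(generate_ensemble(spec)), 7L)
  for (n in seq_len(nrow(prof))) {
    win <- prof$raw[max(1, n - 3):min(nrow(prof), n + 3)]
    expect_gte(prof$smoothed[n], min(win, na.rm = TRUE) - 1e-9)
    expect_lte(prof$smoothed[n], max(win, na.rm = TRUE) + 1e-9)
  }
})

test_that("segment extraction recovers plateaus and respects thresholds", {
  entries <- c(
    lapply(1:8, function(i) mk_entry(paste0("hi", i), c(1L, 42L),
                                     c(12, 21), c(31, 42))),
    lapply(1:2, function(i) mk_entry(paste0("lo", i), c(1L, 42L),
                                     c(1, 42))))
  prof <- compute_profile(mk_db(entries))  # 100% on plateaus, 20% elsewhere
  seg <- extract_segments(prof, 40, use_smoothed = FALSE)
  expect_identical(seg$start, c(12L, 31L))
  expect_identical(seg$end, c(21L, 42L))
  # threshold 0 with every value defined and positive: one full interval
  full <- extract_segments(prof, 0, use_smoothed = FALSE)
  expect_identical(c(full$start, full$end), c(1L, 42L))
  # everywhere-below-threshold profile gives an empty set
  lowp <- compute_profile(mk_db(lapply(1:3, function(i)
    mk_entry(paste0("z", i), c(1L, 42L)))))
  expect_identical(nrow(extract_segments(lowp, 50, use_smoothed = FALSE)), 0L)
  # smoothed extraction requires a smoothed profile
  expect_error(extract_segments(lowp, 50), "window_average")
})

test_that("element counting matches the published multi-molecule expansion", {
  expect_identical(count_elements(read_entry_manifest("abeta_entries.tsv")),
                   39L)
  expect_identical(count_elements(read_entry_manifest("asyn_entries.tsv")),
                   96L)
  expect_identical(count_elements(read_entry_manifest("tau_entries.tsv")),
                   25L)
  # database route: 10 entries with two molecules each -> 20 elements
  db <- generate_ensemble(ensemble_spec(n_entries = 10L,
                                        molecule_dist = c(0, 1, 0),
                                        seed = 3L))
  expect_identical(count_elements(db), 20L)
})

test_that("profile is permutation-invariant and monotone in L_beta_min", {
  spec <- ensemble_spec(noise = 0.15, seed = 23L)
  db <- generate_ensemble(spec)
  p1 <- compute_profile(db, lbeta_min = 1L)
  p4 <- compute_profile(db, lbeta_min = 4L)
  expect_true(all(p4$raw <= p1$raw + 1e-9, na.rm = TRUE))

  db_rev <- db; db_rev$entries <- rev(db$entries)
  expect_equal(compute_profile(db_rev)$raw, p1$raw)

  # identical annotations: exactly 100 on the beta set, 0 elsewhere
  same <- mk_db(lapply(1:5, function(i)
    mk_entry(paste0("s", i), c(1L, 42L), c(12, 21))))
  ps <- compute_profile(same)
  expect_true(all(ps$raw[12:21] == 100))
  expect_true(all(ps$raw[-(12:21)] == 0))
})
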