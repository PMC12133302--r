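test_that("contingency tables classify residues per the printed example", {
  pred <- mk_mask(42, c(15, 21), c(31, 42))
  exp_ <- mk_mask(42, c(12, 21), c(31, 42))
  t <- build_contingency(pred, exp_)
  expect_identical(c(t$bte, t$bt0, t$b0e, t$b00), c(19L, 0L, 3L, 20L))
  expect_identical(t$l, 42L)

  same <- build_contingency(exp_, exp_)
  expect_identical(c(same$bt0, same$b0e), c(0L, 0L))
  comp <- build_contingency(exp_, !exp_)
  expect_identical(c(comp$bte, comp$b00), c(0L, 0L))
  expect_error(build_contingency(pred, mk_mask(40)), "length")
})

test_that("Cohen's kappa matches the published values and edge cases", {
  expect_equal(round(cohen_kappa(contingency_table(19, 0, 3, 20)), 3),
               0.858)
  expect_equal(round(cohen_kappa(contingency_table(17, 3, 5, 17)), 3),
               0.620)
  m <- mk_mask(42, c(10, 20))
  expect_equal(cohen_kappa(build_contingency(m, m)), 1.0)
  expect_true(is.na(cohen_kappa(contingency_table(42, 0, 0, 0))))
  expect_true(is.na(cohen_kappa(contingency_table(0, 0, 0, 42))))
})

test_that("kappa is rater-symmetric and increasing in the concordant count", {
  set.seed(13)
  for (i in 1:50) {
    t <- random_table(sample(10:100, 1))
    tt <- contingency_table(t$bte, t$b0e, t$bt0, t$b00)  # transpose
    expect_equal(cohen_kappa(t), cohen_kappa(tt))
  }
  # fixed margins: slide bte along the support, kappa strictly increases
  for (marg in list(c(20, 12, 15), c(60, 30, 30), c(42, 19, 22))) {
    l <- marg[1]; rowt <- marg[2]; cole <- marg[3]
    support <- max(0, rowt + cole - l):min(rowt, cole)
    k <- vapply(support, function(b)
      cohen_kappa(contingency_table(b, rowt - b, cole - b,
                                    l - rowt - cole + b)), numeric(1))
    expect_true(all(diff(k) > 0))
  }
})

test_that("one-tail Fisher matches brute-force enumeration up to l = 60", {
  expect_equal(fisher_one_tail(contingency_table(2, 0, 0, 2)), 1 / 6)
  set.seed(17)
  for (i in 1:200) {
    t <- random_table(sample(4:60, 1))
    expect_equal(fisher_one_tail(t), fisher_oracle(t), tolerance = 1e-12)
  }
})

test_that("one-tail Fisher tail boundaries behave", {
  # bte minimal for its margins -> P = 1
  t_min <- contingency_table(0, 10, 10, 22)
  expect_equal(fisher_one_tail(t_min), 1)
  # bte maximal for its margins -> P = point probability alone
  t_max <- contingency_table(10, 0, 5, 27)
  rowt <- 10; cole <- 15; l <- 42
  expect_equal(fisher_one_tail(t_max), dhyper(10, cole, l - cole, rowt))
  set.seed(19)
  for (i in 1:50) {
    t <- random_table(50)
    p <- fisher_one_tail(t)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("labels follow the significance and kappa bands", {
  expect_identical(classify_agreement(0.858, 1e-6),
                   list(significance = "***",
                        kappa_class = "extremely good"))
  expect_identical(classify_agreement(0.45, 0.03)$significance, "*")
  expect_identical(classify_agreement(0.45, 0.03)$kappa_class, "good")
  expect_identical(classify_agreement(0.10, 0.2),
                   list(significance = "ns", kappa_class = "scarce"))
  # band edges are right-closed; kappa <= 0 is "none"; 0.05 is not "*"
  expect_identical(classify_agreement(0.2, 0.05),
                   list(significance = "ns", kappa_class = "scarce"))
  expect_identical(classify_agreement(0.8, 0.009),
                   list(significance = "**", kappa_class = "very good"))
  expect_identical(classify_agreement(0, 0.5)$kappa_class, "none")
  expect_identical(classify_agreement(NA, 0.5)$kappa_class, NA_character_)
})

test_that("per-structure agreement scores every element", {
  pred <- segment_set(c(12, 31), c(21, 42), source = "pred")
  db <- mk_db(lapply(1:6, function(i)
    mk_entry(paste0("e", i), c(1L, 42L), c(12, 21), c(31, 42))))
  res <- per_structure_agreement(db, pred, lbeta_min = 4L, bridge = FALSE)
  expect_identical(nrow(res), 6L)
  expect_true(all(res$kappa == 1))
  expect_named(attr(res, "summary"), c("q1", "median", "q3"))

  # empty prediction against non-empty elements: never positive agreement
  res0 <- per_structure_agreement(db, segment_set(), lbeta_min = 1L,
                                  bridge = FALSE)
  expect_true(all(res0$kappa <= 0))
})

test_that("per-structure kappa degrades with flip noise", {
  meds <- vapply(c(0.02, 0.15, 0.35), function(ns) {
    db <- generate_ensemble(ensemble_spec(noise = ns, seed = 101L))
    res <- per_structure_agreement(
      db, segment_set(c(12, 31), c(21, 42)), lbeta_min = 1L,
      bridge = FALSE)
    unname(attr(res, "summary")["median"])
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
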