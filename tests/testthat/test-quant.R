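test_that("isotopomer ratios: defined, undefined and zero cases", {
  rec <- abundance_record("M1", "[M+H]+", 1e6, 5e5)
  expect_equal(isotopomer_ratio(rec)$ratio, 2.0)
  # internal standard below detection limit -> undefined, not zero/error
  expect_true(is.na(isotopomer_ratio(
    abundance_record("M1", "[M+H]+", 1e6))$ratio))
  expect_true(is.na(isotopomer_ratio(
    abundance_record("M1", "[M+H]+", 1e6, 0))$ratio))
  expect_equal(isotopomer_ratio(
    abundance_record("M1", "[M+H]+", 0, 1e5))$ratio, 0.0)
  expect_error(abundance_record("M1", "[M+H]+", -1), "non-negative")
  # scale invariance under joint scaling
  for (k in c(0.1, 3, 1e4)) {
    expect_equal(
      isotopomer_ratio(abundance_record("M1", "[M+H]+", 2e5 * k, 9e4 * k))$ratio,
      isotopomer_ratio(abundance_record("M1", "[M+H]+", 2e5, 9e4))$ratio)
  }
})

test_that("normalization divides by biomass and rejects bad normalizers", {
  expect_equal(normalize_abundance(1e6, 2), 5e5)
  expect_equal(normalize_abundance(1e6, 1), 1e6)
  expect_error(normalize_abundance(1e6, 0), "> 0")
  expect_error(abundance_record("M1", "[M+H]+", 1, normalizer = 0), "> 0")
})

test_that("fold changes: arithmetic, reciprocity, errors", {
  expect_equal(fold_change(c(2, 2, 2, 2), c(1, 1, 1, 1)), 2.0)
  expect_error(fold_change(numeric(0), 1), "empty")
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero denominator")
  set.seed(3)
  for (i in 1:10) {
    a <- runif(4, 0.5, 10); b <- runif(4, 0.5, 10)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1.0,
                 tolerance = 1e-12)
  }
  # undefined ratios are dropped with a message
  expect_message(fold_change(c(2, NA), c(1, 1)), "dropping 1")
})

test_that("group test is an equal-variance Student t", {
  expect_equal(group_test(c(1, 1, 1), c(1, 1, 1)), 1.0)
  a <- c(5.1, 4.9, 5.3, 5.0); b <- c(2.2, 2.0, 1.9, 2.1)
  expect_equal(group_test(a, b),
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_error(group_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment matches hand-computed values", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  # three-element lists, worked by hand:
  #  sorted p (1,2,3): p_i * 3 / i with running minimum from the top
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
})

test_that("BH agrees with the stats oracle and is monotone", {
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # rank-preserving: sorting by p sorts adj non-decreasingly
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("fold_change_table reproduces per-compound group statistics", {
  df <- data.frame(
    compound = rep(c("arg", "glu"), each = 8),
    group = rep(rep(c("A", "B"), each = 4), 2),
    value = c(12, 13, 11, 12, 1, 1.1, 0.9, 1,     # arg: ~12x
              1, 1.05, 0.95, 1, 4.3, 4.5, 4.4, 4.2),  # glu: ~0.23x
    normalizer = 1)
  out <- fold_change_table(df, "A", "B")
  expect_equal(out$fold_change[out$compound == "arg"], 12, tolerance = 0.01)
  expect_equal(out$fold_change[out$compound == "glu"], 0.229, tolerance = 0.01)
  expect_true(all(out$p_adjusted >= out$p_value))
  expect_error(fold_change_table(df[, 1:2], "A", "B"), "lacks column")
})

test_that("quantitation table switches to c12 mode when ratios are missing", {
  recs <- list(
    abundance_record("M189", "[M+H]+", 10, NA, 1, "s1", "A"),
    abundance_record("M189", "[M+H]+", 12, NA, 1, "s2", "A"),
    abundance_record("M189", "[M+H]+", 5, NA, 1, "s3", "B"),
    abundance_record("M189", "[M+H]+", 6, NA, 1, "s4", "B"),
    abundance_record("M147", "[M+H]+", 10, 5, 1, "s1", "A"),
    abundance_record("M147", "[M+H]+", 12, 6, 1, "s2", "A"),
    abundance_record("M147", "[M+H]+", 4, 8, 1, "s3", "B"),
    abundance_record("M147", "[M+H]+", 5, 10, 1, "s4", "B"))
  out <- quantitation_table(recs, "A", "B")
  expect_identical(out$value_kind[out$spectrum_id == "M189"], "c12_normalized")
  expect_identical(out$value_kind[out$spectrum_id == "M147"],
                   "ratio_normalized")
  expect_equal(out$fold_change[out$spectrum_id == "M147"], 4, tolerance = 1e-9)
  expect_equal(out$fold_change[out$spectrum_id == "M189"], 2, tolerance = 1e-9)
})
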