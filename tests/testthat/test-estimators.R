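test_that("imprecision is the unweighted mean of per-level CVs", {
  flat <- iqc_series("x", "L1", "lot", rep(5, 10))
  expect_equal(estimate_imprecision(flat)$cv_wl, 0)

  # two levels engineered to CVs of exactly 3% and 5%:
  # sd of c(m - d, m + d) is d*sqrt(2), so d = cv/sqrt(2) on a mean of 100
  lvl <- function(cv, id) {
    d <- cv / sqrt(2)  # sd = d*sqrt(2) = cv on mean 100
    iqc_series("x", id, "lot", c(100 - d, 100 + d))
  }
  est <- estimate_imprecision(list(lvl(3, "L1"), lvl(5, "L2")))
  expect_equal(est$per_level$cv, c(3, 5), tolerance = 1e-12)
  expect_equal(est$cv_wl, 4)

  expect_error(estimate_imprecision(list(lvl(3, "L1")), min_n = 3), "L1")
})

test_that("imprecision estimate recovers a true CV of 4.1% at n = 500", {
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    s <- iqc_series("alp", "L1", "lot", rnorm(500, 150, 150 * 0.041))
    abs(estimate_imprecision(s)$cv_wl - 4.1) <= 0.6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("imprecision and bias are invariant under unit rescaling", {
  set.seed(42)
  v <- rnorm(50, 80, 2)
  for (c in c(0.001, 1, 59.48)) {
    expect_equal(estimate_imprecision(iqc_series("x", "L", "l", v * c))$cv_wl,
                 estimate_imprecision(iqc_series("x", "L", "l", v))$cv_wl)
    expect_equal(relative_bias(110 * c, 100 * c), 10)
  }
})

test_that("relative bias is the signed percent deviation", {
  expect_equal(relative_bias(100, 100), 0)
  expect_equal(relative_bias(110, 100), 10)
  expect_equal(relative_bias(90, 100), -10)
  expect_error(relative_bias(1, 0), "> 0")
})

test_that("RMS bias dominates the mean and matches hand values", {
  expect_equal(rms_bias(c(3, -4)), sqrt(12.5))
  expect_equal(rms_bias(-7), 7)
  expect_error(rms_bias(numeric(0)), "no bias items")
  for (seed in 1:25) {
    set.seed(seed)
    b <- rnorm(sample(2:15, 1), sample(-5:5, 1), runif(1, 0, 4))
    expect_gte(rms_bias(b) + 1e-12, abs(mean(b)))
  }
})

test_that("RMS of normal draws concentrates on sqrt(mu^2 + sigma^2)", {
  rms <- vapply(1:300, function(s) {
    set.seed(s); rms_bias(rnorm(13, 8.9, 2))
  }, numeric(1))
  expect_equal(median(rms), sqrt(8.9^2 + 4), tolerance = 0.05)
})

test_that("z-score filter keeps |z| = 2, drops beyond, and is idempotent", {
  z <- c(-2.1, -2, -0.5, 0, 1.99, 2, 2.01, 3.5)
  rounds <- make_pt_rounds(rep(0, length(z)), z = z)
  f <- filter_pt_rounds(rounds)
  expect_identical(vapply(f$kept, `[[`, numeric(1), "z_score"),
                   z[abs(z) <= 2])
  expect_identical(vapply(f$discarded, `[[`, numeric(1), "z_score"),
                   z[abs(z) > 2])
  expect_identical(length(f$kept) + length(f$discarded), length(rounds))
  expect_identical(filter_pt_rounds(f$kept)$kept, f$kept)
})

test_that("missing z-scores are recomputed from peer statistics by default", {
  # deviation of +9% at a 3% peer CV -> z = 3, discarded; +3% -> z = 1, kept
  rounds <- list(pt_round("x", "A", 109, 100, 3, 20, z_score = NA),
                 pt_round("x", "B", 103, 100, 3, 20, z_score = NA))
  f <- filter_pt_rounds(rounds)
  expect_identical(vapply(f$kept, `[[`, character(1), "round_id"), "B")
  expect_error(filter_pt_rounds(rounds, missing_z = "reject"), "z-score")
})

test_that("bias estimation handles the three sources and the NC case", {
  crc <- crc_material("x", "cal", 530, 4, 2, replicates = rep(530, 5))
  be <- estimate_bias(list(crc), "crc")
  expect_equal(be$rms_bias, 0)
  expect_identical(be$n, 1L)

  iqcs <- make_iqcs_rounds(rep(0, 6))
  expect_equal(estimate_bias(iqcs, "iqcs")$rms_bias, 0)

  empty <- estimate_bias(list(), "iqcs")
  expect_identical(empty$status, "NC")
  expect_identical(empty$n, 0L)
})

test_that("PT bias recovery: rms close to truth, and exact at vanishing noise", {
  rms <- vapply(1:50, function(seed) {
    cfg <- simulation_config(true_bias = 5, peer_cv = 3, n_pt_rounds = 13,
                             n_lab = 30, outlier_rate = 0, seed = seed)
    rounds <- filter_pt_rounds(simulate_pt(cfg))$kept
    estimate_bias(rounds, "pt")$rms_bias
  }, numeric(1))
  expect_true(all(rms >= 4 & rms <= 7))

  cfg0 <- simulation_config(true_bias = -3, true_cv_wl = 1e-9, peer_cv = 1e-9,
                            outlier_rate = 0, seed = 9)
  rounds0 <- simulate_pt(cfg0)
  expect_equal(estimate_bias(rounds0, "pt")$rms_bias, 3, tolerance = 1e-5)
})
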