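test_that("the generator is deterministic in its seed", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_lab(cfg)
  b <- simulate_lab(cfg)
  expect_identical(a[c("iqc", "pt", "crc", "iqcs")],
                   b[c("iqc", "pt", "crc", "iqcs")])
  c <- simulate_lab(simulation_config(seed = 124))
  expect_false(identical(a$pt, c$pt))
  # byte-identical files from the same seed
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_pt_csv(a$pt, t1); write_pt_csv(b$pt, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("zero-noise configurations give degenerate, exact data", {
  cfg <- simulation_config(true_cv_wl = 0, true_bias = 0, peer_cv = 1e-12,
                           outlier_rate = 0, seed = 2)
  iqc <- simulate_iqc(cfg)
  expect_true(all(vapply(iqc, function(s) length(unique(s$values)) == 1L,
                         logical(1))))
  crc <- simulate_crc(cfg)
  expect_equal(crc[[1]]$replicates, rep(crc[[1]]$assigned_value,
                                        cfg$n_series_per_crc))
  expect_equal(estimate_bias(crc, "crc")$rms_bias, 0)
  iqcs <- simulate_iqcs(cfg)
  expect_equal(estimate_bias(iqcs, "iqcs")$rms_bias, 0, tolerance = 1e-9)
})

test_that("injected outlier rounds are exactly the ones the z-filter removes", {
  hit <- FALSE
  for (seed in 1:10) {
    cfg <- simulation_config(true_bias = 0, true_cv_wl = 1, outlier_rate = 0.3,
                             seed = seed)
    rounds <- simulate_pt(cfg)
    injected <- attr(rounds, "outlier_rounds")
    f <- filter_pt_rounds(rounds)
    discarded <- match(vapply(f$discarded, `[[`, character(1), "round_id"),
                       vapply(rounds, `[[`, character(1), "round_id"))
    expect_identical(sort(discarded), sort(injected))
    expect_true(all(abs(vapply(rounds[injected], `[[`, numeric(1), "z_score")) > 3))
    if (length(injected)) hit <- TRUE
  }
  expect_true(hit)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(outlier_rate = 1.2), "outlier_rate")
  expect_error(simulation_config(true_cv_wl = -1), "CVs")
  expect_error(simulation_config(n_pt_rounds = -1), "counts")
  expect_error(simulation_config(true_concentrations_per_level = c(80, 0)),
               "> 0")
  expect_error(simulate_pt(simulation_config(n_lab = 0)))
})

test_that("IQCS without duplicates drives the Eurolab cell to ND end-to-end", {
  lab <- simulate_lab(simulation_config(seed = 8, n_iqc_per_level = 40,
                                        n_iqcs_replicates = 0))
  budgets <- build_all_budgets("creatinine", estimate_imprecision(lab$iqc),
                               pt = lab$pt, crc = lab$crc, iqcs = lab$iqcs)
  tab <- budget_table(budgets)
  expect_identical(tab$status[tab$approach == "eurolab" & tab$source == "iqcs"],
                   "ND")
  # the same laboratory without an IQCS peer group: those cells become NC
  budgets2 <- build_all_budgets("ca19-9", estimate_imprecision(lab$iqc),
                                pt = lab$pt, crc = lab$crc, iqcs = NULL)
  tab2 <- budget_table(budgets2)
  expect_identical(sort(tab2$status[tab2$source == "iqcs"]),
                   c("NC", "NC", "ND"))
})

test_that("estimated CV_WL tracks the true CV at n = 1000", {
  hits <- vapply(1:30, function(seed) {
    cfg <- simulation_config(true_cv_wl = 4.1, n_iqc_per_level = 1000,
                             seed = seed)
    est <- estimate_imprecision(simulate_iqc(cfg))$cv_wl
    est >= 3.7 && est <= 4.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
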