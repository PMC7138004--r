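test_that("u(PT) pools per-round standard errors of the assigned value", {
  one <- pt_round("x", "R1", 100, 100, cv_pt = 3, n_lab = 9)
  expect_equal(nordtest_u_pt(list(one)), 1)
  # pooling of identical rounds is independent of how many there are
  expect_equal(nordtest_u_pt(rep(list(one), 7)), 1)
  many <- make_pt_rounds(rep(0, 13), cv_pt = 6.85, n_lab = 10)
  expect_equal(nordtest_u_pt(many), 6.85 / sqrt(10), tolerance = 1e-12)
  expect_equal(nordtest_u_pt(many), 2.1662, tolerance = 1e-4)
  expect_error(nordtest_u_pt(list(pt_round("x", "R", 1, 1, 3, n_lab = 1))),
               "n >= 2")
})

test_that("u(CRC) pools replicate-series CVs; u(Cal_man) converts certificates", {
  flat <- crc_material("x", "c1", 100, 0, 2, replicates = rep(100, 4))
  expect_equal(nordtest_u_crc(list(flat)), 0)
  # CV 2% over 4 replicates -> 1; paired with a zero-CV calibrator -> sqrt(0.5)
  # sample sd of 100 + c(-d, d, -d, d) is 2d/sqrt(3); d = sqrt(3) gives sd 2
  cv2 <- crc_material("x", "c2", 100, 0, 2,
                      replicates = 100 + c(-1, 1, -1, 1) * sqrt(3))
  expect_equal(nordtest_u_crc(list(cv2)), 1, tolerance = 1e-12)
  expect_equal(nordtest_u_crc(list(cv2, flat)), sqrt(0.5), tolerance = 1e-12)

  alp_cal <- crc_material("alp", "cal", 530, 4, 2, replicates = c(525, 535))
  expect_equal(u_cal_man(list(alp_cal)), 100 * 2 / 530, tolerance = 1e-12)
  expect_equal(u_cal_man(list(alp_cal)), 0.377, tolerance = 1e-3)
  expect_error(nordtest_u_crc(list(crc_material("x", "c", 1, 0, 2,
                                                replicates = 1))), "n >= 2")
})

test_that("u(IQCS) follows the same pooling contract", {
  one <- iqcs_round("x", "M1", 100, 100, cv_peer = 7, n_lab = 49)
  expect_equal(nordtest_u_iqcs(list(one)), 1)
  expect_equal(nordtest_u_iqcs(rep(list(one), 6)), 1)
  six <- make_iqcs_rounds(rep(0, 6), cv_peer = 5, n_lab = 50)
  expect_equal(nordtest_u_iqcs(six), sqrt(0.5), tolerance = 1e-12)
})

test_that("Nordtest bias uncertainties are quadratures of their components", {
  expect_equal(nordtest_u_bias_pt(0, 2.5), 2.5)
  expect_equal(nordtest_u_bias_pt(2.5, 0), 2.5)
  expect_equal(nordtest_u_bias_pt(3, 4), 5)
  expect_equal(nordtest_u_bias_pt(8.9, 1.90), 9.1006, tolerance = 1e-4)
  expect_equal(nordtest_u_bias_crc(0, 0, 0.4), 0.4)
  expect_equal(nordtest_u_bias_crc(3.6, 0.3, 0.8), 3.7001, tolerance = 1e-4)
  expect_equal(nordtest_u_bias_iqcs(2.8, 0.76), sqrt(2.8^2 + 0.76^2))
  expect_equal(nordtest_u_bias_iqcs(3, 4), 5)
  expect_error(nordtest_u_bias_pt(-1, 2), ">= 0")
})

test_that("Eurolab adds a replicate term and reduces to Nordtest without one", {
  expect_equal(eurolab_u_bias(3, 4, 0, 1), 5)
  expect_equal(eurolab_u_bias(8.9, 1.9, 5.4, 4),
               sqrt(8.9^2 + 1.9^2 + 2.7^2), tolerance = 1e-12)
  expect_equal(eurolab_u_bias(8.9, 1.9, 5.4, 4), 9.4926, tolerance = 1e-4)
  expect_error(eurolab_u_bias(1, 1, 1, 0), "n_rep")
  # the replicate term strictly increases the result
  expect_gt(eurolab_u_bias(5, 1, 2, 2), eurolab_u_bias(5, 1, 0, 1))
})

test_that("Cofrac combines the uniform half-range with the bias dispersion", {
  expect_equal(cofrac_u_bias(c(4, 4)), 0)
  expect_equal(cofrac_u_bias(c(2, 4, 6)), sqrt((2 / sqrt(3))^2 + 4))
  expect_equal(cofrac_u_bias(c(2, 4, 6)), 2.3094, tolerance = 1e-4)
  expect_equal(cofrac_u_bias(-c(2, 4, 6)), cofrac_u_bias(c(2, 4, 6)))
  expect_error(cofrac_u_bias(5), "at least 2")
})

test_that("combination and expansion follow the quadrature and k scaling", {
  expect_equal(combine_uncertainty(3, 4), 5)
  expect_equal(combine_uncertainty(0, 7), 7)
  expect_equal(combine_uncertainty(9.2, 9.1), 12.9403, tolerance = 1e-4)
  expect_equal(expand_uncertainty(12.9403), 25.8806, tolerance = 1e-4)
  expect_equal(expand_uncertainty(4.653, 2), 9.306)
  expect_equal(expand_uncertainty(3.14, 1), 3.14)
  expect_error(expand_uncertainty(1, 0), "> 0")
})

test_that("budgets carry statuses: fixed ND/NE cells and data-driven NC", {
  imp <- 2.0
  ne <- build_budget("ca19-9", "cofrac", "crc", imp,
                     list(crc_material("ca19-9", "c", 30, 0.51, 2, c(29, 31))))
  expect_identical(ne$status, "NE")
  nd <- build_budget("alp", "eurolab", "iqcs", imp, make_iqcs_rounds(c(1, 2)))
  expect_identical(nd$status, "ND")
  nc <- build_budget("testosterone", "nordtest", "iqcs", imp, list())
  expect_identical(nc$status, "NC")
  expect_true(is.na(nc$u_expanded))
  expect_error(verdict(nc, quality_goals("testosterone", 9, 23, 30.6, 8.8)),
               "NC")
})

test_that("a full synthetic lab yields 7 computed budgets and the 2 fixed statuses", {
  lab <- simulate_lab(simulation_config(seed = 5, n_iqc_per_level = 60))
  imp <- estimate_imprecision(lab$iqc)
  budgets <- build_all_budgets(lab$config$analyte, imp, pt = lab$pt,
                               crc = lab$crc, iqcs = lab$iqcs)
  tab <- budget_table(budgets)
  expect_identical(nrow(tab), 9L)
  expect_identical(sum(tab$status == "computed"), 7L)
  expect_identical(tab$status[tab$approach == "eurolab" & tab$source == "iqcs"],
                   "ND")
  expect_identical(tab$status[tab$approach == "cofrac" & tab$source == "crc"],
                   "NE")
  ok <- tab$status == "computed"
  expect_true(all(tab$u_expanded[ok] == tab$k[ok] * tab$u_combined[ok]))
  expect_true(all(tab$u_combined[ok] >= pmax(tab$cv_wl[ok], tab$u_bias[ok])))
})

test_that("quadrature monotonicity and the Eurolab/Nordtest relations hold", {
  for (seed in 1:20) {
    cfg <- simulation_config(seed = seed, true_bias = runif(1, -6, 6),
                             true_cv_wl = runif(1, 0.5, 8),
                             n_iqc_per_level = 40)
    lab <- simulate_lab(cfg)
    pt <- filter_pt_rounds(lab$pt)$kept
    for (src in c("pt", "crc", "iqcs")) {
      recs <- if (src == "pt") pt else lab[[src]]
      be <- estimate_bias(recs, src)
      for (app in c("nordtest", "eurolab")) {
        ub <- bias_uncertainty(app, src, recs)
        if (ub$status == "computed")
          expect_gte(ub$value + 1e-12, be$rms_bias)
      }
    }
    # Eurolab CRC is identically Nordtest CRC
    expect_equal(bias_uncertainty("eurolab", "crc", lab$crc)$value,
                 bias_uncertainty("nordtest", "crc", lab$crc)$value)
    # Eurolab PT >= Nordtest PT (replicate term adds in quadrature)
    expect_gte(bias_uncertainty("eurolab", "pt", pt)$value + 1e-12,
               bias_uncertainty("nordtest", "pt", pt)$value)
  }
})

test_that("budget percentages are invariant under concentration rescaling", {
  lab <- simulate_lab(simulation_config(seed = 21, n_iqc_per_level = 40))
  scale_pt <- function(r, c) {
    r$lab_result <- r$lab_result * c; r$assigned_value <- r$assigned_value * c
    if (!is.null(r$replicates)) r$replicates <- r$replicates * c
    r
  }
  for (c in c(0.01, 17.3)) {
    b1 <- build_budget("x", "nordtest", "pt", 2, lab$pt)
    b2 <- build_budget("x", "nordtest", "pt", 2, lapply(lab$pt, scale_pt, c = c))
    expect_equal(b2$u_expanded, b1$u_expanded, tolerance = 1e-12)
  }
})
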