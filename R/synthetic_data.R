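# Synthetic QC data with known ground truth. The generator emulates the four
# data streams of a routine clinical-chemistry laboratory -- internal QC
# series, PT round summaries, certified reference calibrator replicates and
# monthly IQCS peer comparisons -- so every estimator and formula can be
# exercised against a known true bias and imprecision.

#' Simulation configuration
#'
#' Defaults describe a creatinine-like analyte under typical verification
#' conditions: two QC levels, long-term CV 2.0%, a persistent method bias of
#' +5.2%, 13 PT rounds of 30 laboratories with 3% peer CV, one certified
#' reference calibrator (724.9 +/- 11.6, k = 2) measured in 10 analytical
#' series, and six monthly IQCS peer comparisons of 49 laboratories.
#'
#' PT samples are measured in duplicate (`n_pt_replicates = 2`), the usual
#' practice in bias investigations and what the Eurolab replicate term needs.
#' The simulated PT provider scores z against a prescribed fitness-for-purpose
#' evaluation SD (`z_eval_cv`, percent of the target; the ISO 13528
#' convention), so `|z| <= 2` corresponds to a deviation within
#' `2 * z_eval_cv`. Set `z_eval_cv = NULL` to score against the observed peer
#' SD instead. Gross errors are injected at `outlier_rate` with |z| > 3.
#'
#' @param analyte,unit Labels.
#' @param true_concentrations_per_level True QC-level concentrations.
#' @param true_cv_wl True within-laboratory CV, percent.
#' @param true_bias True method bias, signed percent.
#' @param n_iqc_per_level IQC results per level.
#' @param n_pt_rounds,n_lab,peer_cv,n_pt_replicates,z_eval_cv PT settings.
#' @param n_crc,crc_assigned_values,crc_expanded_uncertainty,crc_coverage_factor,n_series_per_crc
#'   Calibrator settings (values recycled across `n_crc`).
#' @param n_iqcs_rounds,n_lab_iqcs,n_iqcs_results_per_round,n_iqcs_replicates
#'   IQCS settings; `n_iqcs_replicates = 0` (no duplicates) exercises the
#'   Eurolab "ND" path, as in routine practice.
#' @param outlier_rate Probability that a PT round is a gross error.
#' @param seed Integer seed; fixing it fixes every downstream number.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(analyte = "creatinine", unit = "umol/L",
                              true_concentrations_per_level = c(80, 400),
                              true_cv_wl = 2.0, true_bias = 5.2,
                              n_iqc_per_level = 250L,
                              n_pt_rounds = 13L, n_lab = 30L, peer_cv = 3,
                              n_pt_replicates = 2L, z_eval_cv = 6,
                              n_crc = 1L, crc_assigned_values = 724.9,
                              crc_expanded_uncertainty = 11.6,
                              crc_coverage_factor = 2, n_series_per_crc = 10L,
                              n_iqcs_rounds = 6L, n_lab_iqcs = 49L,
                              n_iqcs_results_per_round = 20L,
                              n_iqcs_replicates = 0L,
                              outlier_rate = 0.05, seed = 1L) {
  cfg <- list(analyte = analyte, unit = unit,
              true_concentrations_per_level = as.numeric(true_concentrations_per_level),
              true_cv_wl = true_cv_wl, true_bias = true_bias,
              n_iqc_per_level = as.integer(n_iqc_per_level),
              n_pt_rounds = as.integer(n_pt_rounds), n_lab = as.integer(n_lab),
              peer_cv = peer_cv, n_pt_replicates = as.integer(n_pt_replicates),
              z_eval_cv = z_eval_cv, n_crc = as.integer(n_crc),
              crc_assigned_values = as.numeric(crc_assigned_values),
              crc_expanded_uncertainty = as.numeric(crc_expanded_uncertainty),
              crc_coverage_factor = crc_coverage_factor,
              n_series_per_crc = as.integer(n_series_per_crc),
              n_iqcs_rounds = as.integer(n_iqcs_rounds),
              n_lab_iqcs = as.integer(n_lab_iqcs),
              n_iqcs_results_per_round = as.integer(n_iqcs_results_per_round),
              n_iqcs_replicates = as.integer(n_iqcs_replicates),
              outlier_rate = outlier_rate, seed = as.integer(seed))
  counts <- c(cfg$n_iqc_per_level, cfg$n_pt_rounds, cfg$n_lab,
              cfg$n_pt_replicates, cfg$n_crc, cfg$n_series_per_crc,
              cfg$n_iqcs_rounds, cfg$n_lab_iqcs, cfg$n_iqcs_replicates)
  if (any(counts < 0L)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$true_cv_wl < 0 || cfg$peer_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]", call. = FALSE)
  if (!is.null(cfg$z_eval_cv) && cfg$z_eval_cv <= 0)
    stop("z_eval_cv must be > 0 (or NULL)", call. = FALSE)
  if (any(cfg$true_concentrations_per_level <= 0))
    stop("level concentrations must be > 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

as_config <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  cfg
}

# Per-source seed offsets keep the four streams independent yet jointly
# reproducible from the one configuration seed.
source_seed <- function(cfg, offset) set.seed(cfg$seed + offset)

#' Simulate internal QC series
#'
#' Each level draws `n_iqc_per_level` results from
#' `Normal(m, m * true_cv_wl / 100)` with `m = level * (1 + true_bias/100)`:
#' the bias shifts the mean but not the CV.
#'
#' @param cfg A [simulation_config()] (or a list of its arguments).
#' @return List of [iqc_series()], one per level.
#' @export
simulate_iqc <- function(cfg) {
  cfg <- as_config(cfg)
  source_seed(cfg, 101L)
  dates <- format(seq(as.Date("2016-01-01"), by = "day",
                      length.out = cfg$n_iqc_per_level))
  lapply(seq_along(cfg$true_concentrations_per_level), function(i) {
    m <- cfg$true_concentrations_per_level[i] * (1 + cfg$true_bias / 100)
    iqc_series(cfg$analyte, paste0("L", i), "lot1",
               stats::rnorm(cfg$n_iqc_per_level, m, m * cfg$true_cv_wl / 100),
               dates)
  })
}

#' Simulate proficiency-test rounds
#'
#' Per round, `n_lab - 1` unbiased peer results are drawn around the true
#' concentration with `peer_cv`; the assigned value and round CV are their
#' consensus statistics. The laboratory's own result is the mean of
#' `n_pt_replicates` draws carrying `true_bias` and `true_cv_wl`. With
#' probability `outlier_rate` the round is turned into a gross error placed
#' at |z| > 3 on the provider's scale.
#'
#' @param cfg A [simulation_config()].
#' @return List of [pt_round()] records; the indices of injected outlier
#'   rounds are in `attr(, "outlier_rounds")`.
#' @export
simulate_pt <- function(cfg) {
  cfg <- as_config(cfg)
  if (cfg$n_lab < 2L) stop("n_lab must be >= 2", call. = FALSE)
  source_seed(cfg, 202L)
  tc <- cfg$true_concentrations_per_level[1L]
  outliers <- integer(0)
  rounds <- lapply(seq_len(cfg$n_pt_rounds), function(r) {
    peers <- stats::rnorm(cfg$n_lab - 1L, tc, tc * cfg$peer_cv / 100)
    assigned <- mean(peers)
    sd_peer <- stats::sd(peers)
    m <- tc * (1 + cfg$true_bias / 100)
    reps <- stats::rnorm(cfg$n_pt_replicates, m, m * cfg$true_cv_wl / 100)
    lab <- mean(reps)
    z_scale <- if (is.null(cfg$z_eval_cv)) sd_peer else
      assigned * cfg$z_eval_cv / 100
    if (stats::runif(1L) < cfg$outlier_rate) {
      target <- assigned + sample(c(-1, 1), 1L) * (3.2 + stats::rexp(1L)) * z_scale
      reps <- reps + (target - lab)
      lab <- target
      outliers <<- c(outliers, r)
    }
    pt_round(cfg$analyte, sprintf("R%02d", r), lab, assigned,
             cv_pt = 100 * sd_peer / assigned, n_lab = cfg$n_lab,
             z_score = (lab - assigned) / z_scale,
             replicates = if (cfg$n_pt_replicates >= 2L) reps else NULL)
  })
  attr(rounds, "outlier_rounds") <- outliers
  rounds
}

#' Simulate certified reference calibrator measurements
#'
#' Each calibrator's replicate series are drawn around
#' `assigned * (1 + true_bias/100)` with `true_cv_wl`.
#'
#' @param cfg A [simulation_config()].
#' @return List of [crc_material()] records.
#' @export
simulate_crc <- function(cfg) {
  cfg <- as_config(cfg)
  source_seed(cfg, 303L)
  assigned <- rep_len(cfg$crc_assigned_values, cfg$n_crc)
  uexp <- rep_len(cfg$crc_expanded_uncertainty, cfg$n_crc)
  lapply(seq_len(cfg$n_crc), function(j) {
    m <- assigned[j] * (1 + cfg$true_bias / 100)
    crc_material(cfg$analyte, paste0("CAL", j), assigned[j], uexp[j],
                 cfg$crc_coverage_factor,
                 replicates = stats::rnorm(cfg$n_series_per_crc, m,
                                           m * cfg$true_cv_wl / 100))
  })
}

#' Simulate IQCS peer-comparison rounds
#'
#' Per month, `n_lab_iqcs` unbiased peer-laboratory means are drawn with
#' `peer_cv`; the peer mean and CV are their consensus statistics. The
#' laboratory's monthly mean carries the bias, with imprecision shrunk by the
#' `n_iqcs_results_per_round` results behind it. Replicates are attached only
#' when `n_iqcs_replicates >= 2`, so the default exercises the Eurolab
#' no-duplicates path.
#'
#' @param cfg A [simulation_config()].
#' @return List of [iqcs_round()] records.
#' @export
simulate_iqcs <- function(cfg) {
  cfg <- as_config(cfg)
  source_seed(cfg, 404L)
  tc <- cfg$true_concentrations_per_level[1L]
  lapply(seq_len(cfg$n_iqcs_rounds), function(r) {
    peers <- stats::rnorm(cfg$n_lab_iqcs, tc, tc * cfg$peer_cv / 100)
    m <- tc * (1 + cfg$true_bias / 100)
    lab_mean <- stats::rnorm(1L, m, m * cfg$true_cv_wl / 100 /
                                    sqrt(cfg$n_iqcs_results_per_round))
    reps <- if (cfg$n_iqcs_replicates >= 2L)
      stats::rnorm(cfg$n_iqcs_replicates, m, m * cfg$true_cv_wl / 100) else NULL
    iqcs_round(cfg$analyte, sprintf("M%02d", r), lab_mean, mean(peers),
               cv_peer = 100 * stats::sd(peers) / mean(peers),
               n_lab = cfg$n_lab_iqcs, replicates = reps)
  })
}

#' Simulate a complete laboratory dataset
#'
#' All four QC data streams from one configuration.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `iqc`, `pt`, `crc`, `iqcs` and the `config`.
#' @examples
#' lab <- simulate_lab(simulation_config(seed = 7))
#' length(lab$pt)
#' @export
simulate_lab <- function(cfg) {
  cfg <- as_config(cfg)
  list(iqc = simulate_iqc(cfg), pt = simulate_pt(cfg),
       crc = simulate_crc(cfg), iqcs = simulate_iqcs(cfg), config = cfg)
}
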