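# The three bias-uncertainty formulations and the combined/expanded
# uncertainty. Everything is on the percent scale.

quadrature <- function(...) {
  x <- c(...)
  if (any(x < 0)) stop("quadrature terms must be >= 0", call. = FALSE)
  sqrt(sum(x^2))
}

# RMS pooling of per-item standard-error terms: sqrt(mean(cv_i^2 / n_i)).
# Chosen over the plain arithmetic mean of cv_i/sqrt(n_i) for consistency
# with the RMS style of the bias aggregation and quadrature propagation; the
# two differ by less than reporting precision for homogeneous rounds.
pooled_se <- function(cv, n, what = "item") {
  if (length(cv) == 0L) stop("no ", what, "s", call. = FALSE)
  if (any(n < 2)) stop("every ", what, " needs n >= 2", call. = FALSE)
  if (any(cv < 0)) stop("CVs must be >= 0", call. = FALSE)
  sqrt(mean(cv^2 / n))
}

#' Nordtest uncertainty of the PT assigned value, u(PT)
#'
#' Pools the standard errors of the peer-consensus assigned values over the
#' PT rounds: `sqrt(mean(cv_pt_i^2 / n_lab_i))`, where `cv_pt_i` is the peer
#' CV of round i and `n_lab_i` its number of participating laboratories.
#'
#' @param rounds Non-empty list of (filtered) [pt_round()] records.
#' @return u(PT), percent.
#' @examples
#' r <- pt_round("alp", "R1", 100, 100, cv_pt = 3, n_lab = 9)
#' nordtest_u_pt(list(r))  # 1
#' @export
nordtest_u_pt <- function(rounds) {
  if (inherits(rounds, "pt_round")) rounds <- list(rounds)
  pooled_se(vapply(rounds, `[[`, numeric(1L), "cv_pt"),
            vapply(rounds, `[[`, numeric(1L), "n_lab"), "PT round")
}

#' Nordtest uncertainty components from certified reference calibrators
#'
#' `nordtest_u_crc()` pools the replicate-series CV of each calibrator over
#' its number of measurements: `sqrt(mean(cv_crc_j^2 / n_m_j))`.
#' `u_cal_man()` converts each certificate's expanded uncertainty to a
#' relative standard uncertainty, `100 * (U_cal / k_cal) / assigned`, and
#' combines several calibrators as an RMS.
#'
#' @param crcs Non-empty list of [crc_material()] records, each with at least
#'   two replicate series.
#' @return Percent standard uncertainty.
#' @examples
#' crc <- crc_material("alp", "cal", 530, 4, 2, replicates = c(528, 545, 537, 531))
#' u_cal_man(list(crc))  # 100 * (4/2) / 530 = 0.377
#' @export
nordtest_u_crc <- function(crcs) {
  if (inherits(crcs, "crc_material")) crcs <- list(crcs)
  cv <- vapply(crcs, function(m)
    100 * stats::sd(m$replicates) / mean(m$replicates), numeric(1L))
  pooled_se(cv, vapply(crcs, `[[`, numeric(1L), "n_m"), "CRC")
}

#' @rdname nordtest_u_crc
#' @export
u_cal_man <- function(crcs) {
  if (inherits(crcs, "crc_material")) crcs <- list(crcs)
  u <- vapply(crcs, function(m)
    100 * (m$expanded_uncertainty / m$coverage_factor) / m$assigned_value,
    numeric(1L))
  sqrt(mean(u^2))
}

#' Nordtest uncertainty of the IQCS peer mean, u(IQCS)
#'
#' Same pooling contract as [nordtest_u_pt()], applied to the monthly
#' peer-comparison CVs and group sizes.
#'
#' @param rounds Non-empty list of [iqcs_round()] records.
#' @return u(IQCS), percent.
#' @export
nordtest_u_iqcs <- function(rounds) {
  if (inherits(rounds, "iqcs_round")) rounds <- list(rounds)
  pooled_se(vapply(rounds, `[[`, numeric(1L), "cv_peer"),
            vapply(rounds, `[[`, numeric(1L), "n_lab"), "IQCS round")
}

#' Nordtest bias uncertainty
#'
#' Quadrature of the RMS bias with the uncertainty of the target value --
#' and, for calibrators, additionally with the manufacturer's calibrator
#' uncertainty: `u(Bias) = sqrt(rms^2 + u_target^2 [+ u_cal^2])`.
#'
#' @param rms RMS bias, percent (>= 0).
#' @param u_pt,u_iqcs,u_crc Target-value uncertainty of the source, percent.
#' @param u_cal Relative standard uncertainty of the calibrator certificates
#'   ([u_cal_man()]), percent.
#' @return u(Bias), percent.
#' @examples
#' nordtest_u_bias_pt(3, 4)  # 5
#' @export
nordtest_u_bias_pt <- function(rms, u_pt) quadrature(rms, u_pt)

#' @rdname nordtest_u_bias_pt
#' @export
nordtest_u_bias_crc <- function(rms, u_crc, u_cal) quadrature(rms, u_crc, u_cal)

#' @rdname nordtest_u_bias_pt
#' @export
nordtest_u_bias_iqcs <- function(rms, u_iqcs) quadrature(rms, u_iqcs)

#' Eurolab bias uncertainty
#'
#' Combines the bias deviation, the uncertainty of the target value and the
#' imprecision of the mean of the replicate measurements performed in the
#' bias investigation:
#' `sqrt(bias^2 + u_target^2 + (cv_rep / sqrt(n_rep))^2)`.
#' With several rounds the bias term is the RMS bias by default (`"mean"`
#' uses the absolute mean deviation instead). For calibrator data Eurolab
#' uses the same formula as Nordtest ([nordtest_u_bias_crc()]), so the two
#' agree exactly there.
#'
#' @param bias_term RMS (or mean) bias, percent.
#' @param u_target Uncertainty of the target value (u(PT), u(IQCS) or the
#'   calibrator target uncertainty), percent.
#' @param cv_rep CV among the replicate measurements, percent.
#' @param n_rep Number of replicate measurements; >= 1.
#' @return u(Bias), percent.
#' @examples
#' eurolab_u_bias(3, 4, 0, 1)  # 5
#' @export
eurolab_u_bias <- function(bias_term, u_target, cv_rep = 0, n_rep = 1L) {
  if (n_rep < 1L) stop("n_rep must be >= 1", call. = FALSE)
  quadrature(bias_term, u_target, cv_rep / sqrt(n_rep))
}

#' Cofrac bias uncertainty
#'
#' From the spread of the individual biases alone: the half-range of the
#' biases under a uniform-distribution assumption (half-range / sqrt(3))
#' combined with their dispersion:
#' `sqrt(((max - min) / 2 / sqrt(3))^2 + s_bias^2)`.
#' The dispersion term is the sample SD of the biases in percentage points; a
#' literal CV of signed, near-zero biases would be unstable.
#'
#' @param biases Numeric vector of signed percent biases, length >= 2.
#' @return u(Bias), percent.
#' @examples
#' cofrac_u_bias(c(2, 4, 6))  # sqrt((2/sqrt(3))^2 + 2^2)
#' @export
cofrac_u_bias <- function(biases) {
  if (length(biases) < 2L)
    stop("at least 2 bias items needed (half-range undefined)", call. = FALSE)
  half_range <- (max(biases) - min(biases)) / 2
  quadrature(half_range / sqrt(3), stats::sd(biases))
}

#' Combined and expanded uncertainty
#'
#' `combine_uncertainty()` merges imprecision and bias uncertainty in
#' quadrature, `u_c = sqrt(cv_wl^2 + u_bias^2)`; `expand_uncertainty()`
#' applies the coverage factor, `U = k * u_c` (k = 2 for ~95% coverage).
#'
#' @param cv_wl Within-laboratory CV, percent.
#' @param u_bias Bias uncertainty, percent.
#' @param u_c Combined standard uncertainty, percent.
#' @param k Coverage factor; > 0.
#' @return Percent uncertainty.
#' @examples
#' expand_uncertainty(combine_uncertainty(3, 4))  # 10
#' @export
combine_uncertainty <- function(cv_wl, u_bias) quadrature(cv_wl, u_bias)

#' @rdname combine_uncertainty
#' @export
expand_uncertainty <- function(u_c, k = 2) {
  if (u_c < 0) stop("u_c must be >= 0", call. = FALSE)
  if (k <= 0) stop("coverage factor must be > 0", call. = FALSE)
  k * u_c
}

new_budget <- function(analyte, approach, source, status, cv_wl = NA_real_,
                       u_bias = NA_real_, k = NA_real_, components = list(),
                       bias = NA_real_, n = NA_integer_) {
  u_c <- if (status == "computed") combine_uncertainty(cv_wl, u_bias) else NA_real_
  structure(list(analyte = analyte, approach = approach, source = source,
                 status = status, cv_wl = cv_wl, bias = bias, u_bias = u_bias,
                 u_combined = u_c, coverage_factor_k = k,
                 u_expanded = if (status == "computed") expand_uncertainty(u_c, k) else NA_real_,
                 n = n, components = components),
            class = "mu_budget")
}

#' Bias uncertainty for one approach x source cell
#'
#' Dispatches to the Nordtest, Eurolab or Cofrac formula for one data source,
#' returning the value together with its availability status and all
#' intermediate components. Cells the formula does not cover return a status
#' record -- `"ND"` (Eurolab with IQCS: no duplicate results), `"NE"` (Cofrac
#' with CRC: no bias term) -- and an empty source returns `"NC"` (no peer
#' group).
#'
#' @param approach,source Cell coordinates (see [mu_approaches()]).
#' @param records Source records, already PT-filtered where applicable.
#' @param eurolab_bias_term `"rms"` (default) or `"mean"`: the bias deviation
#'   used in the Eurolab formula.
#' @return An object of class `bias_uncertainty`: `value` (percent or `NA`),
#'   `status`, `components`.
#' @export
bias_uncertainty <- function(approach, source, records,
                             eurolab_bias_term = c("rms", "mean")) {
  approach <- match_approach(approach)
  source <- match_source(source)
  eurolab_bias_term <- match.arg(eurolab_bias_term)
  out <- function(value, status, components = list(), bias = NULL)
    structure(list(approach = approach, source = source, value = value,
                   status = status, components = components,
                   bias = if (is.null(bias)) NULL else bias),
              class = "bias_uncertainty")
  st <- applicability(approach, source)
  if (st != "computed") return(out(NA_real_, st))
  if (is.null(records) || length(records) == 0L) return(out(NA_real_, "NC"))
  be <- estimate_bias(records, source)
  if (approach == "nordtest" || (approach == "eurolab" && source == "crc")) {
    if (source == "pt") {
      u_pt <- nordtest_u_pt(records)
      return(out(nordtest_u_bias_pt(be$rms_bias, u_pt), "computed",
                 list(rms_bias = be$rms_bias, u_pt = u_pt), be))
    }
    if (source == "crc") {
      u_crc <- nordtest_u_crc(records)
      u_cal <- u_cal_man(records)
      return(out(nordtest_u_bias_crc(be$rms_bias, u_crc, u_cal), "computed",
                 list(rms_bias = be$rms_bias, u_crc = u_crc, u_cal_man = u_cal),
                 be))
    }
    u_iqcs <- nordtest_u_iqcs(records)
    return(out(nordtest_u_bias_iqcs(be$rms_bias, u_iqcs), "computed",
               list(rms_bias = be$rms_bias, u_iqcs = u_iqcs), be))
  }
  if (approach == "eurolab") {  # source == "pt"
    u_target <- nordtest_u_pt(records)
    reps <- Filter(function(r) !is.null(r$replicates) && length(r$replicates) >= 2L,
                   records)
    rep_term <- if (length(reps)) {
      terms <- vapply(reps, function(r) {
        cv <- 100 * stats::sd(r$replicates) / mean(r$replicates)
        cv^2 / length(r$replicates)
      }, numeric(1L))
      sqrt(mean(terms))
    } else 0
    bias_term <- if (eurolab_bias_term == "rms") be$rms_bias else abs(be$mean_bias)
    return(out(quadrature(bias_term, u_target, rep_term), "computed",
               list(bias_term = bias_term, u_pt = u_target,
                    replicate_term = rep_term,
                    bias_term_mode = eurolab_bias_term), be))
  }
  # cofrac, pt or iqcs
  b <- be$per_item$bias
  half_range <- (max(b) - min(b)) / 2
  out(cofrac_u_bias(b), "computed",
      list(half_range_term = half_range / sqrt(3), sd_bias_term = stats::sd(b)),
      be)
}

#' Assemble an uncertainty budget
#'
#' Runs one approach x source cell end to end: PT filtering (unless already
#' done), bias estimation, the approach's bias-uncertainty formula, and the
#' combination and expansion with imprecision. Cells that cannot be computed
#' come back as status records (`"NC"`, `"ND"`, `"NE"`) with the numeric
#' fields `NA`.
#'
#' @param analyte Analyte name.
#' @param approach,source Cell coordinates.
#' @param imprecision An `imprecision_estimate` (or the CV_WL as a number).
#' @param records Source records.
#' @param k Coverage factor, default 2.
#' @param pre_filtered Set `TRUE` when PT rounds have already been through
#'   [filter_pt_rounds()].
#' @param eurolab_bias_term Passed to [bias_uncertainty()].
#' @return An object of class `mu_budget`.
#' @export
build_budget <- function(analyte, approach, source, imprecision, records,
                         k = 2, pre_filtered = FALSE,
                         eurolab_bias_term = c("rms", "mean")) {
  approach <- match_approach(approach)
  source <- match_source(source)
  cv_wl <- if (inherits(imprecision, "imprecision_estimate"))
    imprecision$cv_wl else as.numeric(imprecision)
  if (source == "pt" && !pre_filtered && length(records))
    records <- filter_pt_rounds(records)$kept
  ub <- bias_uncertainty(approach, source, records,
                         eurolab_bias_term = eurolab_bias_term)
  if (ub$status != "computed")
    return(new_budget(analyte, approach, source, ub$status, cv_wl = cv_wl, k = k))
  new_budget(analyte, approach, source, "computed", cv_wl = cv_wl,
             u_bias = ub$value, k = k, components = ub$components,
             bias = ub$bias$rms_bias, n = ub$bias$n)
}

#' Budgets for the full approach x source matrix of one analyte
#'
#' @param analyte Analyte name.
#' @param imprecision An `imprecision_estimate` or CV_WL value.
#' @param pt,crc,iqcs Source record lists (`NULL` or empty when the
#'   laboratory has no such data; those cells become `"NC"` where otherwise
#'   computable).
#' @param k Coverage factor.
#' @param eurolab_bias_term Passed through.
#' @return A list of 9 `mu_budget` objects (class `mu_budget_list`): 7
#'   computable cells plus the fixed `"ND"`/`"NE"` cells; see
#'   [budget_table()] to flatten.
#' @export
build_all_budgets <- function(analyte, imprecision, pt = NULL, crc = NULL,
                              iqcs = NULL, k = 2,
                              eurolab_bias_term = c("rms", "mean")) {
  if (!is.null(pt) && length(pt)) pt <- filter_pt_rounds(pt)$kept
  grid <- applicability_matrix()
  budgets <- mapply(function(a, s) {
    build_budget(analyte, a, s, imprecision,
                 switch(s, pt = pt, crc = crc, iqcs = iqcs),
                 k = k, pre_filtered = TRUE,
                 eurolab_bias_term = eurolab_bias_term)
  }, grid$approach, grid$source, SIMPLIFY = FALSE)
  structure(budgets, class = "mu_budget_list")
}

#' Flatten budgets to a data frame
#'
#' @param budgets A `mu_budget`, a `mu_budget_list`, or a plain list of
#'   budgets (possibly across analytes).
#' @return A data frame with one row per approach x source cell: `analyte`,
#'   `approach`, `source`, `status`, `bias`, `u_bias`, `cv_wl`, `u_combined`,
#'   `k`, `u_expanded`, `n`.
#' @export
budget_table <- function(budgets) {
  if (inherits(budgets, "mu_budget")) budgets <- list(budgets)
  rows <- lapply(budgets, function(b)
    data.frame(analyte = b$analyte, approach = b$approach, source = b$source,
               status = b$status, bias = b$bias, u_bias = b$u_bias,
               cv_wl = b$cv_wl, u_combined = b$u_combined,
               k = b$coverage_factor_k, u_expanded = b$u_expanded,
               n = b$n, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mu_budget <- function(x, ...) {
  cat(sprintf("<mu_budget> %s | %s x %s | %s\n", x$analyte,
              display_label(x$approach), display_label(x$source), x$status))
  if (x$status == "computed")
    cat(sprintf("  CV_WL %.2f%%  u(Bias) %.2f%%  u_c %.2f%%  U (k=%g) %.2f%%\n",
                x$cv_wl, x$u_bias, x$u_combined, x$coverage_factor_k,
                x$u_expanded))
  invisible(x)
}
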