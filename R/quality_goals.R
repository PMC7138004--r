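# Analytical quality goals: Westgard allowable total error from biological
# variation, observed analytical total error, and the Haeckel-style
# permissible uncertainty derived from the reference interval.

# Permissible-uncertainty power laws. The underlying non-linear relation
# between the reference-interval width and the permissible limit is published
# only as input -> output pairs at this precision; these constants are
# calibrated (least squares in log space) to four such pairs:
#   creatinine 44-97        -> 10.6 / 17.3
#   testosterone 8.8-30.6   -> 13.1 / 21.6
#   ALP  <128 (LL = 15% UL) -> 16.0 / 26.2
#   CA 19-9 <37 (LL = 15% UL) -> 16.0 / 26.2
# and reproduce all of them within 0.2 percentage points.
.haeckel <- list(a_u = 2.772328, b_u = 0.4451984,
                 a_pt = 4.487075, b_pt = 0.4488929)

#' Biological variation of an analyte
#'
#' Within-subject (CV_I) and between-subject (CV_G) biological variation,
#' both percent. These are user-supplied inputs -- the package bundles no
#' biological-variation database, because database versions drift.
#'
#' @param analyte Analyte name.
#' @param cv_i Within-subject CV, percent; > 0.
#' @param cv_g Between-subject CV, percent; > 0.
#' @return An object of class `biological_variation`.
#' @export
biological_variation <- function(analyte, cv_i, cv_g) {
  if (!isTRUE(cv_i > 0) || !isTRUE(cv_g > 0))
    stop("cv_i and cv_g must be > 0", call. = FALSE)
  structure(list(analyte = analyte, cv_i = cv_i, cv_g = cv_g),
            class = "biological_variation")
}

#' Westgard allowable total error (desirable goal)
#'
#' `TEa = z * (0.5 * CV_I) + 0.25 * sqrt(CV_I^2 + CV_G^2)` with z = 1.65
#' (95% one-sided confidence).
#'
#' @param bv A [biological_variation()] object, or CV_I as a number.
#' @param cv_g Between-subject CV when `bv` is numeric.
#' @param z Confidence multiplier, default 1.65.
#' @return Allowable total error, percent.
#' @examples
#' allowable_total_error(6, 8)  # 1.65*3 + 0.25*10 = 7.45
#' @export
allowable_total_error <- function(bv, cv_g = NULL, z = 1.65) {
  if (inherits(bv, "biological_variation")) {
    cv_i <- bv$cv_i; cv_g <- bv$cv_g
  } else {
    cv_i <- bv
    if (is.null(cv_g)) stop("cv_g required", call. = FALSE)
  }
  if (cv_i < 0 || cv_g < 0) stop("biological variation must be >= 0", call. = FALSE)
  z * (0.5 * cv_i) + 0.25 * sqrt(cv_i^2 + cv_g^2)
}

#' Observed analytical total error
#'
#' The standard linear total-error model, `TE = |bias| + z * CV_WL`. Which
#' bias source to use (PT, CRC or IQCS) is the caller's choice and is passed
#' explicitly.
#'
#' @param bias Observed bias, signed percent (absolute value is taken).
#' @param cv_wl Within-laboratory CV, percent.
#' @param z Confidence multiplier, default 1.65.
#' @return Total error, percent.
#' @export
analytical_total_error <- function(bias, cv_wl, z = 1.65) {
  if (cv_wl < 0) stop("cv_wl must be >= 0", call. = FALSE)
  abs(bias) + z * cv_wl
}

#' Permissible measurement uncertainty from the reference interval
#'
#' Maps the width of the reference interval through a non-linear permissible-
#' limit function. The empirical reference-interval CV assumes the interval
#' spans the central 95% of a log-normal population:
#' `s = ln(UL/LL) / 3.92`, `CV_E = 100 * sqrt(exp(s^2) - 1)`. Two companion
#' limits are returned: the permissible expanded uncertainty for routine
#' results and the wider permissible uncertainty applied to single PT
#' results. Both depend on the limits only through their ratio, so they are
#' invariant under unit rescaling. When the lower limit is unknown it is set
#' to 15% of the upper limit.
#'
#' @param spec An [analyte_spec()], or the upper reference limit as a number.
#' @param lower_rl Lower reference limit when `spec` is numeric; `NULL` to
#'   apply the 15% rule.
#' @return A list: `cv_empirical`, `permissible_u`, `permissible_u_pt`
#'   (all percent).
#' @examples
#' permissible_uncertainty(97, 44)   # creatinine: ~10.6 / ~17.3
#' permissible_uncertainty(128)      # ALP, lower limit by the 15% rule
#' @export
permissible_uncertainty <- function(spec, lower_rl = NULL) {
  if (inherits(spec, "analyte_spec")) {
    ul <- spec$upper_reference_limit
    ll <- spec$lower_reference_limit
  } else {
    ul <- spec; ll <- lower_rl
  }
  if (is.null(ul) || is.na(ul)) stop("upper reference limit required", call. = FALSE)
  if (is.null(ll) || is.na(ll) || ll <= 0) ll <- 0.15 * ul
  if (ll >= ul) stop("lower limit must be below the upper limit", call. = FALSE)
  s <- log(ul / ll) / 3.92
  cv_e <- 100 * sqrt(exp(s^2) - 1)
  list(cv_empirical = cv_e,
       permissible_u = .haeckel$a_u * cv_e^.haeckel$b_u,
       permissible_u_pt = .haeckel$a_pt * cv_e^.haeckel$b_pt)
}

#' Quality-goal bundle for an analyte
#'
#' @param analyte Analyte name.
#' @param cv_i,cv_g Biological variation, percent.
#' @param upper_rl,lower_rl Reference limits (lower may be `NULL`).
#' @param z Confidence multiplier for the total-error goal.
#' @return An object of class `quality_goals` with `allowable_te`,
#'   `permissible_u`, `permissible_u_pt`.
#' @export
quality_goals <- function(analyte, cv_i, cv_g, upper_rl, lower_rl = NULL,
                          z = 1.65) {
  pu <- permissible_uncertainty(upper_rl, lower_rl)
  structure(list(analyte = analyte,
                 allowable_te = allowable_total_error(cv_i, cv_g, z = z),
                 permissible_u = pu$permissible_u,
                 permissible_u_pt = pu$permissible_u_pt,
                 cv_empirical = pu$cv_empirical),
            class = "quality_goals")
}

#' Judge a budget against the quality goals
#'
#' Flags whether the expanded uncertainty meets the permissible uncertainty
#' and the allowable total error, and (when an observed total error is
#' supplied) whether the analytical total error meets its allowable goal.
#' Margins are goal minus value: negative means the goal is missed.
#'
#' @param budget A computed `mu_budget`, or the expanded uncertainty as a
#'   number.
#' @param goals A [quality_goals()] object.
#' @param analytical_te Optional observed total error, percent.
#' @return Data frame with one row per check: `check`, `value`, `goal`,
#'   `margin`, `pass`.
#' @export
verdict <- function(budget, goals, analytical_te = NULL) {
  u <- if (inherits(budget, "mu_budget")) {
    if (budget$status != "computed")
      stop("cannot judge a ", budget$status, " status record", call. = FALSE)
    budget$u_expanded
  } else as.numeric(budget)
  rows <- data.frame(
    check = c("expanded_u_vs_permissible_u", "expanded_u_vs_allowable_te"),
    value = c(u, u),
    goal = c(goals$permissible_u, goals$allowable_te),
    stringsAsFactors = FALSE)
  if (!is.null(analytical_te))
    rows <- rbind(rows, data.frame(check = "analytical_te_vs_allowable_te",
                                   value = analytical_te,
                                   goal = goals$allowable_te,
                                   stringsAsFactors = FALSE))
  rows$margin <- rows$goal - rows$value
  rows$pass <- rows$value <= rows$goal
  rows
}
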