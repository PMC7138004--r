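#' Within-laboratory imprecision (CV_WL)
#'
#' Long-term intermediate precision from internal QC series. Each control
#' level contributes a CV (100 x sample SD / mean, n-1 denominator); the
#' imprecision of the analyte, CV_WL, is the unweighted arithmetic mean of
#' the per-level CVs.
#'
#' @param series A list of [iqc_series()] records, a single record, or a long
#'   data frame with columns `analyte`, `level_id`, `value`.
#' @param min_n Minimum number of results required per level. Two results are
#'   the mathematical minimum; long-term estimates are typically based on
#'   hundreds of results per level.
#' @return An object of class `imprecision_estimate`: the analyte, a
#'   `per_level` data frame (`level_id`, `n`, `mean`, `sd`, `cv`) and the
#'   scalar `cv_wl` (percent).
#' @examples
#' s1 <- iqc_series("alp", "L1", "lot1", c(98, 101, 100, 99))
#' s2 <- iqc_series("alp", "L2", "lot1", c(300, 306, 297, 303))
#' estimate_imprecision(list(s1, s2))$cv_wl
#' @export
estimate_imprecision <- function(series, min_n = 2L) {
  if (inherits(series, "iqc_series")) series <- list(series)
  if (is.data.frame(series)) {
    series <- lapply(split(series, series$level_id), function(d)
      iqc_series(d$analyte[1L], d$level_id[1L],
                 if ("lot_id" %in% names(d)) d$lot_id[1L] else "NA", d$value))
  }
  stopifnot(length(series) >= 1L)
  per <- lapply(series, function(s) {
    n <- length(s$values)
    if (n < min_n)
      stop("level '", s$level_id, "' has ", n, " results; at least ", min_n,
           " required", call. = FALSE)
    m <- mean(s$values)
    if (m <= 0) stop("level '", s$level_id, "' has non-positive mean", call. = FALSE)
    data.frame(level_id = s$level_id, n = n, mean = m,
               sd = stats::sd(s$values), cv = 100 * stats::sd(s$values) / m,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(analyte = series[[1L]]$analyte, per_level = per,
                 cv_wl = mean(per$cv)),
            class = "imprecision_estimate")
}

#' Relative bias, percent
#'
#' `100 * (measured - expected) / expected`. Vectorised; scale invariant.
#'
#' @param measured Measured value(s).
#' @param expected Assigned / target value(s); > 0.
#' @return Signed percent deviation.
#' @examples
#' relative_bias(110, 100)  # 10
#' @export
relative_bias <- function(measured, expected) {
  if (any(expected <= 0)) stop("expected value must be > 0", call. = FALSE)
  100 * (measured - expected) / expected
}

#' Root mean square of bias values
#'
#' `sqrt(sum(b_i^2) / n)` over the individual per-round or per-calibrator
#' biases. Always at least as large as the absolute mean bias.
#'
#' @param biases Non-empty numeric vector of signed percent biases.
#' @return RMS bias, percent.
#' @examples
#' rms_bias(c(3, -4))  # sqrt(12.5)
#' @export
rms_bias <- function(biases) {
  if (length(biases) == 0L) stop("no bias items", call. = FALSE)
  sqrt(mean(biases^2))
}

#' Filter PT rounds on the z-score acceptance rule
#'
#' Only satisfactory PT results are used for bias estimation: rounds with
#' z-scores > 2 or < -2 are discarded. The boundary |z| = 2 is kept. Rounds
#' missing a provider z-score are, by default, rescored from the peer
#' statistics as `(lab_result - assigned_value) / (assigned_value * cv_pt /
#' 100)`; in strict mode they are rejected.
#'
#' @param rounds List of [pt_round()] records.
#' @param missing_z `"recompute"` (default) or `"reject"`.
#' @return A list with components `kept` and `discarded`, an exhaustive and
#'   disjoint partition of `rounds`. Applying the filter to `kept` again is a
#'   no-op.
#' @export
filter_pt_rounds <- function(rounds, missing_z = c("recompute", "reject")) {
  missing_z <- match.arg(missing_z)
  if (inherits(rounds, "pt_round")) rounds <- list(rounds)
  z <- vapply(rounds, function(r) {
    if (is.na(r$z_score)) {
      if (missing_z == "reject")
        stop("round '", r$round_id, "' has no z-score", call. = FALSE)
      if (r$cv_pt <= 0)
        stop("round '", r$round_id, "': cannot recompute z with cv_pt <= 0",
             call. = FALSE)
      (r$lab_result - r$assigned_value) / (r$assigned_value * r$cv_pt / 100)
    } else r$z_score
  }, numeric(1L))
  keep <- abs(z) <= 2
  list(kept = rounds[keep], discarded = rounds[!keep])
}

#' Estimate bias from one QC data source
#'
#' Computes the individual relative biases -- one per PT round (lab result vs
#' peer assigned value), per calibrator (mean of its replicate series vs the
#' certified value) or per IQCS peer comparison (lab monthly mean vs peer
#' mean) -- and aggregates them as the RMS bias. PT rounds should be passed
#' through [filter_pt_rounds()] first.
#'
#' @param records List of source records (all of one type).
#' @param source `"pt"`, `"crc"` or `"iqcs"`.
#' @return An object of class `bias_estimate` with `per_item` (data frame
#'   `item_id`, `bias`), `rms_bias`, `mean_bias`, `n` and `status`
#'   (`"computed"`, or `"NC"` for an empty source -- no peer group).
#' @export
estimate_bias <- function(records, source = c("pt", "crc", "iqcs")) {
  source <- match.arg(source)
  if (inherits(records, c("pt_round", "crc_material", "iqcs_round")))
    records <- list(records)
  if (is.null(records) || length(records) == 0L) {
    return(structure(list(analyte = NA_character_, source = source,
                          per_item = data.frame(item_id = character(),
                                                bias = numeric()),
                          rms_bias = NA_real_, mean_bias = NA_real_, n = 0L,
                          status = "NC"),
                     class = "bias_estimate"))
  }
  per <- switch(source,
    pt = data.frame(
      item_id = vapply(records, `[[`, character(1L), "round_id"),
      bias = vapply(records, function(r)
        relative_bias(r$lab_result, r$assigned_value), numeric(1L)),
      stringsAsFactors = FALSE),
    crc = data.frame(
      item_id = vapply(records, `[[`, character(1L), "calibrator_id"),
      bias = vapply(records, function(r)
        relative_bias(mean(r$replicates), r$assigned_value), numeric(1L)),
      stringsAsFactors = FALSE),
    iqcs = data.frame(
      item_id = vapply(records, `[[`, character(1L), "round_id"),
      bias = vapply(records, function(r)
        relative_bias(r$lab_mean, r$peer_mean), numeric(1L)),
      stringsAsFactors = FALSE))
  structure(list(analyte = records[[1L]]$analyte, source = source,
                 per_item = per, rms_bias = rms_bias(per$bias),
                 mean_bias = mean(per$bias), n = nrow(per),
                 status = "computed"),
            class = "bias_estimate")
}
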