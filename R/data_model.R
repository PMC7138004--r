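#' labmu: top-down measurement uncertainty for clinical laboratories
#'
#' Estimates measurement uncertainty (MU) from routine quality-control data:
#' within-laboratory imprecision (CV_WL) from internal QC series, and bias from
#' three data sources -- proficiency tests (PT), certified reference
#' calibrators (CRC) and inter-laboratory internal QC scheme peer comparisons
#' (IQCS). The uncertainty of the bias is computed under three published
#' top-down formulations (Nordtest, Eurolab, Cofrac), combined with
#' imprecision in quadrature and expanded with a coverage factor, then judged
#' against analytical quality goals (Westgard allowable total error and
#' Haeckel permissible uncertainty).
#'
#' All percentages in this package are on the percent scale (9.2 means 9.2%),
#' never fractions.
#'
#' @keywords internal
"_PACKAGE"

#' Enumerations of bias-uncertainty approaches and bias data sources
#'
#' @return Character vector of the recognised approach / source codes.
#' @export
mu_approaches <- function() c("nordtest", "eurolab", "cofrac")

#' @rdname mu_approaches
#' @export
mu_sources <- function() c("pt", "crc", "iqcs")

display_label <- function(x) {
  map <- c(nordtest = "Nordtest", eurolab = "Eurolab", cofrac = "Cofrac",
           pt = "PT", crc = "CRC", iqcs = "IQCS")
  unname(map[match(x, names(map))])
}

match_approach <- function(approach) {
  match.arg(tolower(approach), mu_approaches())
}

match_source <- function(source) {
  match.arg(tolower(source), mu_sources())
}

#' Analyte specification
#'
#' Carries the units and adult reference limits of an analyte. When the lower
#' reference limit is unknown (common for tumour markers and enzymes reported
#' as "< upper limit") it is left `NULL`; downstream the permissible-
#' uncertainty calculation substitutes 15% of the upper limit.
#'
#' @param name Analyte name.
#' @param unit Concentration unit (informational).
#' @param upper_reference_limit Upper reference limit, in analyte units; > 0.
#' @param lower_reference_limit Lower reference limit or `NULL` when unknown.
#' @param report_decimals Decimals used when rendering reports.
#' @return An object of class `analyte_spec`.
#' @examples
#' analyte_spec("creatinine", "umol/L", 97, 44)
#' @export
analyte_spec <- function(name, unit, upper_reference_limit,
                         lower_reference_limit = NULL, report_decimals = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(upper_reference_limit))
  structure(list(name = name, unit = unit,
                 upper_reference_limit = upper_reference_limit,
                 lower_reference_limit = lower_reference_limit,
                 report_decimals = as.integer(report_decimals)),
            class = "analyte_spec")
}

#' Internal QC level series
#'
#' One control level of one analyte: the ordered series of measured IQC
#' results used to estimate long-term (intermediate) imprecision.
#'
#' @param analyte Analyte name.
#' @param level_id Control level identifier (e.g. "L1").
#' @param lot_id Control material lot.
#' @param values Numeric vector of measured results, all > 0.
#' @param dates Optional vector of dates (informational; no formula uses
#'   time ordering).
#' @return An object of class `iqc_series`.
#' @export
iqc_series <- function(analyte, level_id, lot_id, values, dates = NULL) {
  values <- as.numeric(values)
  if (is.null(dates)) dates <- rep(NA_character_, length(values))
  stopifnot(length(dates) == length(values))
  structure(list(analyte = analyte, level_id = as.character(level_id),
                 lot_id = as.character(lot_id), values = values,
                 dates = as.character(dates)),
            class = "iqc_series")
}

#' Proficiency-test round record
#'
#' The laboratory's own summary of one PT round: its reported result, the
#' peer-group assigned value, the peer CV of the round, the number of
#' participating laboratories and the provider z-score. Replicate results, if
#' the PT sample was measured more than once, feed the Eurolab replicate term.
#'
#' @param analyte Analyte name.
#' @param round_id Round identifier.
#' @param lab_result The laboratory's reported result (mean of `replicates`
#'   when those are given).
#' @param assigned_value Peer-group target value; > 0.
#' @param cv_pt Peer CV of the round, percent.
#' @param n_lab Number of participating laboratories; >= 2.
#' @param z_score Provider z-score; `NA` to have [filter_pt_rounds()]
#'   recompute it from the peer statistics.
#' @param replicates Optional numeric vector of the laboratory's replicate
#'   measurements of the PT sample.
#' @return An object of class `pt_round`.
#' @export
pt_round <- function(analyte, round_id, lab_result, assigned_value, cv_pt,
                     n_lab, z_score = NA_real_, replicates = NULL) {
  structure(list(analyte = analyte, round_id = as.character(round_id),
                 lab_result = as.numeric(lab_result),
                 assigned_value = as.numeric(assigned_value),
                 cv_pt = as.numeric(cv_pt), n_lab = as.integer(n_lab),
                 z_score = as.numeric(z_score),
                 replicates = if (is.null(replicates)) NULL else as.numeric(replicates)),
            class = "pt_round")
}

#' Certified reference calibrator
#'
#' A calibrator (different from the one used to calibrate the assay) with a
#' certified assigned value and the manufacturer's expanded uncertainty, plus
#' the laboratory's replicate measurements of it, one per analytical series.
#'
#' @param analyte Analyte name.
#' @param calibrator_id Calibrator identifier.
#' @param assigned_value Certified value; > 0.
#' @param expanded_uncertainty Manufacturer's expanded uncertainty, same
#'   units as `assigned_value`.
#' @param coverage_factor Coverage factor of the certificate (k, default 2).
#' @param replicates Measured results across analytical series; >= 2 needed
#'   for a CV.
#' @param series_ids Optional identifiers of the analytical series.
#' @return An object of class `crc_material`.
#' @export
crc_material <- function(analyte, calibrator_id, assigned_value,
                         expanded_uncertainty, coverage_factor = 2,
                         replicates, series_ids = NULL) {
  replicates <- as.numeric(replicates)
  if (is.null(series_ids)) series_ids <- paste0("S", seq_along(replicates))
  stopifnot(length(series_ids) == length(replicates))
  structure(list(analyte = analyte, calibrator_id = as.character(calibrator_id),
                 assigned_value = as.numeric(assigned_value),
                 expanded_uncertainty = as.numeric(expanded_uncertainty),
                 coverage_factor = as.numeric(coverage_factor),
                 replicates = replicates, series_ids = as.character(series_ids),
                 n_m = length(replicates)),
            class = "crc_material")
}

#' Inter-laboratory internal QC scheme (IQCS) peer-comparison round
#'
#' One monthly peer comparison of IQC results: the laboratory's monthly mean
#' against the peer-group mean, with the peer CV and group size.
#'
#' @param analyte Analyte name.
#' @param round_id Round (month) identifier.
#' @param lab_mean The laboratory's monthly mean for the control material.
#' @param peer_mean Peer-group mean; > 0.
#' @param cv_peer Peer CV of the comparison, percent.
#' @param n_lab Number of participating laboratories; >= 2.
#' @param replicates Optional replicate results (usually absent; IQC is not
#'   commonly run in duplicate, which is what blocks the Eurolab IQCS cell).
#' @return An object of class `iqcs_round`.
#' @export
iqcs_round <- function(analyte, round_id, lab_mean, peer_mean, cv_peer, n_lab,
                       replicates = NULL) {
  structure(list(analyte = analyte, round_id = as.character(round_id),
                 lab_mean = as.numeric(lab_mean), peer_mean = as.numeric(peer_mean),
                 cv_peer = as.numeric(cv_peer), n_lab = as.integer(n_lab),
                 replicates = if (is.null(replicates)) NULL else as.numeric(replicates)),
            class = "iqcs_round")
}

record_id <- function(rec) {
  switch(class(rec)[1L],
         iqc_series = paste(rec$analyte, rec$level_id, sep = "/"),
         pt_round = paste(rec$analyte, rec$round_id, sep = "/"),
         crc_material = paste(rec$analyte, rec$calibrator_id, sep = "/"),
         iqcs_round = paste(rec$analyte, rec$round_id, sep = "/"),
         analyte_spec = rec$name,
         "?")
}

#' Approach x source applicability
#'
#' Not every bias-uncertainty formula applies to every bias data source: the
#' Eurolab formula needs replicate (duplicate) results, which IQCS peer
#' reports do not carry (`"ND"`), and the Cofrac formula does not include a
#' bias term for calibrator data (`"NE"`). Every other cell is computable;
#' whether it actually computes still depends on data being available (an
#' empty source yields the data-driven `"NC"`, no peer group, at estimation
#' time).
#'
#' @param approach One of `"nordtest"`, `"eurolab"`, `"cofrac"`.
#' @param source One of `"pt"`, `"crc"`, `"iqcs"`.
#' @return `"computed"`, `"ND"` or `"NE"`.
#' @examples
#' applicability("eurolab", "iqcs")  # "ND"
#' applicability("cofrac", "crc")    # "NE"
#' @export
applicability <- function(approach, source) {
  approach <- match_approach(approach)
  source <- match_source(source)
  if (approach == "eurolab" && source == "iqcs") return("ND")
  if (approach == "cofrac" && source == "crc") return("NE")
  "computed"
}

#' @rdname applicability
#' @return `applicability_matrix()`: a data frame of all 9 approach x source
#'   cells and their status (7 are computable).
#' @export
applicability_matrix <- function() {
  grid <- expand.grid(approach = mu_approaches(), source = mu_sources(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$status <- mapply(applicability, grid$approach, grid$source)
  grid
}

violation <- function(rec, rule) {
  data.frame(record = record_id(rec), type = class(rec)[1L], rule = rule,
             stringsAsFactors = FALSE)
}

check_record <- function(rec) {
  v <- list()
  add <- function(rule) v[[length(v) + 1L]] <<- violation(rec, rule)
  if (inherits(rec, "analyte_spec")) {
    if (!isTRUE(rec$upper_reference_limit > 0)) add("upper_reference_limit > 0")
    if (!is.null(rec$lower_reference_limit) &&
        !isTRUE(rec$lower_reference_limit >= 0 &&
                rec$lower_reference_limit < rec$upper_reference_limit))
      add("0 <= lower_reference_limit < upper_reference_limit")
  } else if (inherits(rec, "iqc_series")) {
    if (length(rec$values) < 2L) add("at least 2 results per level")
    if (any(rec$values <= 0)) add("all measured values > 0")
  } else if (inherits(rec, "pt_round")) {
    if (!isTRUE(rec$assigned_value > 0)) add("assigned_value > 0")
    if (!isTRUE(rec$n_lab >= 2L)) add("n_lab >= 2")
    if (!isTRUE(rec$cv_pt >= 0)) add("cv_pt >= 0")
  } else if (inherits(rec, "crc_material")) {
    if (!isTRUE(rec$assigned_value > 0)) add("assigned_value > 0")
    if (!isTRUE(rec$expanded_uncertainty >= 0)) add("expanded_uncertainty >= 0")
    if (!isTRUE(rec$coverage_factor > 0)) add("coverage_factor > 0")
    if (rec$n_m < 2L) add("n_m >= 2")
  } else if (inherits(rec, "iqcs_round")) {
    if (!isTRUE(rec$peer_mean > 0)) add("peer_mean > 0")
    if (!isTRUE(rec$n_lab >= 2L)) add("n_lab >= 2")
  }
  v
}

#' Validate a dataset of QC records
#'
#' Checks the type invariants of every record and reports violations instead
#' of throwing: an empty report means the dataset is valid.
#'
#' @param records A list of records ([pt_round()], [crc_material()],
#'   [iqcs_round()], [iqc_series()], [analyte_spec()]), possibly mixed.
#' @return A data frame with columns `record`, `type`, `rule`; zero rows when
#'   all invariants hold.
#' @examples
#' bad <- pt_round("alp", "R1", 100, 100, 3, n_lab = 1)
#' validate_dataset(list(bad))
#' @export
validate_dataset <- function(records) {
  if (inherits(records, c("pt_round", "crc_material", "iqcs_round",
                          "iqc_series", "analyte_spec")))
    records <- list(records)
  out <- do.call(rbind, c(lapply(records, function(r) {
    vs <- check_record(r)
    if (length(vs)) do.call(rbind, vs) else NULL
  }), list(data.frame(record = character(), type = character(),
                      rule = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
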