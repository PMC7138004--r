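# Plain-CSV readers and writers for the four QC data streams, the
# summary-level entry point, and report rendering. All files are UTF-8 with
# a header row and "." as the decimal separator.
#
# Schemas:
#   iqc.csv : analyte,level_id,lot_id,date,value            (long, one row per result)
#   pt.csv  : analyte,round_id,lab_result,assigned_value,cv_pt,n_lab,z_score[,rep1,...]
#   crc.csv : analyte,calibrator_id,assigned_value,expanded_uncertainty,
#             coverage_factor,series_id,value               (long, one row per series)
#   iqcs.csv: analyte,round_id,lab_mean,peer_mean,cv_peer,n_lab[,rep1,...]

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

rep_cols <- function(df) grep("^rep[0-9]+$", names(df), value = TRUE)

row_reps <- function(df, i) {
  cols <- rep_cols(df)
  if (!length(cols)) return(NULL)
  v <- suppressWarnings(as.numeric(df[i, cols]))
  v <- v[!is.na(v)]
  if (length(v)) v else NULL
}

reps_frame <- function(records) {
  k <- max(c(0L, vapply(records, function(r) length(r$replicates), integer(1L))))
  if (k == 0L) return(NULL)
  out <- do.call(rbind, lapply(records, function(r) {
    v <- rep(NA_real_, k)
    if (!is.null(r$replicates)) v[seq_along(r$replicates)] <- r$replicates
    v
  }))
  colnames(out) <- paste0("rep", seq_len(k))
  as.data.frame(out)
}

#' Read and write the QC data CSV schemas
#'
#' One reader/writer pair per data stream. Writing then reading a dataset
#' returns records equal to the originals (to full numeric precision).
#'
#' @param path CSV file path.
#' @param series,rounds,crcs Record lists, as produced by the constructors or
#'   the simulators.
#' @return Readers return record lists ([iqc_series()], [pt_round()],
#'   [crc_material()], [iqcs_round()]); writers return the path, invisibly.
#' @name qc_csv
NULL

#' @rdname qc_csv
#' @export
read_iqc_csv <- function(path) {
  df <- read_schema_csv(path, c("analyte", "level_id", "lot_id", "date", "value"))
  if (!is.numeric(df$value)) stop(path, ": non-numeric 'value'", call. = FALSE)
  keys <- unique(df[, c("analyte", "level_id", "lot_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$analyte == keys$analyte[i] & df$level_id == keys$level_id[i] &
      df$lot_id == keys$lot_id[i]
    iqc_series(keys$analyte[i], keys$level_id[i], keys$lot_id[i],
               df$value[sel], df$date[sel])
  })
}

#' @rdname qc_csv
#' @export
write_iqc_csv <- function(series, path) {
  if (inherits(series, "iqc_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(analyte = s$analyte, level_id = s$level_id, lot_id = s$lot_id,
               date = s$dates, value = s$values, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname qc_csv
#' @export
read_pt_csv <- function(path) {
  df <- read_schema_csv(path, c("analyte", "round_id", "lab_result",
                                "assigned_value", "cv_pt", "n_lab", "z_score"))
  lapply(seq_len(nrow(df)), function(i)
    pt_round(df$analyte[i], df$round_id[i], df$lab_result[i],
             df$assigned_value[i], df$cv_pt[i], df$n_lab[i], df$z_score[i],
             replicates = row_reps(df, i)))
}

#' @rdname qc_csv
#' @export
write_pt_csv <- function(rounds, path) {
  if (inherits(rounds, "pt_round")) rounds <- list(rounds)
  df <- do.call(rbind, lapply(rounds, function(r)
    data.frame(analyte = r$analyte, round_id = r$round_id,
               lab_result = r$lab_result, assigned_value = r$assigned_value,
               cv_pt = r$cv_pt, n_lab = r$n_lab, z_score = r$z_score,
               stringsAsFactors = FALSE)))
  reps <- reps_frame(rounds)
  if (!is.null(reps)) df <- cbind(df, reps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname qc_csv
#' @export
read_crc_csv <- function(path) {
  df <- read_schema_csv(path, c("analyte", "calibrator_id", "assigned_value",
                                "expanded_uncertainty", "coverage_factor",
                                "series_id", "value"))
  keys <- unique(df[, c("analyte", "calibrator_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$analyte == keys$analyte[i] & df$calibrator_id == keys$calibrator_id[i]
    sub <- df[sel, ]
    crc_material(keys$analyte[i], keys$calibrator_id[i], sub$assigned_value[1L],
                 sub$expanded_uncertainty[1L], sub$coverage_factor[1L],
                 replicates = sub$value, series_ids = sub$series_id)
  })
}

#' @rdname qc_csv
#' @export
write_crc_csv <- function(crcs, path) {
  if (inherits(crcs, "crc_material")) crcs <- list(crcs)
  df <- do.call(rbind, lapply(crcs, function(m)
    data.frame(analyte = m$analyte, calibrator_id = m$calibrator_id,
               assigned_value = m$assigned_value,
               expanded_uncertainty = m$expanded_uncertainty,
               coverage_factor = m$coverage_factor, series_id = m$series_ids,
               value = m$replicates, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname qc_csv
#' @export
read_iqcs_csv <- function(path) {
  df <- read_schema_csv(path, c("analyte", "round_id", "lab_mean", "peer_mean",
                                "cv_peer", "n_lab"))
  lapply(seq_len(nrow(df)), function(i)
    iqcs_round(df$analyte[i], df$round_id[i], df$lab_mean[i], df$peer_mean[i],
               df$cv_peer[i], df$n_lab[i], replicates = row_reps(df, i)))
}

#' @rdname qc_csv
#' @export
write_iqcs_csv <- function(rounds, path) {
  if (inherits(rounds, "iqcs_round")) rounds <- list(rounds)
  df <- do.call(rbind, lapply(rounds, function(r)
    data.frame(analyte = r$analyte, round_id = r$round_id, lab_mean = r$lab_mean,
               peer_mean = r$peer_mean, cv_peer = r$cv_peer, n_lab = r$n_lab,
               stringsAsFactors = FALSE)))
  reps <- reps_frame(rounds)
  if (!is.null(reps)) df <- cbind(df, reps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read all available QC sources with validation
#'
#' @param iqc,pt,crc,iqcs File paths (`NULL` for sources the laboratory does
#'   not have; missing sources simply yield `"NC"` cells downstream).
#' @param strict Stop when any record violates its invariants; otherwise the
#'   violations are only reported.
#' @return A list with the record lists and a `validation` data frame.
#' @export
read_sources <- function(iqc = NULL, pt = NULL, crc = NULL, iqcs = NULL,
                         strict = TRUE) {
  out <- list(iqc = if (!is.null(iqc)) read_iqc_csv(iqc),
              pt = if (!is.null(pt)) read_pt_csv(pt),
              crc = if (!is.null(crc)) read_crc_csv(crc),
              iqcs = if (!is.null(iqcs)) read_iqcs_csv(iqcs))
  out$validation <- validate_dataset(c(out$iqc, out$pt, out$crc, out$iqcs))
  if (strict && nrow(out$validation))
    stop("invalid records: ",
         paste(out$validation$record, out$validation$rule, sep = ": ",
               collapse = "; "), call. = FALSE)
  out
}

#' Uncertainty budgets from summary-level inputs
#'
#' Entry point for laboratories (and verification runs) that already hold the
#' bias uncertainties and the within-laboratory CV per analyte x approach x
#' source: only the combination and expansion steps are applied. Cells not
#' present in the table become `"NC"` where the approach covers the source,
#' and the fixed `"ND"`/`"NE"` statuses otherwise.
#'
#' @param summaries Data frame (or CSV path) with columns `analyte`,
#'   `approach`, `source`, `u_bias`, `cv_wl`.
#' @param k Coverage factor, default 2.
#' @return A list of `mu_budget` objects covering the full matrix for every
#'   analyte in the input (see [budget_table()]).
#' @export
budgets_from_summaries <- function(summaries, k = 2) {
  if (is.character(summaries))
    summaries <- read_schema_csv(summaries, c("analyte", "approach", "source",
                                              "u_bias", "cv_wl"))
  summaries$approach <- tolower(summaries$approach)
  summaries$source <- tolower(summaries$source)
  budgets <- list()
  for (an in unique(summaries$analyte)) {
    sub <- summaries[summaries$analyte == an, ]
    cv_wl <- sub$cv_wl[!is.na(sub$cv_wl)][1L]
    grid <- applicability_matrix()
    for (i in seq_len(nrow(grid))) {
      a <- grid$approach[i]; s <- grid$source[i]
      row <- sub[sub$approach == a & sub$source == s, ]
      b <- if (grid$status[i] != "computed") {
        new_budget(an, a, s, grid$status[i], cv_wl = cv_wl, k = k)
      } else if (nrow(row) == 0L || is.na(row$u_bias[1L])) {
        new_budget(an, a, s, "NC", cv_wl = cv_wl, k = k)
      } else {
        new_budget(an, a, s, "computed", cv_wl = cv_wl,
                   u_bias = row$u_bias[1L], k = k)
      }
      budgets[[length(budgets) + 1L]] <- b
    }
  }
  structure(budgets, class = "mu_budget_list")
}

# Report rounding: half away from zero, matching how the budgets are quoted.
round_half_out <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render an uncertainty report
#'
#' Writes a wide TSV (one row per analyte, one expanded-uncertainty column
#' per approach x source, statuses printed literally as NC/ND/NE, numbers
#' rounded half-away-from-zero to `decimals`) and a JSON report keeping full
#' precision, all intermediate components and the formula-variant settings of
#' the run.
#'
#' @param budgets A `mu_budget_list` (or plain list of budgets).
#' @param path_tsv,path_json Output paths (`NULL` to skip either).
#' @param goals Optional list of [quality_goals()] objects, keyed or named by
#'   analyte, appended as goal columns.
#' @param decimals Decimals in the TSV.
#' @param settings Named list recorded in the JSON `settings` block.
#' @return The wide data frame, invisibly.
#' @export
render_report <- function(budgets, path_tsv = NULL, path_json = NULL,
                          goals = NULL, decimals = 1L,
                          settings = list(pooling = "rms",
                                          eurolab_bias_term = "rms",
                                          cofrac_dispersion = "sd_points")) {
  tab <- budget_table(budgets)
  cells <- expand.grid(approach = mu_approaches(), source = mu_sources(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wide <- data.frame(analyte = unique(tab$analyte), stringsAsFactors = FALSE)
  wide$cv_wl <- vapply(wide$analyte, function(an)
    tab$cv_wl[tab$analyte == an][1L], numeric(1L))
  for (i in seq_len(nrow(cells))) {
    col <- paste("U", cells$approach[i], cells$source[i], sep = "_")
    wide[[col]] <- vapply(wide$analyte, function(an) {
      row <- tab[tab$analyte == an & tab$approach == cells$approach[i] &
                   tab$source == cells$source[i], ]
      if (nrow(row) == 0L) return(NA_character_)
      if (row$status[1L] != "computed") return(row$status[1L])
      format(round_half_out(row$u_expanded[1L], decimals), nsmall = decimals)
    }, character(1L))
  }
  if (!is.null(goals)) {
    gmap <- stats::setNames(goals, vapply(goals, `[[`, character(1L), "analyte"))
    for (col in c("allowable_te", "permissible_u", "permissible_u_pt"))
      wide[[col]] <- vapply(wide$analyte, function(an)
        if (!is.null(gmap[[an]]))
          format(round_half_out(gmap[[an]][[col]], decimals), nsmall = decimals)
        else NA_character_, character(1L))
  }
  if (!is.null(path_tsv))
    utils::write.table(wide, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_json)) {
    payload <- list(settings = settings, budgets = lapply(budgets, unclass))
    if (!is.null(goals)) payload$goals <- lapply(goals, unclass)
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(wide)
}
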