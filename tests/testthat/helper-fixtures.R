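# Small in-code fixtures shared across test files.

make_pt_rounds <- function(biases, assigned = 100, cv_pt = 3, n_lab = 30,
                           z = NULL, analyte = "demo") {
  lapply(seq_along(biases), function(i)
    pt_round(analyte, paste0("R", i), assigned * (1 + biases[i] / 100),
             assigned, cv_pt, n_lab,
             z_score = if (is.null(z)) biases[i] / cv_pt else z[i]))
}

make_iqcs_rounds <- function(biases, peer = 100, cv_peer = 3, n_lab = 49,
                             analyte = "demo") {
  lapply(seq_along(biases), function(i)
    iqcs_round(analyte, paste0("M", i), peer * (1 + biases[i] / 100), peer,
               cv_peer, n_lab))
}

# Summary-level bias uncertainties and CV_WL of the four-analyte worked
# example bundled with the package (also in inst/extdata/example_summaries.csv).
example_summaries_df <- function() {
  read.csv(system.file("extdata", "example_summaries.csv", package = "labmu"),
           stringsAsFactors = FALSE)
}
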