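#!/usr/bin/env Rscript
# Generate a synthetic laboratory dataset with known ground truth (a
# creatinine-like analyte: true bias +5.2%, true CV_WL 2.0%) and write the
# four QC data streams as CSVs under results/data/.

suppressPackageStartupMessages(library(labmu))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260925)
lab <- simulate_lab(cfg)

write_iqc_csv(lab$iqc, "results/data/iqc.csv")
write_pt_csv(lab$pt, "results/data/pt.csv")
write_crc_csv(lab$crc, "results/data/crc.csv")
write_iqcs_csv(lab$iqcs, "results/data/iqcs.csv")

cat(sprintf("wrote %d IQC results x %d levels, %d PT rounds (%d injected outliers),\n",
            cfg$n_iqc_per_level, length(lab$iqc), length(lab$pt),
            length(attr(lab$pt, "outlier_rounds"))))
cat(sprintf("%d calibrator(s) x %d series, %d IQCS rounds to results/data/\n",
            length(lab$crc), cfg$n_series_per_crc, length(lab$iqcs)))
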