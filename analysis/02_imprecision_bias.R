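#!/usr/bin/env Rscript
# Estimate imprecision (CV_WL) and the bias from each QC source for the
# simulated laboratory; writes results/bias_imprecision.tsv.

suppressPackageStartupMessages(library(labmu))
src <- read_sources(iqc = "results/data/iqc.csv", pt = "results/data/pt.csv",
                    crc = "results/data/crc.csv", iqcs = "results/data/iqcs.csv")

imp <- estimate_imprecision(src$iqc)
cat(sprintf("CV_WL = %.2f%% (per-level: %s)\n", imp$cv_wl,
            paste(sprintf("%s %.2f%%", imp$per_level$level_id,
                          imp$per_level$cv), collapse = ", ")))

f <- filter_pt_rounds(src$pt)
cat(sprintf("PT filter: %d kept, %d discarded (|z| > 2)\n",
            length(f$kept), length(f$discarded)))

rows <- lapply(list(list(recs = f$kept, src = "pt"),
                    list(recs = src$crc, src = "crc"),
                    list(recs = src$iqcs, src = "iqcs")), function(x) {
  be <- estimate_bias(x$recs, x$src)
  cat(sprintf("%-4s bias: RMS %.2f%% (mean %+.2f%%, n = %d)\n",
              toupper(x$src), be$rms_bias, be$mean_bias, be$n))
  data.frame(source = x$src, n = be$n, rms_bias = be$rms_bias,
             mean_bias = be$mean_bias, cv_wl = imp$cv_wl)
})
write.table(do.call(rbind, rows), "results/bias_imprecision.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
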