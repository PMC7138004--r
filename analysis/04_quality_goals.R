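#!/usr/bin/env Rscript
# Judge the simulated laboratory's budgets against analytical quality goals:
# Westgard desirable allowable TE (biological variation supplied here:
# creatinine CV_I 6.0%, CV_G 14.6%) and the permissible uncertainty derived
# from the adult-male reference interval 44-97 umol/L.

suppressPackageStartupMessages(library(labmu))
src <- read_sources(iqc = "results/data/iqc.csv", pt = "results/data/pt.csv",
                    crc = "results/data/crc.csv", iqcs = "results/data/iqcs.csv")
imp <- estimate_imprecision(src$iqc)
budgets <- build_all_budgets("creatinine", imp, pt = src$pt, crc = src$crc,
                             iqcs = src$iqcs)
goals <- quality_goals("creatinine", cv_i = 6.0, cv_g = 14.6,
                       upper_rl = 97, lower_rl = 44)
cat(sprintf("goals: allowable TE %.1f%%, permissible U %.1f%%, permissible U (PT) %.1f%%\n",
            goals$allowable_te, goals$permissible_u, goals$permissible_u_pt))

tab <- budget_table(budgets)
tab <- tab[tab$status == "computed", ]
rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
  te <- analytical_total_error(tab$bias[i], tab$cv_wl[i])
  v <- verdict(tab$u_expanded[i], goals, analytical_te = te)
  cbind(approach = tab$approach[i], source = tab$source[i], v)
}))
write.table(rows, "results/goal_verdicts.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
fails <- rows[!rows$pass, c("approach", "source", "check", "margin")]
cat(sprintf("%d of %d goal checks failed\n", nrow(fails), nrow(rows)))
if (nrow(fails)) print(fails, row.names = FALSE)
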