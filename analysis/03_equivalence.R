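#!/usr/bin/env Rscript
# Design-stage sample sizes and the telephone vs in-person equivalence
# analysis (paired TOST with bounds at 0.5 SD of the differences).

suppressPackageStartupMessages(library(tvfb))

cat("design: pairs for TOST (dz 0.5, alpha .05, power .90):",
    tost_sample_size(0.5, 0.05, 0.90), "(normal approximation),",
    tost_sample_size(0.5, 0.05, 0.90, method = "exact"), "(exact t)\n")
cat("design: N for the adjustment regression (f2 .05, 3 predictors, power .90):",
    regression_sample_size(0.05, 3, 0.05, 0.90), "\n\n")

paired <- read_cohort("results/cohort_paired.csv")
rows <- lapply(c("pvf", "svf", "avf", "csi"), function(m) {
  res <- tost_paired(paired[[m]] - paired[[paste0(m, "_ip")]], dz = 0.5)
  cat(sprintf("%-4s telephone %6.2f vs in-person %6.2f: t(%d) = %5.2f, p = %.3f; TOST p = %.4g -> %s\n",
              m, mean(paired[[m]]), mean(paired[[paste0(m, "_ip")]]),
              res$df, res$t_nhst, res$p_nhst, res$p_tost,
              if (res$equivalent) "equivalent" else "not equivalent"))
  data.frame(measure = m, n = res$n, mean_diff = res$mean_diff,
             sd_diff = res$sd_diff, t = res$t_nhst, p = res$p_nhst,
             p_tost = res$p_tost, equivalent = res$equivalent)
})
write.csv(do.call(rbind, rows), "results/equivalence.csv", row.names = FALSE)
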