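#!/usr/bin/env Rscript
# Reliability and construct validity on the simulated cohorts: inter-rater
# and test-retest ICCs, internal consistency, component structure, and
# normality-gated correlations among the battery's measures.

suppressPackageStartupMessages(library(tvfb))
cohort <- read_cohort("results/cohort_normative.csv")
retest <- read_cohort("results/cohort_retest.csv")
rated <- read_cohort("results/cohort_rated.csv")

rows <- lapply(c("pvf", "svf", "avf"), function(m) {
  rt <- icc(retest[c(m, paste0(m, "_rt"))], model = "consistency")
  ir <- icc(rated[c(m, paste0(m, "_r2"))], model = "absolute")
  cat(sprintf("%-4s test-retest ICC %.2f [%.2f, %.2f]; inter-rater ICC %.2f [%.2f, %.2f]\n",
              m, rt$icc, rt$ci[1], rt$ci[2], ir$icc, ir$ci[1], ir$ci[2]))
  data.frame(measure = m, icc_retest = rt$icc, icc_retest_lo = rt$ci[1],
             icc_retest_hi = rt$ci[2], icc_rater = ir$icc,
             icc_rater_lo = ir$ci[1], icc_rater_hi = ir$ci[2])
})
write.csv(do.call(rbind, rows), "results/reliability.csv", row.names = FALSE)

# internal consistency and structure on demographically adjusted trial scores
cards <- published_norm_cards()
adj <- sapply(trial_names(), function(tn) {
  adjust_cohort(cohort, cards[[tn]]$equation, score_col = tn)
})
alpha <- cronbach_alpha(adj)
ps <- pca_structure(adj)
cat(sprintf("\nCronbach alpha over the nine adjusted trials: %.2f\n", alpha))
cat(sprintf("PCA: %d component retained, %.1f%% of variance, loadings %.2f-%.2f\n",
            ps$n_retained, 100 * ps$explained_retained,
            min(ps$loadings), max(ps$loadings)))

# convergent validity: totals against each other, Bonferroni-adjusted
pairs <- combn(c("pvf", "svf", "avf", "csi"), 2)
a_adj <- bonferroni_alpha(0.05, ncol(pairs))
cors <- apply(pairs, 2, function(pr) {
  r <- gated_correlation(cohort[[pr[1]]], cohort[[pr[2]]],
                         alpha_adjusted = a_adj,
                         label = paste(pr, collapse = " vs "))
  cat(sprintf("%-12s %-14s r = %5.2f  p = %.2g%s\n", r$label, r$method,
              r$estimate, r$p, if (r$significant) " *" else ""))
  r$estimate
})
invisible(cors)
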