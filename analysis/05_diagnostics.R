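#!/usr/bin/env Rscript
# Diagnostic accuracy of the battery against the simulated clinical group:
# ROC of demographically adjusted scores, lower-is-abnormal.

suppressPackageStartupMessages(library(tvfb))
cohort <- read_cohort("results/cohort_normative.csv")
clinical <- read_cohort("results/cohort_clinical.csv")
cards <- read_norm_cards("results/norm_cards_fitted.json")

rows <- lapply(c("pvf", "svf", "avf"), function(m) {
  eq <- cards[[m]]$equation
  roc <- roc_auc(adjust_cohort(clinical, eq), adjust_cohort(cohort, eq),
                 direction = "lower")
  cat(sprintf("%-4s AUC = %.2f, SE = %.2f, 95%% CI [%.2f, %.2f]\n",
              m, roc$auc, roc$se, roc$ci[1], roc$ci[2]))
  data.frame(measure = m, auc = roc$auc, se = roc$se,
             ci_lo = roc$ci[1], ci_hi = roc$ci[2])
})
write.csv(do.call(rbind, rows), "results/diagnostics.csv", row.names = FALSE)

# Equivalent-Score distribution of the clinical group under the fitted norms
es <- classify_es(cards$avf, adjust_cohort(clinical, cards$avf$equation))
cat("\nclinical alternate-fluency Equivalent Scores:\n")
print(table(factor(es, levels = 0:4)))
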