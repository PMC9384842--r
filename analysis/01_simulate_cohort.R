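#!/usr/bin/env Rscript
# Build the synthetic study cohorts: a 335-subject stratified normative
# sample, the 47-pair telephone/in-person subsample, the 18-subject retest
# and 27-protocol dual-rating subsamples, and a 27-case clinical group
# shifted 1.5 residual SD. Writes everything under results/.

suppressPackageStartupMessages(library(tvfb))
seed <- 20260930L
dir.create("results", showWarnings = FALSE)

cfg <- default_sim_config()
cohort <- generate_normative(cfg, seed = seed)
write_cohort(cohort, "results/cohort_normative.csv")
cat(sprintf("normative cohort: %d subjects (%d M / %d F), age %d-%d, education %d-%d\n",
            nrow(cohort), sum(cohort$sex == "M"), sum(cohort$sex == "F"),
            min(cohort$age), max(cohort$age),
            min(cohort$education), max(cohort$education)))
cat(sprintf("mean totals: PVF %.1f, SVF %.1f, AVF %.1f, CSI %.2f\n",
            mean(cohort$pvf), mean(cohort$svf), mean(cohort$avf),
            mean(cohort$csi)))

set.seed(seed)  # replicate subsamples are random draws from the cohort
sub <- function(n) cohort[sample(nrow(cohort), n), ]
paired <- generate_paired_modality(sub(cfg$paired$n),
                                   rho = cfg$paired$rho,
                                   delta = cfg$paired$delta, seed = seed + 1)
write_cohort(paired, "results/cohort_paired.csv")

retest <- generate_retest(sub(cfg$retest$n), rho = cfg$retest$rho,
                          seed = seed + 2)
write_cohort(retest, "results/cohort_retest.csv")

rated <- generate_ratings(sub(cfg$raters$n),
                          disagreement_rate = cfg$raters$disagreement_rate,
                          seed = seed + 3)
write_cohort(rated, "results/cohort_rated.csv")

clinical <- generate_clinical(cfg, seed = seed + 4)
write_cohort(clinical, "results/cohort_clinical.csv")
cat(sprintf("replicates: %d pairs, %d retests, %d dual-rated, %d clinical cases\n",
            nrow(paired), nrow(retest), nrow(rated), nrow(clinical)))
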