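# Shared fixtures, built in code at test time.

default_cfg <- function() default_sim_config()

# A no-demographic-effect configuration (pure noise around the trial means).
null_effect_cfg <- function() {
  cfg <- default_sim_config()
  for (m in names(cfg$measures)) {
    cfg$measures[[m]]$effects <- cfg$measures[[m]]$effects[0, ]
  }
  cfg
}

# Printed normative trial means, used as worked-example inputs.
printed_trial_means <- c(
  pvf_f = 14.98, pvf_a = 13.1, pvf_s = 14.52,
  svf_col = 15.74, svf_ani = 22.9, svf_fru = 16.88,
  avf_acol = 13.62, avf_fani = 14.13, avf_sfru = 14.39)

# Independent brute-force tolerance-rank oracle: literal scan over all ranks.
oracle_tolerance_ranks <- function(n, p = 0.05, confidence = 0.95) {
  otl <- NA_integer_; itl <- NA_integer_
  for (r in 1:n) {
    if (pbinom(r - 1, n, p) <= 1 - confidence) otl <- r
    if (pbinom(r - 1, n, p) < confidence) itl <- r
  }
  if (is.na(otl)) stop("no valid rank")
  c(otl = otl, itl = itl)
}

# Independent pairwise-count AUC oracle (ties = 1/2).
oracle_auc <- function(cases, controls, direction = "lower") {
  tot <- 0
  for (a in cases) for (b in controls) {
    cmp <- if (direction == "lower") (a < b) + 0.5 * (a == b)
           else (a > b) + 0.5 * (a == b)
    tot <- tot + cmp
  }
  tot / (length(cases) * length(controls))
}

# ANOVA mean-squares ICC oracle via aov().
oracle_icc <- function(x, model) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (model == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
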