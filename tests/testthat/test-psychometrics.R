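test_that("the normality gate routes between product-moment and rank correlation", {
  set.seed(17)
  x <- rnorm(200)
  y <- 2 * x + 1
  rep1 <- gated_correlation(x, y)
  expect_equal(rep1$method, "product-moment")
  expect_equal(rep1$estimate, 1.0)

  xl <- exp(rnorm(200))  # lognormal: sample skewness far above 1
  expect_gt(e1071::skewness(xl, type = 2), 1)
  rep2 <- gated_correlation(xl, y[seq_along(xl)])
  expect_equal(rep2$method, "rank")

  # gate decision is invariant to positive affine rescaling
  rep3 <- gated_correlation(100 + 3 * xl, -2 + 0.1 * y)
  expect_equal(rep3$method, rep2$method)
  expect_error(gated_correlation(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("Bonferroni adjustment matches the reported family levels", {
  expect_equal(bonferroni_alpha(0.05, 50), 0.001)
  expect_equal(bonferroni_alpha(0.05, 8), 0.00625)
  set.seed(18)
  r <- gated_correlation(rnorm(100), rnorm(100),
                         alpha_adjusted = bonferroni_alpha(0.05, 50))
  expect_equal(r$alpha_adjusted, 0.001)
})

test_that("Cronbach's alpha matches its closed form on an exact covariance", {
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  x <- MASS::mvrnorm(60, rep(0, 3), sigma, empirical = TRUE)
  expect_equal(cronbach_alpha(x), 0.75, tolerance = 1e-12)
  # identical items are perfectly consistent
  z <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(z, z, z)), 1)
  # independent items have vanishing consistency at large n
  set.seed(19)
  ind <- matrix(rnorm(4000 * 3), ncol = 3)
  expect_lt(abs(cronbach_alpha(ind)), 0.15)
  expect_error(cronbach_alpha(cbind(rep(2, 5), rep(2, 5))), "zero total variance")
})

test_that("ICC separates consistency from absolute agreement", {
  z <- rnorm(20, 50, 10)
  perfect <- cbind(z, z)
  expect_equal(icc(perfect, "consistency")$icc, 1)
  expect_equal(icc(perfect, "absolute")$icc, 1)
  shifted <- cbind(z, z + 10)
  expect_equal(icc(shifted, "consistency")$icc, 1)
  expect_lt(icc(shifted, "absolute")$icc, 1)
  # identical rows: no between-subject variance to apportion
  expect_error(icc(cbind(rep(1, 6), rep(3, 6))), "between-subject")
})

test_that("both ICC forms agree with the ANOVA mean-squares oracle", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(5:20, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n)  # correlated rows
    for (model in c("consistency", "absolute")) {
      expect_equal(icc(x, model)$icc, oracle_icc(x, model), tolerance = 1e-9)
    }
  }
})

test_that("ICC confidence intervals bracket the estimate sensibly", {
  set.seed(29)
  subj <- rnorm(30, 0, 3)
  x <- cbind(subj + rnorm(30), subj + rnorm(30))
  for (model in c("consistency", "absolute")) {
    res <- icc(x, model)
    expect_lt(res$ci[1], res$icc)
    expect_gt(res$ci[2], res$icc)
    expect_lte(res$ci[2], 1)
  }
})

test_that("principal-component structure follows the correlation spectrum", {
  # exactly uncorrelated variables split the variance three equal ways
  sigma <- diag(3)
  x <- MASS::mvrnorm(100, rep(0, 3), sigma, empirical = TRUE)
  ps <- pca_structure(x)
  expect_equal(ps$prop_variance, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(ps$eigenvalues), 3, tolerance = 1e-9)

  # uniform correlation 0.5 on 3 variables: leading eigenvalue 1 + 2r = 2
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  x <- MASS::mvrnorm(100, rep(0, 3), sigma, empirical = TRUE)
  ps <- pca_structure(x)
  expect_equal(ps$eigenvalues[1], 2, tolerance = 1e-9)
  expect_equal(ps$n_retained, 1)
  expect_equal(ps$explained_retained, 2 / 3, tolerance = 1e-9)

  dup <- cbind(x, x[, 1])
  expect_error(pca_structure(dup), "singular")
})

test_that("a common factor across the nine trials yields a mono-component battery", {
  coh <- generate_normative(default_cfg(), seed = 101)
  cards <- published_norm_cards()
  adj <- sapply(trial_names(), function(tn) {
    adjust_cohort(coh, cards[[tn]]$equation, score_col = tn)
  })
  ps <- pca_structure(adj)
  expect_equal(ps$n_retained, 1)
  # with a common loading of 0.77 on nine trials the leading component
  # carries (1 + 8 * 0.77^2) / 9 ~ 64% of the variance
  expect_gt(ps$explained_retained, 0.55)
  expect_lt(ps$explained_retained, 0.70)
  expect_true(all(ps$loadings > 0.6))
  # and the same scores are internally consistent
  expect_gt(cronbach_alpha(adj), 0.85)
})

test_that("AUC equals the pairwise count and matches the published example shape", {
  r <- roc_auc(c(3, 5), c(1, 2, 4), direction = "higher")
  expect_equal(r$auc, 5 / 6)
  expect_equal(r$n_cases, 2); expect_equal(r$n_controls, 3)
  # perfect separation and exchangeable groups
  expect_equal(roc_auc(c(1, 2), c(5, 6, 7), direction = "lower")$auc, 1)
  set.seed(31)
  same <- roc_auc(rnorm(400), rnorm(400))
  expect_lt(abs(same$auc - 0.5), 0.06)
  expect_error(roc_auc(numeric(0), rnorm(5)), "at least one")
})

test_that("AUC agrees with brute force and pROC on random tied instances", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (r in 1:20) {
    na <- sample(1:50, 1); nc <- sample(1:50, 1)
    cases <- sample(0:15, na, replace = TRUE)     # heavy ties on purpose
    controls <- sample(3:18, nc, replace = TRUE)
    mine <- roc_auc(cases, controls, direction = "lower")
    expect_equal(mine$auc, oracle_auc(cases, controls, "lower"))
    ref <- suppressMessages(pROC::roc(
      response = c(rep(1, na), rep(0, nc)),
      predictor = c(cases, controls), direction = ">", quiet = TRUE))
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  }
})

test_that("Hanley-McNeil interval behaves at the edges", {
  r <- roc_auc(c(1, 1, 2), c(8, 9, 10, 11), direction = "lower")
  expect_equal(r$auc, 1)
  expect_equal(r$ci[2], 1)   # clipped to the unit interval
  expect_gte(r$ci[1], 0)
})
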