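test_that("generated cohorts honor the stratification grid exactly", {
  cfg <- default_cfg()
  coh <- generate_normative(cfg, seed = 3)
  expect_equal(nrow(coh), 335)
  expect_equal(sum(coh$sex == "M"), 140)
  expect_equal(sum(coh$sex == "F"), 195)
  st <- cfg$stratification
  for (i in seq_len(nrow(st))) {
    got <- sum(coh$sex == st$sex[i] &
                 coh$age >= st$age_min[i] & coh$age <= st$age_max[i] &
                 coh$education >= st$edu_min[i] & coh$education <= st$edu_max[i])
    expect_equal(got, st$n[i])
  }
  expect_true(all(coh$age >= 18 & coh$age <= 96))
  expect_true(all(coh$education >= 4 & coh$education <= 23))
  validate_cohort(coh)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- default_cfg()
  a <- generate_normative(cfg, seed = 99)
  b <- generate_normative(cfg, seed = 99)
  attr(a, "latent") <- NULL; attr(b, "latent") <- NULL
  expect_identical(a, b)
  c_ <- generate_normative(cfg, seed = 100)
  expect_false(identical(a$pvf, c_$pvf))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_normative(cfg, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the noise-free limit collapses scores onto the demographic model", {
  cfg <- null_effect_cfg()
  for (m in names(cfg$measures)) cfg$measures[[m]]$residual_sd <- 1e-9
  coh <- generate_normative(cfg, seed = 8)
  lat <- attr(coh, "latent")
  for (tn in trial_names()) {
    expect_lt(diff(range(lat[, tn])), 1e-6)
  }
})

test_that("an empty grid is refused", {
  cfg <- default_cfg()
  cfg$stratification$n <- 0L
  expect_error(generate_normative(cfg, seed = 1), "empty stratification")
})

test_that("perfectly correlated paired modality reproduces the first administration", {
  coh <- generate_normative(default_cfg(), seed = 21)[1:47, ]
  p <- generate_paired_modality(coh, rho = 1, delta = 0, seed = 22)
  for (tn in trial_names()) expect_equal(p[[paste0(tn, "_ip")]], p[[tn]])
  expect_equal(sort(unique(p$order)), c("in_person_first", "telephone_first"))
  expect_error(generate_paired_modality(coh, rho = 1.2), "\\[-1, 1\\]")
})

test_that("null-shift pairs behave like the null: NHST quiet, TOST powered as designed", {
  coh <- generate_normative(default_cfg(), seed = 31)[1:47, ]
  p_nhst <- numeric(500); equiv <- logical(500)
  for (r in 1:500) {
    p <- generate_paired_modality(coh, rho = 0.8, delta = 0, seed = 5000 + r)
    d <- p$pvf - p$pvf_ip
    p_nhst[r] <- t.test(d)$p.value
    equiv[r] <- tost_paired(d, dz = 0.5)$equivalent
  }
  expect_gte(mean(p_nhst > 0.05), 0.90)
  # analytic double-rejection power at n = 47, bounds at 0.5 SD, true 0
  crit <- sqrt(47) * 0.5 - qt(0.95, 46)
  pow <- 1 - 2 * pt(-crit, 46)
  expect_lt(abs(mean(equiv) - pow), 0.05)
})

test_that("rater disagreement drives inter-rater ICC as designed", {
  coh <- generate_normative(default_cfg(), seed = 41)[1:27, ]
  r0 <- generate_ratings(coh, disagreement_rate = 0, seed = 42)
  expect_equal(icc(r0[c("pvf", "pvf_r2")], model = "absolute")$icc, 1)
  expect_error(generate_ratings(coh, disagreement_rate = 1.5), "\\[0, 1\\]")
})

test_that("retest correlation is an exact latent-scale contract", {
  cfg <- default_cfg()
  cfg$stratification$n <- cfg$stratification$n * 2  # 670 rows
  coh <- generate_normative(cfg, seed = 51)[1:200, ]
  rt0 <- generate_retest(coh, rho = 0, seed = 52)
  expect_lt(abs(icc(rt0[c("pvf", "pvf_rt")], model = "consistency")$icc), 0.15)

  small <- coh[1:18, ]
  inside <- vapply(1:100, function(r) {
    rt <- generate_retest(small, rho = 0.9, seed = 6000 + r)
    est <- icc(rt[c("pvf", "pvf_rt")], model = "consistency")$icc
    est >= 0.6 && est <= 0.98
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("clinical shift controls diagnostic separation monotonically", {
  cfg <- default_cfg()
  coh <- generate_normative(cfg, seed = 61)
  cl0 <- generate_clinical(cfg, shift_es = 0, n = 100, seed = 62)
  expect_lt(abs(roc_auc(cl0$pvf, coh$pvf, direction = "lower")$auc - 0.5), 0.08)
  cl6 <- generate_clinical(cfg, shift_es = 6, n = 100, seed = 63)
  expect_gt(roc_auc(cl6$pvf, coh$pvf, direction = "lower")$auc, 0.99)
  expect_error(generate_clinical(cfg, shift_es = -1), ">= 0")
  expect_true(all(cl6$cohort == "clinical:mixed"))
})

test_that("word streams carry their ground-truth segmentation", {
  s <- generate_word_stream(5, c(3, 2), within = 0.9, between = 0.1)
  expect_equal(s$truth$n_clusters, 2)
  expect_equal(s$truth$switches, 1)
  expect_equal(s$truth$mean_cluster_size, 1.5)
  one <- generate_word_stream(6, 6)
  expect_equal(one$truth$switches, 0)
  singles <- generate_word_stream(4, rep(1, 4))
  expect_equal(singles$truth$n_clusters, 4)
  expect_equal(singles$truth$switches, 3)
  expect_equal(singles$truth$mean_cluster_size, 0)
  expect_error(generate_word_stream(5, c(3, 3)), "sum to n_words")
})
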