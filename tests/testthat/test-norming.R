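test_that("tolerance-limit ranks match the exact binomial construction", {
  tr <- tolerance_ranks(335)
  expect_equal(tr$otl_rank, 10L)
  expect_equal(tr$itl_rank, 24L)
  # too small a sample: even the minimum cannot bound the 5th centile
  expect_error(tolerance_ranks(20), "no valid tolerance-limit rank")
  expect_equal(pbinom(0, 20, 0.05), 0.95^20)  # the reason: 0.358 > 0.05
  # spot-check the brute-force oracle on assorted sizes
  for (n in c(59, 100, 335, 731, 1500)) {
    o <- oracle_tolerance_ranks(n)
    tr <- tolerance_ranks(n)
    expect_identical(c(otl = tr$otl_rank, itl = tr$itl_rank), o)
  }
  # doubling the sample never lowers the outer rank
  for (n in seq(100, 1000, by = 150)) {
    expect_gte(tolerance_ranks(2 * n)$otl_rank, tolerance_ranks(n)$otl_rank)
  }
})

test_that("stepwise selection finds the structure that generated the data", {
  cfg <- null_effect_cfg()
  cfg$measures$pvf_f$effects <- data.frame(
    predictor = "education", transform = "identity",
    coef = 0.58, center = 13.42)
  coh <- generate_normative(cfg, seed = 71)
  eq <- fit_adjustment(coh, "pvf_f")
  expect_true("education" %in% eq$terms$predictor)
  expect_false(any(c("age", "sex") %in% eq$terms$predictor))

  # no demographic effect at all: the empty equation, AS = RS
  # (a strict entry threshold keeps the null case deterministic in spirit:
  # at 0.05 a spurious term would still enter ~14% of the time)
  coh0 <- generate_normative(null_effect_cfg(), seed = 72)
  eq0 <- fit_adjustment(coh0, "pvf_f", selection_alpha = 0.001)
  expect_equal(nrow(eq0$terms), 0)
  expect_equal(adjust_cohort(coh0, eq0), coh0$pvf_f)
})

test_that("the noise-free regression limit is recovered to six significant digits", {
  cfg <- null_effect_cfg()
  cfg$measures$pvf_f$effects <- data.frame(
    predictor = "education", transform = "identity",
    coef = 0.581857, center = 13.41791)
  for (m in names(cfg$measures)) cfg$measures[[m]]$residual_sd <- 1e-9
  coh <- generate_normative(cfg, seed = 73)
  coh$y <- attr(coh, "latent")[, "pvf_f"]  # un-discretized scores
  eq <- fit_adjustment(coh, "y",
                       candidate_transforms = list(education = "identity"))
  expect_equal(eq$terms$coef, 0.581857, tolerance = 1e-6)
})

test_that("degenerate fits are refused with a reason", {
  coh <- generate_normative(default_cfg(), seed = 74)
  coh$flat <- 7
  expect_error(fit_adjustment(coh, "flat"), "constant")
  expect_error(fit_adjustment(coh[1:30, ], "pvf"), "at least 50")
  coh$edu2 <- coh$pvf
  expect_error(fit_adjustment(coh, "pvf", min_n = 50,
                              candidate_transforms = list(education = "identity")),
               NA)  # a clean single-term fit still works
})

test_that("published adjustment equations evaluate as printed", {
  cards <- published_norm_cards()
  # letter-F phonemic trial: AS = RS - 0.581857 * (edu - 13.41791)
  as_ <- adjust_score(cards$pvf_f$equation, rs = 10, education = 8)
  expect_equal(as_, 10 - 0.581857 * (8 - 13.41791), tolerance = 1e-12)
  expect_equal(round(as_, 3), 13.152)
  # sex term: equal-demographic M vs F differ by twice the printed constant
  eq_col <- cards$svf_col$equation
  m <- adjust_score(eq_col, 15, age = 50, education = 13, sex = "M")
  f <- adjust_score(eq_col, 15, age = 50, education = 13, sex = "F")
  expect_equal(m - f, 2 * 0.549597, tolerance = 1e-12)
  # centering identity: at the normative means the adjustment vanishes
  eq <- cards$pvf_f$equation
  expect_equal(adjust_score(eq, 20, education = 13.41791), 20, tolerance = 1e-9)
  # a missing demographic that the equation needs is an error
  expect_error(adjust_score(eq_col, 15, education = 13, sex = "M"),
               "needs demographic 'age'")
})

test_that("norm cards place their cut-points at the prescribed order statistics", {
  card <- derive_norm_card(1:335, measure = "toy")
  expect_equal(card$cuts, c(10, 46, 98, 168))
  expect_equal(card$otl, 10)
  expect_equal(card$itl, 24)
  expect_error(derive_norm_card(rep(5, 200)), "degenerate")
  expect_error(derive_norm_card(1:50), "at least 100")
})

test_that("Equivalent-Score bands are exhaustive, ordered and monotone", {
  set.seed(81)
  card <- derive_norm_card(rnorm(335, 50, 10), measure = "toy")
  expect_true(all(diff(card$cuts) > 0))
  expect_lte(card$otl, card$itl)
  grid <- seq(0, 100, length.out = 2000)
  es <- classify_es(card, grid)
  expect_true(all(es %in% 0:4))
  expect_true(all(diff(es) >= 0))          # monotone in the score
  expect_equal(sort(unique(es)), 0:4)      # every band is reachable
  expect_equal(names(classify_es(card, card$cuts[1])), "impaired")
  expect_equal(names(classify_es(card, card$cuts[4] + 1)), "normal")
})

test_that("tied scores trigger the widen-by-rank rule instead of empty bands", {
  x <- c(rep(1, 150), rep(2, 100), rep(3, 50), rep(4, 35))
  card <- derive_norm_card(x, measure = "tied")
  expect_equal(card$cuts, c(1, 2, 3, 4))
  expect_match(card$provenance, "widened by rank")
  # ties so extreme that no distinct value is left for a band are refused
  expect_error(derive_norm_card(c(rep(1, 300), rep(2, 35))), "degenerate")
})

test_that("norm cards survive a serialization round trip", {
  coh <- generate_normative(default_cfg(), seed = 91)
  eq <- fit_adjustment(coh, "svf")
  card <- derive_norm_card(adjust_cohort(coh, eq), equation = eq)
  path <- tempfile(fileext = ".json")
  write_norm_cards(list(card), path)
  back <- read_norm_cards(path)[[1]]
  grid <- seq(min(coh$svf) - 10, max(coh$svf) + 10, length.out = 10000)
  expect_identical(unname(classify_es(back, grid)),
                   unname(classify_es(card, grid)))
  expect_equal(back$otl, card$otl)
  expect_equal(back$equation$terms$coef, eq$terms$coef)
})

test_that("healthy cohorts are rarely classified as impaired, by construction", {
  cfg <- default_cfg()
  coh <- generate_normative(cfg, seed = 92)
  eq <- fit_adjustment(coh, "pvf")
  card <- derive_norm_card(adjust_cohort(coh, eq), equation = eq)
  es_self <- classify_es(card, adjust_cohort(coh, eq))
  # the outer limit sits at rank 10 of 335; ties at the cut (same raw score
  # and education) can only pull a few extra subjects into the band
  expect_gte(mean(es_self == 0), 10 / 335 - 1e-9)
  expect_lte(mean(es_self == 0), 0.05)
})
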