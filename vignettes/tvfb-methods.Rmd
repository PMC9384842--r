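---
title: "Norming a telephone-based verbal fluency battery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming a telephone-based verbal fluency battery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette describes the statistical machinery in `tvfb`: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic cohort generator does and does not emulate, and where
genuinely open design choices were settled.

## The battery and its scores

The battery comprises nine 60-second word-generation trials: three phonemic
(letter cues F, A, S), three semantic (colors, animals, fruits) and three
alternate trials in which the examinee alternates a letter-cued and a
category-cued word (A/colors, F/animals, S/fruits). Each subtest total (PVF,
SVF, AVF) is the sum of its three trial counts. The Composite Shifting Index

$$\mathrm{CSI} = \frac{\mathrm{AVF}}{(\mathrm{PVF}+\mathrm{SVF})/2}$$

measures the cost of shifting from single-cued to double-cued fluency: near 1
when alternating costs nothing, lower when it does. A total is defined only
when all three of its trials are present, and the CSI only when all three
totals are — a spoiled trial propagates as "undefined" rather than as a
silent zero, because a zero count is a legitimate (impaired) observation
while an absent one is not. Fractional inputs are accepted so that published
group means can flow through the same arithmetic; strict integer validation
is available behind a flag.

## Demographic adjustment

Raw scores are adjusted by a centered linear model on transformed
demographics,

$$AS = RS - \sum_j \beta_j\,\big(T_j(x_j) - \overline{T_j(x)}\big),$$

with age and education entering through one member of a fixed power family
(identity, square root, log10, reciprocal, square, cube) and sex sign-coded
(+1 male, −1 female, centered at zero) so its coefficient is the familiar
"±c" correction. Transforms are chosen per predictor by the largest absolute
marginal correlation with the raw score; predictors then enter by forward
selection with backward pruning, both gated at p < 0.05 on the partial
t-test (the threshold is a parameter). Centering constants are stored to
full precision with the equation so that `AS = RS` holds exactly at the
normative means.

Two numerical points deserve note. First, the power-family members are
nearly collinear (correlations above 0.99 between, say, age² and age³ over
an adult age range), so *which* family member gets selected is not stable
across samples even though the fitted adjustment surface is. The package
therefore treats transform identity as a modelling convenience, judges
collinearity on the condition number of the *standardized* design (refusing
above 10⁶), and the coefficient-recovery checks are run with the candidate
set restricted to the generating transforms — they test estimation, which
is identified, not family-member selection, which is not. Second, adjusted
scores are never re-rounded before threshold comparison; classification
uses `≤` on the stored boundary values.

## Tolerance limits and Equivalent Scores

Clinical cut-offs follow the Equivalent-Score tradition: instead of plugging
in the empirical 5th centile, the scale is anchored at nonparametric
tolerance limits obtained from the exact binomial distribution of the number
of observations below the population 5th centile. With $X \sim
\mathrm{Bin}(N, 0.05)$ and CDF $F$:

- the **outer tolerance limit** is the order statistic at the largest rank
  $r$ with $F(r-1) \le 0.05$ — with 95% confidence it lies *below* the true
  5th centile (the conservative side used for the impairment call);
- the **inner tolerance limit** is the order statistic at the largest rank
  $s$ with $F(s-1) < 0.95$ — the highest rank still compatible, at 95%
  confidence, with lying at or below that centile. It is reported on every
  card but plays no role in classification.

At N = 335 these are ranks 10 and 24. No rank exists below N = 59 (since
$0.95^N > 0.05$); the package raises an explicit no-limit error rather than
returning a pseudo-rank.

The five Equivalent-Score bands are bounded by order statistics at
cumulative probabilities obtained by splitting the standard-normal interval
from the 5th centile's z to the median into three equal segments: 0.05,
0.1364, 0.2917, 0.50, with rank = ⌈N·c⌉ and the ES0/ES1 boundary pinned to
the outer tolerance limit. This equal-z partition is the published rule in
the tradition the battery's norms follow; it reproduces the qualitative
structure of the battery's printed grid (the ES1 band extends beyond the
inner limit; ES4 starts at the median). If ties would leave a band empty,
its upper cut widens to the next distinct order statistic and the card's
provenance records the fact; an all-tied sample is refused as degenerate.
Bands partition the real line, so classification is total and monotone.

## Equivalence testing and design arithmetic

Telephone/in-person agreement is judged by the paired TOST: with differences
$d_i$, bounds $\pm\Delta = \pm d_z\,\mathrm{SD}(d)$ (default $d_z = 0.5$,
the convention of the tool family the battery's design used; raw-unit
bounds are accepted too), the two one-sided statistics are
$t_{low} = (\bar d + \Delta)/SE$ and $t_{up} = (\bar d - \Delta)/SE$ with
$df = n - 1$, and the TOST p is the larger one-sided p; equivalence is
declared below α = 0.05. The ordinary paired t-test is always reported
alongside, since "not significantly different" and "significantly
equivalent" answer different questions.

The design-stage pair count uses the closed-form normal approximation
$n = \lceil ((z_{1-\alpha} + z_{1-\beta/2})/d_z)^2 \rceil$, which gives the
conventional n = 44 at $d_z = 0.5$, α = 0.05, power 0.90; an exact central-t
iteration is available and lands at 44–46 depending on the target. The
regression sample size iterates the noncentral-F power function with
noncentrality λ = f²·N; conventions for λ and rounding differ across
published tools, so counts may differ by a subject or two from other
software (this one returns 288 for f² = 0.05, u = 3, power 0.90).

## Reliability, validity, diagnostics

Correlations are normality-gated: product-moment when both variables have
|skewness| < 1 and |excess kurtosis| < 3 (SPSS-type bias-corrected
estimators; the excess convention, normal = 0, is deliberate and documented
because the raw-kurtosis reading of the same rule would gate almost
nothing), Spearman otherwise. Bonferroni families are explicit parameters —
the package never guesses a family size.

ICCs come from the two-way ANOVA mean squares, single-measure form:
consistency $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$ for test-retest (a stable
practice effect should not count against a test), absolute agreement (which
additionally charges the rater/occasion mean square) for inter-rater
reliability. Confidence intervals are the standard F constructions, with
the Satterthwaite approximation for the agreement form. Cronbach's α uses
the variance form of the closed formula. The component analysis
eigen-decomposes the correlation matrix, retains eigenvalues above 1, and
reports loadings as eigenvectors scaled by the root eigenvalues.

ROC analysis takes "lower score = more abnormal" as its default
orientation, computes the AUC as the normalized rank-sum with ties counted
one half, and attaches the Hanley–McNeil standard error with a Wald
interval clipped to [0, 1]. The AUC is reported exactly as computed under
the stated orientation — no silent flipping — so the pairwise-counting
identity holds verbatim.

## Cluster and switch scoring

Word streams are segmented greedily left to right: a new cluster opens
whenever the semantic relatedness of the *adjacent* pair falls below θ
(default 0.5 on a [0, 1]-normalized scale; the chain rule is the simplest
scheme consistent with "transitions between clusters", and θ is exposed
because no canonical value exists). Switches are clusters minus one per
trial, summed across trials; cluster size is run length minus one, averaged
over clusters (the raw-length convention is available). Relatedness is an
interface — a labelled similarity matrix or an embedding table under cosine
similarity — so any semantic space satisfying symmetry and unit
self-similarity plugs in; training such a space is out of scope. Unknown
word pairs are an error naming the pair, never a default similarity.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, with
known ground truth, at the study's own design points. Its packaged default
encodes: the 335-slot stratification grid (sex × six age bands 18–96 × five
education bands 4–23), demographics drawn uniformly within each cell's
band; per-trial latent scores equal to a linear predictor in transformed
demographics (the adjustment equations sign-flipped into generative form,
with their published centering constants) plus Gaussian noise split into a
shared subject factor (loading 0.77) and a unique part; truncation at zero
and rounding to integer counts as the final step. Residual SDs were fixed
once, before any testing, as √(target SD² − demographic variance) so that
generated score SDs match the normative table. Totals are computed from the
generated trials (never drawn separately), so scoring invariants hold by
construction.

Replicates correlate on the *full* latent score: the retest or
second-modality latent is drawn around the first with correlation ρ and
optional shift δ, standardized against the cohort's latent moments. This
makes ρ an exact correlation contract — at ρ = 0 the replicate is
independent of the original *including* its demographic component, which is
what a test-retest ICC near zero requires. It is a statistical contract,
not a causal model of repeated testing. Rater replicates instead perturb
observed counts directly (±1 word with a small probability per trial),
because rater disagreement is a transcription phenomenon, not a latent one.
Clinical cohorts lower each trial's latent by `shift_es` *residual* SDs:
the shift is thereby a standardized effect size on the
demographics-removed scale, and diagnostic checks accordingly evaluate
adjusted scores, where a 1.5-SD deficit implies AUC ≈ Φ(1.5/√2) ≈ 0.86
regardless of the demographic mix. Word-stream fixtures are built from
block-structured similarity matrices with the true segmentation attached.

What the generator does **not** emulate: real lexical content (tokens are
synthetic labels), occupation/region covariates, order effects in the
counterbalanced modality design (orders are labelled but exchangeable),
non-Gaussian score shapes, floor/ceiling compression beyond the zero
truncation, and any dependence of retest noise on ability. Tests passing on
these cohorts therefore certify the *machinery* — selection, limits,
classification, test statistics — under the stated model, not the empirical
values of any particular population; data-dependent published quantities
(α = 0.91, specific ICCs and AUCs) define target regimes, not point
targets.

With the default loading of 0.77 the nine trials share pairwise latent
correlation 0.77² ≈ 0.59, so the leading component of the adjusted trial
scores carries about (1 + 8·0.59)/9 ≈ 64% of the variance — a
mono-component battery in the published spirit, and the band the structure
tests check.

## Problem sizes and determinism

Every generator and the pipeline are pure functions of (configuration,
seed); the master seed fans out through fixed per-stage substreams, and the
caller's RNG state is always restored. The simulation-based checks use
sizes chosen to keep Monte-Carlo error well inside the asserted margins:
200 replicates of the N = 335 cohort for coefficient recovery and for the
clinical-AUC regime, 2,000 replicates for TOST power and type-I error
(binomial SE ≈ 0.007), 500 for the paired-null checks, a tenfold cohort for
impairment rates, and exhaustive scans elsewhere (tolerance ranks over
N = 50–2000, pairwise AUC counting at n ≤ 50).

## Known limitations

- Stepwise selection at a fixed α is kept because it is the procedure the
  norming tradition prescribes, not because it is optimal; with three
  candidate predictors its false-inclusion rate at α = 0.05 is ≈ 14% under
  the null, and users wanting a confirmatory fit should restrict
  `candidate_transforms` to a pre-specified form.
- The equal-z band partition is one defensible reading of the Equivalent
  Score construction; published grids derived under slightly different
  banding conventions will disagree near cut-points even when the
  tolerance limits agree exactly.
- The ICC interval for absolute agreement is approximate (Satterthwaite
  df); at n below ~10 its coverage is nominal only roughly.
- CSI norms inherit the ratio's skew; the gate usually routes CSI
  correlations to Spearman, and its ES bands are materially asymmetric.
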