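# Paired two-one-sided-tests (TOST) equivalence machinery and the
# design-stage sample-size calculators that accompany it.

#' Two-sided (or one-sided) p-value from a t statistic
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (>= 1).
#' @param tails 2 (default) for the two-sided p, 1 for the upper-tail p of
#'   `|t|`.
#' @return The central-t tail probability.
#' @examples
#' p_from_t(1.45, 46) # ~0.154
#' @export
p_from_t <- function(t, df, tails = 2) {
  if (any(df < 1)) stop("df must be >= 1")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  tails * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Paired-samples TOST equivalence test
#'
#' Two one-sided tests against equivalence bounds placed at `dz` standard
#' deviations of the paired differences (or at explicit raw bounds): the mean
#' difference is declared equivalent to zero when it is significantly above
#' the lower bound *and* significantly below the upper bound, i.e. when the
#' larger of the two one-sided p-values is below `alpha`. The conventional
#' paired t-test (NHST) is reported alongside.
#'
#' Accepts either the raw paired differences or their summary statistics;
#' both routes give identical results.
#'
#' @param differences Numeric vector of paired differences (alternative to
#'   the summary triple).
#' @param n,mean_diff,sd_diff Summary statistics of the differences.
#' @param dz Standardized half-width of the equivalence region (default 0.5);
#'   the raw bounds are `c(-1, 1) * dz * sd_diff`.
#' @param bounds_raw Optional explicit raw bounds `c(lower, upper)`,
#'   overriding `dz`.
#' @param alpha One-sided level of each test (default 0.05).
#' @return A `tost_result`: list with `n`, `mean_diff`, `sd_diff`, `se`,
#'   `df`, `t_nhst`, `p_nhst`, `dz`, `bounds` (raw), `t_lower`, `p_lower`,
#'   `t_upper`, `p_upper`, `p_tost` (the max one-sided p) and `equivalent`.
#' @examples
#' tost_paired(n = 47, mean_diff = 0.9, sd_diff = 9.79)
#' @export
tost_paired <- function(differences = NULL, n = NULL, mean_diff = NULL,
                        sd_diff = NULL, dz = 0.5, bounds_raw = NULL,
                        alpha = 0.05) {
  if (!is.null(differences)) {
    differences <- stats::na.omit(differences)
    n <- length(differences)
    mean_diff <- mean(differences)
    sd_diff <- stats::sd(differences)
  }
  if (is.null(n) || is.null(mean_diff) || is.null(sd_diff)) {
    stop("supply either 'differences' or all of n, mean_diff, sd_diff")
  }
  if (n < 3) stop("need at least 3 pairs")
  if (sd_diff <= 0) stop("degenerate differences: sd_diff must be > 0")
  if (is.null(bounds_raw)) {
    if (dz <= 0) stop("invalid equivalence bounds: dz must be > 0")
    bounds_raw <- c(-1, 1) * dz * sd_diff
  } else {
    if (length(bounds_raw) != 2 || bounds_raw[1] >= bounds_raw[2]) {
      stop("bounds_raw must be c(lower, upper) with lower < upper")
    }
    dz <- (bounds_raw[2] - bounds_raw[1]) / (2 * sd_diff)
  }
  df <- n - 1
  se <- sd_diff / sqrt(n)
  t_nhst <- mean_diff / se
  t_lower <- (mean_diff - bounds_raw[1]) / se  # H0: diff <= lower bound
  t_upper <- (mean_diff - bounds_raw[2]) / se  # H0: diff >= upper bound
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  structure(list(n = n, mean_diff = mean_diff, sd_diff = sd_diff, se = se,
                 df = df, t_nhst = t_nhst, p_nhst = p_from_t(t_nhst, df),
                 dz = dz, bounds = bounds_raw,
                 t_lower = t_lower, p_lower = p_lower,
                 t_upper = t_upper, p_upper = p_upper,
                 p_tost = p_tost, alpha = alpha,
                 equivalent = p_tost < alpha),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("Paired TOST (n = %d, df = %d)\n", x$n, x$df))
  cat(sprintf("  mean diff %.3f (SD %.3f); NHST t = %.3f, p = %.4f\n",
              x$mean_diff, x$sd_diff, x$t_nhst, x$p_nhst))
  cat(sprintf("  bounds [%.3f, %.3f] (dz = %.2f): lower t = %.3f p = %.4g; upper t = %.3f p = %.4g\n",
              x$bounds[1], x$bounds[2], x$dz, x$t_lower, x$p_lower,
              x$t_upper, x$p_upper))
  cat(sprintf("  TOST p = %.4g -> %s at alpha = %g\n", x$p_tost,
              if (x$equivalent) "equivalent" else "not equivalent", x$alpha))
  invisible(x)
}

#' Sample size for a paired TOST design
#'
#' Pairs needed to declare equivalence with the requested power when the
#' true standardized difference is zero and the bounds sit at `dz` SDs of
#' the differences. The default is the closed-form normal approximation
#' `n = ceiling(((z[1 - alpha] + z[1 - beta/2]) / dz)^2)`; the `"exact"`
#' mode instead iterates the central-t power of the double rejection region
#' and is typically 0-2 pairs larger.
#'
#' @param dz Standardized equivalence half-width (> 0).
#' @param alpha One-sided level of each test.
#' @param power Target probability of declaring equivalence (0-1).
#' @param method `"normal"` (default, closed form) or `"exact"` (iterative
#'   central-t).
#' @return Integer number of pairs.
#' @examples
#' tost_sample_size(0.5, 0.05, 0.90) # 44
#' @export
tost_sample_size <- function(dz, alpha = 0.05, power = 0.90,
                             method = c("normal", "exact")) {
  if (dz <= 0) stop("dz must be > 0")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  method <- match.arg(method)
  if (method == "normal") {
    n <- ceiling(((stats::qnorm(1 - alpha) +
                     stats::qnorm(1 - (1 - power) / 2)) / dz)^2)
    return(as.integer(n))
  }
  n <- 3L
  repeat {
    crit <- sqrt(n) * dz - stats::qt(1 - alpha, n - 1)
    pw <- if (crit <= 0) 0 else 1 - 2 * stats::pt(-crit, n - 1)
    if (pw >= power) return(n)
    n <- n + 1L
    if (n > 1e6) stop("no attainable n below 1e6")
  }
}

#' Sample size for a multiple-regression F test
#'
#' Smallest total `N = u + v + 1` whose noncentral-F power (numerator df
#' `u`, denominator df `v = N - u - 1`, noncentrality `f2 * N`) reaches the
#' requested power at level `alpha`. Conventions differ across tools in the
#' noncentrality definition and rounding, so published values may differ by
#' one or two subjects from this count.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param u Numerator degrees of freedom (number of tested predictors).
#' @param alpha Type-I error rate.
#' @param power Target power.
#' @return Integer total sample size.
#' @export
regression_sample_size <- function(f2, u, alpha = 0.05, power = 0.90) {
  if (f2 <= 0) stop("f2 must be > 0")
  if (u < 1) stop("u must be >= 1")
  n <- as.integer(u + 2)
  repeat {
    v <- n - u - 1
    pw <- stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = f2 * n,
                    lower.tail = FALSE)
    if (pw >= power) return(n)
    n <- n + 1L
    if (n > 1e6) stop("no attainable N below 1e6")
  }
}
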