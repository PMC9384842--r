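# Reliability and validity statistics: normality-gated correlations,
# Bonferroni adjustment, Cronbach's alpha, ANOVA-based intraclass
# correlations, principal-component structure and ROC/AUC.

#' Bonferroni-adjusted significance level
#'
#' @param alpha Familywise level (default 0.05).
#' @param m Number of comparisons in the family.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Normality-gated correlation
#'
#' Product-moment (Pearson) correlation when both variables pass the
#' normality gate — absolute skewness below 1 and absolute *excess* kurtosis
#' below 3 (SPSS-style bias-corrected estimators; excess kurtosis is zero
#' for a normal distribution) — and rank (Spearman) correlation otherwise.
#'
#' @param x,y Numeric vectors (at least 4 complete pairs).
#' @param alpha_adjusted Significance level after any multiplicity
#'   adjustment, e.g. [bonferroni_alpha()].
#' @param label Optional pair label carried on the report.
#' @return A `correlation_report`: list with `label`, `method`
#'   (`"product-moment"` or `"rank"`), `estimate`, `p`, `alpha_adjusted`,
#'   `significant` and the gate moments (`skewness`, `ex_kurtosis` per
#'   variable).
#' @export
gated_correlation <- function(x, y, alpha_adjusted = 0.05, label = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  sk <- c(x = e1071::skewness(x, type = 2), y = e1071::skewness(y, type = 2))
  ku <- c(x = e1071::kurtosis(x, type = 2), y = e1071::kurtosis(y, type = 2))
  normal_ok <- all(abs(sk) < 1) && all(abs(ku) < 3)
  method <- if (normal_ok) "product-moment" else "rank"
  ct <- if (normal_ok) {
    stats::cor.test(x, y, method = "pearson")
  } else {
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  }
  structure(list(label = label, method = method,
                 estimate = unname(ct$estimate), p = ct$p.value,
                 alpha_adjusted = alpha_adjusted,
                 significant = ct$p.value < alpha_adjusted,
                 skewness = sk, ex_kurtosis = ku, n = length(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s correlation%s: r = %.3f, p = %.4g (n = %d)%s\n",
              x$method,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$estimate, x$p, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total))`.
#'
#' @param item_matrix Numeric matrix or data frame, subjects in rows and at
#'   least two item columns, three subjects.
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("need at least 2 items")
  if (nrow(x) < 3) stop("need at least 3 subjects")
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("zero total variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Intraclass correlation (two-way, single measure)
#'
#' ANOVA mean-squares ICC for a complete subjects-by-raters (or
#' subjects-by-occasions) table: the consistency form ICC(C,1) =
#' `(MSR - MSE) / (MSR + (k - 1) MSE)` ignores systematic rater/occasion
#' offsets; the absolute-agreement form ICC(A,1) additionally penalizes them
#' through the rater mean square. Confidence intervals use the standard
#' F-based constructions (exact for consistency; the Satterthwaite-df
#' approximation for agreement).
#'
#' @param ratings Numeric matrix or data frame, `n >= 5` subjects in rows,
#'   `k >= 2` raters/occasions in columns, no missing cells.
#' @param model `"consistency"` or `"absolute"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `icc_result`: list with `model`, `icc`, `ci`, the mean squares
#'   (`msr`, `msc`, `mse`) and `n`, `k`.
#' @export
icc <- function(ratings, model = c("consistency", "absolute"),
                conf_level = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings must be complete (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters/occasions")
  row_means <- rowMeans(x); col_means <- colMeans(x); grand <- mean(x)
  if (stats::var(row_means) == 0) {
    stop("zero between-subject variance: ICC undefined")
  }
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (model == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Satterthwaite df for the rater+error composite (McGraw & Wong)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  structure(list(model = model, icc = est, ci = pmin(pmax(ci, -1), 1),
                 conf_level = conf_level,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measure): %.3f, %g%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$model, x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Principal-component structure of a score matrix
#'
#' Eigen-decomposition of the correlation matrix; components with
#' eigenvalue above 1 are retained, and loadings are the eigenvectors
#' scaled by the square roots of their eigenvalues (sign-normalized so each
#' retained component loads positively on balance).
#'
#' @param score_matrix Numeric matrix or data frame, more subjects than the
#'   `>= 3` variables.
#' @return A `pca_structure`: list with `eigenvalues`, `prop_variance`,
#'   `n_retained`, `loadings` (variables x retained components) and
#'   `explained_retained` (proportion of variance carried by the retained
#'   components).
#' @export
pca_structure <- function(score_matrix) {
  x <- as.matrix(score_matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 3) stop("need at least 3 variables")
  if (nrow(x) <= ncol(x)) stop("need more subjects than variables")
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant variable: drop it before the PCA")
  }
  cm <- stats::cor(x)
  ev <- eigen(cm, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    stop("singular correlation matrix: drop collinear measures and refit")
  }
  retained <- which(ev$values > 1)
  load <- ev$vectors[, retained, drop = FALSE] %*%
    diag(sqrt(ev$values[retained]), length(retained))
  for (j in seq_len(ncol(load))) {
    if (sum(load[, j]) < 0) load[, j] <- -load[, j]
  }
  if (length(retained) > 0) {
    dimnames(load) <- list(colnames(x), paste0("PC", retained))
  }
  structure(list(eigenvalues = ev$values,
                 prop_variance = ev$values / ncol(x),
                 n_retained = length(retained),
                 loadings = load,
                 explained_retained = sum(ev$values[retained]) / ncol(x)),
            class = "pca_structure")
}

#' @export
print.pca_structure <- function(x, ...) {
  cat(sprintf("PCA: %d component(s) retained (eigenvalue > 1), %.1f%% of variance\n",
              x$n_retained, 100 * x$explained_retained))
  cat("  loadings range:", paste(round(range(x$loadings), 2), collapse = " to "), "\n")
  invisible(x)
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' The AUC is the normalized rank-sum (Mann-Whitney) statistic: the
#' probability that a randomly drawn case scores more abnormally than a
#' randomly drawn control, counting ties as one half. With
#' `direction = "lower"` (the default for ability scores, where patients
#' score low) "more abnormally" means lower. The standard error uses the
#' Hanley-McNeil formula and the 95% interval is Wald, clipped to `[0, 1]`.
#'
#' @param case_scores,control_scores Scores of cases (patients) and controls.
#' @param direction `"lower"` if abnormality lowers the score, `"higher"`
#'   otherwise.
#' @param conf_level Confidence level (default 0.95).
#' @return A `roc_report`: list with `auc`, `se`, `ci`, `n_cases`,
#'   `n_controls`, `direction`.
#' @export
roc_auc <- function(case_scores, control_scores,
                    direction = c("lower", "higher"), conf_level = 0.95) {
  direction <- match.arg(direction)
  case_scores <- stats::na.omit(case_scores)
  control_scores <- stats::na.omit(control_scores)
  na <- length(case_scores); nc <- length(control_scores)
  if (na < 1 || nc < 1) stop("need at least one case and one control")
  r <- rank(c(case_scores, control_scores))
  auc_higher <- (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nc)
  auc <- if (direction == "lower") 1 - auc_higher else auc_higher
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (na - 1) * (q1 - auc^2) +
                (nc - 1) * (q2 - auc^2)) / (na * nc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  structure(list(auc = auc, se = se, ci = ci, conf_level = conf_level,
                 n_cases = na, n_controls = nc, direction = direction),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, SE = %.3f, %g%% CI [%.3f, %.3f] (%d cases vs %d controls, %s-is-abnormal)\n",
              x$auc, x$se, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_cases, x$n_controls, x$direction))
  invisible(x)
}
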