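# Regression-based norming in the Equivalent-Score tradition: stepwise
# demographic adjustment, nonparametric (binomial) tolerance limits on the
# adjusted scores, and a five-band ordinal Equivalent-Score scale.

#' Fit a demographic adjustment equation by stepwise selection
#'
#' Selects, per predictor, the transform most correlated (in absolute value)
#' with the raw score, then runs forward selection with backward pruning over
#' the transformed predictors at `selection_alpha` (enter and stay thresholds
#' both `selection_alpha`, on the partial t-test p-value). The fitted
#' equation stores each coefficient with the cohort mean of its transformed
#' predictor as centering constant, so the adjusted score is
#' `AS = RS - sum(coef * (transform(x) - center))` and `AS = RS` for a
#' subject at the centering means. The sex term is sign-coded (+1 M, -1 F)
#' and centered at zero, yielding the conventional "+c if M; -c if F" form.
#'
#' @param cohort Cohort data frame with `age`, `education`, `sex` and the
#'   measure column; rows with missing values are dropped.
#' @param measure Name of the score column to adjust.
#' @param candidate_transforms Named list of candidate transform names per
#'   predictor (default [default_transform_grid()]). Restrict it to fit a
#'   pre-specified functional form.
#' @param selection_alpha Entry/stay p-value threshold (default 0.05).
#' @param min_n Minimum complete rows required (default 50).
#' @param max_condition Condition-number threshold above which the selected
#'   design is refused as collinear.
#' @return An `adjustment_equation`: list with `measure`, `terms` (data frame
#'   `predictor`, `transform`, `coef`, `center`, `se`, `ci_lo`, `ci_hi`),
#'   `n`, `sigma` (residual SD) and `r_squared`. `terms` has zero rows when
#'   no predictor clears the threshold (then `AS = RS`).
#' @export
fit_adjustment <- function(cohort, measure,
                           candidate_transforms = default_transform_grid(),
                           selection_alpha = 0.05,
                           min_n = 50, max_condition = 1e6) {
  need <- c("age", "education", "sex", measure)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- cohort[stats::complete.cases(cohort[need]), need]
  if (nrow(d) < min_n) {
    stop("need at least ", min_n, " complete rows; got ", nrow(d))
  }
  y <- d[[measure]]
  if (stats::sd(y) == 0) {
    stop("score column '", measure, "' is constant; no model can be fitted")
  }

  # One candidate column per predictor: the transform with the largest
  # absolute marginal correlation with the raw score.
  cand <- list()
  for (pred in names(candidate_transforms)) {
    x_raw <- d[[.predictor_column(pred)]]
    best <- NULL
    for (tr in candidate_transforms[[pred]]) {
      xt <- apply_transform(tr, x_raw)
      if (stats::sd(xt) == 0) next
      r <- abs(stats::cor(xt, y))
      if (is.null(best) || r > best$r) best <- list(tr = tr, x = xt, r = r)
    }
    if (!is.null(best)) {
      cand[[pred]] <- list(transform = best$tr,
                           center = if (pred == "sex") 0 else mean(best$x),
                           x = best$x - if (pred == "sex") 0 else mean(best$x))
    }
  }

  selected <- character(0)
  fit_terms <- function(terms) {
    df <- data.frame(lapply(cand[terms], `[[`, "x"))
    names(df) <- terms
    df$.y <- y
    stats::lm(.y ~ ., data = df)
  }
  term_p <- function(fit) {
    cf <- summary(fit)$coefficients
    stats::setNames(cf[-1, 4], rownames(cf)[-1])
  }
  repeat {
    changed <- FALSE
    # forward step: best admissible candidate
    pool <- setdiff(names(cand), selected)
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(pred) {
        term_p(fit_terms(c(selected, pred)))[[pred]]
      }, numeric(1))
      if (any(pvals < selection_alpha)) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward step: prune anything no longer significant
    if (length(selected) > 1) {
      p <- term_p(fit_terms(selected))
      worst <- which.max(p)
      if (p[worst] >= selection_alpha) {
        selected <- setdiff(selected, names(p)[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(selected) == 0) {
    eq <- list(measure = measure,
               terms = data.frame(predictor = character(0),
                                  transform = character(0),
                                  coef = numeric(0), center = numeric(0),
                                  se = numeric(0), ci_lo = numeric(0),
                                  ci_hi = numeric(0)),
               n = nrow(d), sigma = stats::sd(y), r_squared = 0)
    class(eq) <- "adjustment_equation"
    return(eq)
  }

  fit <- fit_terms(selected)
  X <- stats::model.matrix(fit)
  X[, -1] <- scale(X[, -1])  # judge collinearity net of column scaling
  if (kappa(X, exact = TRUE) > max_condition) {
    stop("selected terms are collinear (condition number above ",
         format(max_condition), "); refusing to fit")
  }
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  tcrit <- stats::qt(0.975, fit$df.residual)
  eq <- list(
    measure = measure,
    terms = data.frame(
      predictor = selected,
      transform = vapply(cand[selected], `[[`, "", "transform"),
      coef = unname(cf[, 1]),
      center = vapply(cand[selected], `[[`, 0, "center"),
      se = unname(cf[, 2]),
      ci_lo = unname(cf[, 1] - tcrit * cf[, 2]),
      ci_hi = unname(cf[, 1] + tcrit * cf[, 2]),
      stringsAsFactors = FALSE, row.names = NULL),
    n = nrow(d), sigma = sm$sigma, r_squared = sm$r.squared)
  class(eq) <- "adjustment_equation"
  eq
}

#' @export
print.adjustment_equation <- function(x, ...) {
  cat("Adjustment equation for", x$measure,
      sprintf("(n = %d, R^2 = %.3f)\n", x$n, x$r_squared))
  if (nrow(x$terms) == 0) {
    cat("  AS = RS (no demographic term selected)\n")
  } else {
    rhs <- paste(sprintf("%+g*(%s(%s) - %g)", -x$terms$coef,
                         x$terms$transform, x$terms$predictor,
                         x$terms$center), collapse = " ")
    cat("  AS = RS", rhs, "\n")
  }
  invisible(x)
}

#' Demographically adjust raw scores
#'
#' Evaluates a stored adjustment equation:
#' `AS = RS - sum(coef * (transform(x) - center))`.
#'
#' @param equation An `adjustment_equation` (from [fit_adjustment()] or a
#'   norm card).
#' @param rs Raw score(s).
#' @param age,education Demographics in years (required when the equation
#'   uses them).
#' @param sex `"M"`/`"F"` (required when the equation has a sex term).
#' @return Adjusted score(s), same length as `rs`.
#' @export
adjust_score <- function(equation, rs, age = NULL, education = NULL,
                         sex = NULL) {
  terms <- equation$terms
  as_ <- rs
  if (is.null(terms) || nrow(terms) == 0) return(as_)
  for (i in seq_len(nrow(terms))) {
    x <- switch(terms$predictor[i], age = age, education = education,
                sex = sex)
    if (is.null(x) || anyNA(x)) {
      stop("equation for ", equation$measure, " needs demographic '",
           terms$predictor[i], "'")
    }
    as_ <- as_ - terms$coef[i] *
      (apply_transform(terms$transform[i], x) - terms$center[i])
  }
  as_
}

#' Adjust a whole cohort column
#'
#' @param cohort Cohort data frame.
#' @param equation An `adjustment_equation` for a measure present in the
#'   cohort.
#' @param score_col Column holding the raw scores (defaults to the equation's
#'   measure).
#' @return The adjusted scores as a numeric vector.
#' @export
adjust_cohort <- function(cohort, equation, score_col = equation$measure) {
  adjust_score(equation, cohort[[score_col]],
               age = cohort$age, education = cohort$education,
               sex = cohort$sex)
}

#' Nonparametric tolerance-limit ranks
#'
#' Ranks of the order statistics bounding the population `p`-th centile at
#' the given confidence, from the exact binomial distribution of the number
#' of observations below that centile. The outer limit (conservative side)
#' is the largest rank `r` whose order statistic is, with at least the stated
#' confidence, below the centile: the largest `r` with
#' `pbinom(r - 1, n, p) <= 1 - confidence`. The inner limit
#' (anticonservative side) is the largest rank still compatible, at the
#' stated confidence, with lying at or below the centile: the largest `s`
#' with `pbinom(s - 1, n, p) < confidence`.
#'
#' @param n Sample size.
#' @param p Centile being bounded (default 0.05).
#' @param confidence Confidence level (default 0.95).
#' @return List with integer `otl_rank` and `itl_rank`.
#' @examples
#' tolerance_ranks(335) # ranks 10 and 24
#' @export
tolerance_ranks <- function(n, p = 0.05, confidence = 0.95) {
  stopifnot(n >= 1, p > 0, p < 1, confidence > 0, confidence < 1)
  r <- seq_len(n)
  cdf_below <- stats::pbinom(r - 1, n, p)
  ok <- which(cdf_below <= 1 - confidence)
  if (length(ok) == 0) {
    stop("no valid tolerance-limit rank at n = ", n,
         ": even the minimum has P(all above centile) = ",
         format(cdf_below[1], digits = 3), " > ", format(1 - confidence))
  }
  list(otl_rank = max(ok), itl_rank = max(which(cdf_below < confidence)))
}

# Cumulative probabilities of the ES band boundaries: the standard-normal
# interval from the p-th centile's z to the median, split into three equal
# z-width segments.
.es_cum_probs <- function(p = 0.05) {
  z0 <- stats::qnorm(p)
  stats::pnorm(c(z0, 2 * z0 / 3, z0 / 3, 0))
}

#' Derive a norm card from adjusted scores
#'
#' Computes the outer/inner tolerance limits as the order statistics at
#' [tolerance_ranks()] and the Equivalent-Score cut-points as order
#' statistics at the ranks `ceiling(n * c)` for cumulative probabilities `c`
#' splitting the z-interval from the `p`-th centile to the median into three
#' equal segments (0.05, 0.136, 0.292, 0.50 at the defaults). The ES0/ES1
#' boundary is the outer tolerance limit; the ES4 band starts above the
#' sample median. If ties make a band empty, its upper cut is widened to the
#' next distinct order statistic and the tie is noted in the card's
#' provenance.
#'
#' @param adjusted_scores Numeric vector of at least 100 adjusted scores.
#' @param equation Optional `adjustment_equation` stored on the card so it
#'   can classify raw scores later.
#' @param measure Measure name (defaults to the equation's).
#' @param p,confidence Tolerance-limit parameters.
#' @return A `norm_card`: list with `measure`, `equation`, `n`, `otl`, `itl`,
#'   `cuts` (upper bounds of bands ES0-ES3) and `provenance`.
#' @export
derive_norm_card <- function(adjusted_scores, equation = NULL,
                             measure = if (!is.null(equation)) equation$measure else "score",
                             p = 0.05, confidence = 0.95) {
  x <- stats::na.omit(as.numeric(adjusted_scores))
  if (length(x) < 100) stop("need at least 100 adjusted scores")
  if (max(x) == min(x)) stop("degenerate card: all adjusted scores identical")
  n <- length(x)
  xs <- sort(x)
  tr <- tolerance_ranks(n, p = p, confidence = confidence)
  ranks <- ceiling(n * .es_cum_probs(p))
  ranks[1] <- tr$otl_rank  # ES0/ES1 boundary sits at the outer limit
  cuts <- xs[ranks]
  prov <- sprintf("derived from %d adjusted scores (p = %g, confidence = %g)",
                  n, p, confidence)
  # widen-by-rank tie rule: every band must contain at least one distinct value
  for (k in 2:4) {
    if (cuts[k] <= cuts[k - 1]) {
      higher <- xs[xs > cuts[k - 1]]
      if (length(higher) == 0) stop("degenerate card: ties exhaust the scale")
      cuts[k] <- higher[1]
      prov <- paste0(prov, "; tie at band ", k - 1, "/", k,
                     " widened by rank")
    }
  }
  structure(list(measure = measure, equation = equation, n = n,
                 otl = cuts[1], itl = xs[tr$itl_rank], cuts = cuts,
                 provenance = prov),
            class = "norm_card")
}

#' Equivalent-Score labels
#'
#' @return Named character vector mapping ES 0-4 to their clinical labels.
#' @export
es_labels <- function() {
  c(`0` = "impaired", `1` = "borderline", `2` = "low-end normal",
    `3` = "normal", `4` = "normal")
}

#' Classify adjusted scores into Equivalent Scores
#'
#' Band lookup against a norm card: scores at or below the outer tolerance
#' limit are ES 0 (impaired); scores above the last cut are ES 4 (at/above
#' the normative median). Comparisons use `<=` on the stored cut values;
#' adjusted scores are not re-rounded first.
#'
#' @param norm_card A `norm_card`.
#' @param adjusted_score Adjusted score(s).
#' @return Integer vector of Equivalent Scores in `0:4`, with the clinical
#'   labels attached as names.
#' @export
classify_es <- function(norm_card, adjusted_score) {
  cuts <- norm_card$cuts
  es <- rowSums(outer(adjusted_score, cuts, ">"))
  stats::setNames(as.integer(es), es_labels()[as.character(es)])
}

#' @export
print.norm_card <- function(x, ...) {
  cat(sprintf("Norm card: %s (n = %d)\n", x$measure, x$n))
  cat(sprintf("  oTL %.4g | iTL %.4g\n", x$otl, x$itl))
  cat(sprintf("  ES0 <= %.4g < ES1 <= %.4g < ES2 <= %.4g < ES3 <= %.4g < ES4\n",
              x$cuts[1], x$cuts[2], x$cuts[3], x$cuts[4]))
  invisible(x)
}

.card_to_list <- function(card) {
  terms <- if (!is.null(card$equation)) card$equation$terms else NULL
  list(measure = jsonlite::unbox(card$measure),
       terms = if (is.null(terms)) list() else
         terms[c("predictor", "transform", "coef", "center")],
       n = jsonlite::unbox(card$n),
       otl = jsonlite::unbox(card$otl), itl = jsonlite::unbox(card$itl),
       cuts = card$cuts,
       provenance = jsonlite::unbox(card$provenance))
}

.card_from_list <- function(lst) {
  terms <- as.data.frame(lst$terms)
  eq <- NULL
  if (nrow(terms) > 0) {
    eq <- structure(list(measure = lst$measure, terms = terms,
                         n = lst$n, sigma = NA_real_, r_squared = NA_real_),
                    class = "adjustment_equation")
  }
  structure(list(measure = lst$measure, equation = eq, n = lst$n,
                 otl = lst$otl, itl = lst$itl, cuts = as.numeric(lst$cuts),
                 provenance = if (is.null(lst$provenance)) "" else lst$provenance),
            class = "norm_card")
}

#' Read and write norm cards as JSON
#'
#' Norm cards travel as a schema-versioned JSON document holding, per
#' measure, the adjustment equation (coefficients, transforms, centering
#' constants), the tolerance limits and the Equivalent-Score cut-points.
#'
#' @param cards List of `norm_card` objects.
#' @param path File path.
#' @return `read_norm_cards()` a named list of `norm_card`s;
#'   `write_norm_cards()` the path, invisibly.
#' @export
write_norm_cards <- function(cards, path) {
  doc <- list(schema = jsonlite::unbox("tvfb-norm-cards/1"),
              cards = lapply(unname(cards), .card_to_list))
  jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_norm_cards
#' @export
read_norm_cards <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "tvfb-norm-cards/")) {
    stop("not a norm-card document: ", path)
  }
  raw <- doc$cards
  cards <- lapply(seq_len(nrow(raw)), function(i) {
    .card_from_list(list(measure = raw$measure[i],
                         terms = raw$terms[[i]],
                         n = raw$n[i], otl = raw$otl[i], itl = raw$itl[i],
                         cuts = raw$cuts[[i]],
                         provenance = raw$provenance[i]))
  })
  stats::setNames(cards, vapply(cards, `[[`, "", "measure"))
}

#' Published norm cards of the battery
#'
#' The packaged transcription of the battery's published standardization:
#' for each of the 13 measures, the demographic adjustment equation
#' (coefficients on transformed predictors with their centering constants)
#' and the outer/inner tolerance limits and Equivalent-Score cut-points
#' derived from the 335-subject normative sample.
#'
#' @return Named list of 13 `norm_card` objects.
#' @export
published_norm_cards <- function() {
  read_norm_cards(system.file("extdata", "norm_cards.json", package = "tvfb"))
}
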