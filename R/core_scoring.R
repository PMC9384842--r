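#' Trial and subtest layout of the battery
#'
#' The battery comprises nine 60-second trials grouped into three subtests:
#' phonemic fluency (letter cues F, A, S), semantic fluency (colors, animals,
#' fruits) and alternate fluency (letter/category pairs A/colors, F/animals,
#' S/fruits). Each subtest total is the sum of its three trial counts.
#'
#' @return `trial_names()` returns the nine trial column names in canonical
#'   order; `subtest_trials()` returns a named list mapping each subtest total
#'   (`pvf`, `svf`, `avf`) to its three trial columns.
#' @export
trial_names <- function() {
  c("pvf_f", "pvf_a", "pvf_s",
    "svf_col", "svf_ani", "svf_fru",
    "avf_acol", "avf_fani", "avf_sfru")
}

#' @rdname trial_names
#' @export
subtest_trials <- function() {
  list(pvf = c("pvf_f", "pvf_a", "pvf_s"),
       svf = c("svf_col", "svf_ani", "svf_fru"),
       avf = c("avf_acol", "avf_fani", "avf_sfru"))
}

#' All scored measures of the battery
#'
#' The nine trial counts, the three subtest totals and the Composite Shifting
#' Index, in the order used by the published norm tables.
#'
#' @return Character vector of 13 measure names.
#' @export
measure_names <- function() {
  c("pvf_f", "pvf_a", "pvf_s", "pvf",
    "svf_col", "svf_ani", "svf_fru", "svf",
    "avf_acol", "avf_fani", "avf_sfru", "avf",
    "csi")
}

#' Composite Shifting Index
#'
#' The cost of shifting from single-cued (phonemic, semantic) to alternating
#' fluency: the alternate-fluency total divided by the mean of the phonemic
#' and semantic totals, `avf / ((pvf + svf) / 2)`. A value near 1 means no
#' shifting cost; lower values mean disproportionate difficulty with the
#' alternating task.
#'
#' @param pvf_total,svf_total,avf_total Subtest totals (nonnegative; group
#'   means are accepted, so fractional values are allowed).
#' @return The index, a nonnegative dimensionless ratio. Vectorized.
#' @examples
#' compute_csi(42.6, 55.52, 42.11) # ~0.86
#' @export
compute_csi <- function(pvf_total, svf_total, avf_total) {
  stopifnot(length(pvf_total) == length(svf_total),
            length(svf_total) == length(avf_total))
  bad <- !is.na(pvf_total) & !is.na(svf_total) & (pvf_total + svf_total) <= 0
  if (any(bad)) {
    stop("CSI is undefined when the phonemic + semantic total is zero")
  }
  if (any(stats::na.omit(c(pvf_total, svf_total, avf_total)) < 0)) {
    stop("subtest totals must be nonnegative")
  }
  avf_total / ((pvf_total + svf_total) / 2)
}

.check_trials <- function(trials, integer_only = FALSE) {
  if (is.null(names(trials)) || any(!nzchar(names(trials)))) {
    stop("trial counts must be named by trial (",
         paste(trial_names(), collapse = ", "), ")")
  }
  unknown <- setdiff(names(trials), trial_names())
  if (length(unknown) > 0) {
    stop("unknown trial key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- stats::na.omit(unlist(trials))
  if (any(vals < 0)) stop("trial counts must be nonnegative")
  if (integer_only && any(vals != round(vals))) {
    stop("trial counts must be integers (integer_only = TRUE)")
  }
  invisible(TRUE)
}

#' Score one battery administration
#'
#' Computes the three subtest totals (each the sum of its three trial word
#' counts) and the Composite Shifting Index from the nine per-trial counts.
#' A subtest total is defined only when all three of its trials are present;
#' the index is defined only when all three totals are defined and the
#' phonemic + semantic total is positive — otherwise the corresponding field
#' is `NA`.
#'
#' @param trials Named numeric vector (or list) of per-trial word counts,
#'   keyed by [trial_names()]. Missing trials may be given as `NA` or simply
#'   omitted. Fractional values are accepted (so published group means flow
#'   through the same arithmetic); set `integer_only = TRUE` to enforce
#'   integer counts.
#' @param integer_only Reject fractional counts when `TRUE` (default `FALSE`).
#' @return An object of class `battery_scores`: a list with `trials` (all nine
#'   slots, `NA` where absent), `pvf`, `svf`, `avf` and `csi`.
#' @examples
#' score_battery(c(pvf_f = 15, pvf_a = 13, pvf_s = 14,
#'                 svf_col = 16, svf_ani = 23, svf_fru = 17,
#'                 avf_acol = 14, avf_fani = 14, avf_sfru = 14))
#' @export
score_battery <- function(trials, integer_only = FALSE) {
  trials <- unlist(trials)
  .check_trials(trials, integer_only = integer_only)
  full <- stats::setNames(rep(NA_real_, 9L), trial_names())
  full[names(trials)] <- as.numeric(trials)
  totals <- vapply(subtest_trials(), function(cols) {
    x <- full[cols]
    if (anyNA(x)) NA_real_ else sum(x)
  }, numeric(1))
  csi <- if (anyNA(totals) || totals[["pvf"]] + totals[["svf"]] <= 0) {
    NA_real_
  } else {
    compute_csi(totals[["pvf"]], totals[["svf"]], totals[["avf"]])
  }
  structure(list(trials = full,
                 pvf = totals[["pvf"]], svf = totals[["svf"]],
                 avf = totals[["avf"]], csi = csi),
            class = "battery_scores")
}

#' @export
print.battery_scores <- function(x, ...) {
  cat("Battery scores\n")
  cat("  PVF:", x$pvf, " SVF:", x$svf, " AVF:", x$avf,
      " CSI:", round(x$csi, 3), "\n")
  invisible(x)
}

#' Score every row of a cohort table
#'
#' Adds (or recomputes) the subtest totals `pvf`, `svf`, `avf` and the
#' Composite Shifting Index `csi` from the nine trial columns.
#'
#' @param cohort Data frame with the nine trial columns of [trial_names()].
#' @param integer_only Reject fractional counts when `TRUE`.
#' @return The cohort with `pvf`, `svf`, `avf`, `csi` columns filled in.
#' @export
score_cohort <- function(cohort, integer_only = FALSE) {
  missing_cols <- setdiff(trial_names(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks trial column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (tn in trial_names()) {
    .check_trials(stats::setNames(list(cohort[[tn]]), tn),
                  integer_only = integer_only)
  }
  for (st in names(subtest_trials())) {
    cols <- subtest_trials()[[st]]
    cohort[[st]] <- rowSums(as.matrix(cohort[cols]))
  }
  denom_ok <- !is.na(cohort$pvf) & !is.na(cohort$svf) &
    (cohort$pvf + cohort$svf) > 0
  cohort$csi <- NA_real_
  cohort$csi[denom_ok] <- compute_csi(cohort$pvf[denom_ok],
                                      cohort$svf[denom_ok],
                                      cohort$avf[denom_ok])
  cohort
}
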