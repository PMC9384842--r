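# Cohort tables travel as plain CSV (UTF-8, "." decimal, locale-independent).
# Required columns: id, age, education, sex, cohort + the nine trial columns;
# optional: itel_mmse, bds_wm, bds_t, the derived totals/csi and any paired
# replicate columns (suffixes _ip, _rt, _r2).

.cohort_required <- function() {
  c("id", "age", "education", "sex", "cohort", trial_names())
}

#' Validate a cohort table
#'
#' Checks the documented cohort schema: required columns present, unique ids,
#' ages of at least 18 years, nonnegative education, sex coded `"M"`/`"F"`,
#' nonnegative trial counts, and (when present) covariates within their
#' instrument ranges (telephone MMSE 0-22, backward-digit-span working-memory
#' span 0-8, backward-digit-span total 0-14).
#'
#' @param cohort Data frame to check.
#' @return The cohort, invisibly; stops with a descriptive error otherwise.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_required(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(cohort) == 0) stop("cohort table has no rows")
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique")
  demo <- cohort[c("age", "education", "sex")]
  if (anyNA(demo)) stop("missing demographics (age/education/sex)")
  if (any(cohort$age < 18)) stop("age must be >= 18 years")
  if (any(cohort$education < 0)) stop("education must be >= 0 years")
  if (!all(cohort$sex %in% c("M", "F"))) stop('sex must be "M" or "F"')
  for (tn in trial_names()) {
    if (any(stats::na.omit(cohort[[tn]]) < 0)) {
      stop("negative counts in trial column ", tn)
    }
  }
  ranges <- list(itel_mmse = c(0, 22), bds_wm = c(0, 8), bds_t = c(0, 14))
  for (cv in names(ranges)) {
    if (cv %in% names(cohort)) {
      v <- stats::na.omit(cohort[[cv]])
      if (any(v < ranges[[cv]][1] | v > ranges[[cv]][2])) {
        stop(cv, " outside its instrument range [",
             ranges[[cv]][1], ", ", ranges[[cv]][2], "]")
      }
    }
  }
  invisible(cohort)
}

#' Read and write cohort tables
#'
#' Cohort tables are comma-separated UTF-8 text with a header row and `"."` as
#' the decimal mark, regardless of locale. `read_cohort()` validates the
#' schema on the way in.
#'
#' @param path File path.
#' @param cohort Data frame in the cohort schema.
#' @param validate Validate on read (default `TRUE`).
#' @return `read_cohort()` the cohort data frame; `write_cohort()` the path,
#'   invisibly.
#' @export
read_cohort <- function(path, validate = TRUE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (validate) validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}
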