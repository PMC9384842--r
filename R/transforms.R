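# Predictor transforms used by the demographic adjustment equations.
# Age and education enter through one member of a fixed power family;
# sex enters sign-coded (+1 male, -1 female) so its coefficient is the
# familiar additive "+c if M; -c if F" correction.

.transform_fns <- list(
  identity   = function(x) x,
  sqrt       = function(x) sqrt(x),
  log10      = function(x) log10(x),
  reciprocal = function(x) 1 / x,
  square     = function(x) x^2,
  cube       = function(x) x^3,
  sign       = function(x) {
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      if (!all(x %in% c("M", "F"))) stop('sex must be "M" or "F"')
      ifelse(x == "M", 1, -1)
    } else {
      if (!all(x %in% c(-1, 1))) stop("sign-coded values must be +1/-1")
      as.numeric(x)
    }
  }
)

#' Apply a named predictor transform
#'
#' @param transform One of `"identity"`, `"sqrt"`, `"log10"`, `"reciprocal"`,
#'   `"square"`, `"cube"` (numeric predictors) or `"sign"` (sex: `"M"` maps to
#'   +1, `"F"` to -1).
#' @param x Predictor values.
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(transform, x) {
  fn <- .transform_fns[[transform]]
  if (is.null(fn)) stop("unknown transform: ", transform)
  fn(x)
}

#' Candidate transform grid for adjustment-equation selection
#'
#' The default search family for demographic adjustment: every power-family
#' transform for age and education, and the sign coding for sex.
#'
#' @return Named list of candidate transform names per predictor.
#' @export
default_transform_grid <- function() {
  fam <- c("identity", "sqrt", "log10", "reciprocal", "square", "cube")
  list(age = fam, education = fam, sex = "sign")
}

.predictor_column <- function(predictor) {
  switch(predictor,
         age = "age", education = "education", sex = "sex",
         stop("unknown predictor: ", predictor))
}
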