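#' Covariate transformations used in the normative model space
#'
#' The model space applies a fixed catalogue of monotone (and two non-monotone)
#' transformations to age and years of education before fitting: none, square
#' root, square, cube, natural log, reciprocal, and -- for age only --
#' `ln(100 - age)`. Transform names are used throughout the package to label
#' candidate models, correction terms and norm grids.
#'
#' @param include_ln100 logical; include `ln_100_minus_age` (age only).
#' @return character vector of transform names.
#' @export
age_transforms <- function(include_ln100 = FALSE) {
  base <- c("identity", "sqrt", "square", "cube", "ln", "reciprocal")
  if (include_ln100) c(base, "ln_100_minus_age") else base
}

#' @rdname age_transforms
#' @export
education_transforms <- function() {
  c("identity", "sqrt", "square", "cube", "ln", "reciprocal")
}

#' Apply a named covariate transform
#'
#' @param transform transform name (see [age_transforms()]).
#' @param x numeric vector (age in years or education in years).
#' @return transformed numeric vector.
#' @details Domain violations (log or reciprocal of a non-positive value,
#'   `ln(100 - age)` for age >= 100) raise an error naming the offending
#'   transform rather than returning `NaN`/`Inf`.
#' @export
apply_transform <- function(transform, x) {
  transform <- match.arg(transform, c(age_transforms(TRUE)))
  ok <- !is.na(x)
  bad <- switch(transform,
    ln = ,
    reciprocal = ok & x <= 0,
    sqrt = ok & x < 0,
    ln_100_minus_age = ok & x >= 100,
    ok & FALSE
  )
  if (any(bad)) {
    stop(sprintf("value %s outside the domain of transform '%s'",
                 format(x[bad][1]), transform), call. = FALSE)
  }
  switch(transform,
    identity = x,
    sqrt = sqrt(x),
    square = x^2,
    cube = x^3,
    ln = log(x),
    reciprocal = 1 / x,
    ln_100_minus_age = log(100 - x)
  )
}

# round half away from zero, the presentation convention of the printed grids
# (base round() is half-to-even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
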