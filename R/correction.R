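#' Construct a demographic correction model
#'
#' A correction model is the portable form of a selected regression: a set of
#' terms (covariate, transform, coefficient, centring constant). The additive
#' correction for a participant is
#' `-(sum of coefficient * (transform(covariate) - centring))`, and the
#' corrected score is the raw score plus the correction, so predicted
#' disadvantage (old age, low education on time scores) raises the corrected
#' value toward the centred reference.
#'
#' @param score_name score label, e.g. `"t4"` or `"t4_t3"`.
#' @param terms data.frame with columns `covariate` (`"age"`, `"education"` or
#'   `"sex"`), `transform`, `coefficient`, `centring`.
#' @param consistent logical flag carried by the frozen published norms:
#'   `FALSE` marks an as-published formula that does not reproduce its
#'   published correction grid.
#' @return object of class `correction_model`.
#' @export
correction_model <- function(score_name, terms, consistent = TRUE) {
  stopifnot(is.data.frame(terms),
            all(c("covariate", "transform", "coefficient", "centring") %in%
                  names(terms)),
            all(is.finite(terms$coefficient)), all(is.finite(terms$centring)),
            all(terms$transform %in% c(age_transforms(TRUE), "identity")))
  structure(list(score_name = score_name, terms = terms,
                 consistent = isTRUE(consistent)),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("Correction model for", x$score_name,
      if (!x$consistent) "(as published; inconsistent with the printed grid)",
      "\n")
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %+.7g * (%s - %.10g)\n", x$terms$coefficient[i],
                transform_label(x$terms$covariate[i], x$terms$transform[i]),
                x$terms$centring[i]))
  invisible(x)
}

#' Convert a selected fit into a correction model
#'
#' @param fit an `scwt_fit` from [fit_model()] or [select_best()].
#' @return a [correction_model()].
#' @export
as_correction_model <- function(fit) {
  stopifnot(inherits(fit, "scwt_fit"))
  rows <- list()
  m <- fit$model
  if (isTRUE(m$sex))
    rows[[length(rows) + 1]] <- gen_term("sex", "identity",
                                         fit$coefficients[["sex"]],
                                         0)
  if (!is.na(m$age_transform))
    rows[[length(rows) + 1]] <- gen_term("age", m$age_transform,
                                         fit$coefficients[["age"]],
                                         fit$centring[["age"]])
  if (!is.na(m$education_transform))
    rows[[length(rows) + 1]] <- gen_term("education", m$education_transform,
                                         fit$coefficients[["education"]],
                                         fit$centring[["education"]])
  terms <- if (length(rows)) do.call(rbind, rows) else
    gen_term(character(0), character(0), numeric(0), numeric(0))
  correction_model(attr(fit, "response") %||% "score", terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Additive demographic correction for one participant
#'
#' @param model a [correction_model()].
#' @param age age in years.
#' @param education education in years.
#' @param sex `"male"` or `"female"`; only used when the model has a sex term
#'   (female is the reference level).
#' @return the additive correction, in the units of the score. At covariates
#'   equal to the centring constants the correction is exactly zero.
#' @export
correction_term <- function(model, age, education, sex = "female") {
  stopifnot(inherits(model, "correction_model"))
  n <- max(length(age), length(education), length(sex))
  age <- rep_len(age, n); education <- rep_len(education, n)
  sex <- rep_len(sex, n)
  s <- numeric(n)
  t <- model$terms
  for (i in seq_len(nrow(t))) {
    x <- switch(t$covariate[i],
                age = age,
                education = education,
                sex = as.numeric(sex == "male"))
    s <- s + t$coefficient[i] * (apply_transform(t$transform[i], x) - t$centring[i])
  }
  -s
}

#' Apply a demographic correction to a raw score
#'
#' @param raw raw score value(s).
#' @param model a [correction_model()].
#' @inheritParams correction_term
#' @param floor_at_zero floor the corrected value at zero (sensible for error
#'   scores, whose raw range starts at zero).
#' @return corrected score, `raw + correction`.
#' @export
apply_correction <- function(raw, model, age, education, sex = "female",
                             floor_at_zero = FALSE) {
  adj <- raw + correction_term(model, age, education, sex)
  if (floor_at_zero) pmax(0, adj) else adj
}

#' Published age and education bands
#'
#' The fourteen 5-year age bands spanning 20-90 and the four education bands
#' (0-4, 5-8, 9-13, 14-19 years) of the printed correction grids. Midpoints
#' `(lo + hi) / 2` are used wherever a band must become a number.
#'
#' @return data.frame with `lo`, `hi`, `mid` and a `label` column.
#' @export
scwt_age_bands <- function() {
  lo <- c(20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85)
  hi <- c(24, 29, 34, 39, 44, 49, 54, 59, 64, 69, 74, 79, 84, 90)
  data.frame(lo = lo, hi = hi, mid = (lo + hi) / 2,
             label = paste0(lo, "-", hi), stringsAsFactors = FALSE)
}

#' @rdname scwt_age_bands
#' @export
scwt_education_bands <- function() {
  lo <- c(0, 5, 9, 14)
  hi <- c(4, 8, 13, 19)
  data.frame(lo = lo, hi = hi, mid = (lo + hi) / 2,
             label = paste0(lo, "-", hi), stringsAsFactors = FALSE)
}

#' Build a band-midpoint correction grid
#'
#' Evaluates the correction term at the midpoint of every age band (columns)
#' and education band (rows; a single unnamed row when the model has no
#' education term). Full precision is retained; `round` applies the
#' half-away-from-zero display rounding of the printed grids.
#'
#' @param model a [correction_model()].
#' @param age_bands,education_bands band tables as [scwt_age_bands()]; bands
#'   must be ordered and non-overlapping.
#' @param round decimal places for display rounding, or `NULL` for full
#'   precision.
#' @return object of class `norm_grid`: a matrix with band labels, plus the
#'   band tables as attributes.
#' @export
build_norm_grid <- function(model, age_bands = scwt_age_bands(),
                            education_bands = scwt_education_bands(),
                            round = 2) {
  stopifnot(inherits(model, "correction_model"),
            !is.unsorted(age_bands$lo), all(age_bands$lo <= age_bands$hi))
  has_edu <- "education" %in% model$terms$covariate
  erows <- if (has_edu) education_bands$mid else NA_real_
  cells <- t(vapply(erows, function(e) {
    correction_term(model, age_bands$mid,
                    if (is.na(e)) 10 else rep(e, nrow(age_bands)))
  }, numeric(nrow(age_bands))))
  if (!is.null(round)) cells <- round_half_away(cells, round)
  dimnames(cells) <- list(
    if (has_edu) education_bands$label else "all",
    age_bands$label)
  structure(cells, class = c("norm_grid", class(cells)),
            score_name = model$score_name, age_bands = age_bands,
            education_bands = if (has_edu) education_bands else NULL)
}

#' @export
print.norm_grid <- function(x, ...) {
  cat("Correction grid for", attr(x, "score_name"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Grid-lookup correction by nearest band
#'
#' Looks a participant up in a printed correction grid by assigning the
#' nearest age and education bands (values inside a band map to that band;
#' values in the gaps between or beyond bands map to the closest band edge).
#' This is the recommended mode for the published scores whose printed exact
#' formula is inconsistent with the printed grid.
#'
#' @param grid a `norm_grid`.
#' @param age,education participant demographics in years.
#' @return correction value(s) from the grid cells.
#' @export
grid_correction <- function(grid, age, education = NULL) {
  ab <- attr(grid, "age_bands")
  eb <- attr(grid, "education_bands")
  nearest <- function(x, bands) {
    vapply(x, function(v) {
      inside <- which(v >= bands$lo & v <= bands$hi)
      if (length(inside)) inside[1]
      else which.min(pmin(abs(v - bands$lo), abs(v - bands$hi)))
    }, integer(1))
  }
  j <- nearest(age, ab)
  i <- if (is.null(eb)) rep(1L, length(age)) else {
    if (is.null(education))
      stop("grid for ", attr(grid, "score_name"), " requires education",
           call. = FALSE)
    nearest(education, eb)
  }
  unclass(grid)[cbind(i, j)]
}
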