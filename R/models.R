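#' Enumerate the transformed-covariate model space
#'
#' Builds every candidate linear model for one score: the null model, each
#' single predictor (sex untransformed; age and education under each allowed
#' transform) and every multi-predictor combination. With the six shared
#' transforms this yields 98 models (1 null + 1 sex + 6 age + 6 education +
#' 6 sex:age + 6 sex:education + 36 age:education + 36 sex:age:education);
#' including `ln(100 - age)` as a seventh age transform yields 112. Ordering
#' is canonical and stable.
#'
#' @param include_ln100 logical; include the `ln(100 - age)` age transform.
#' @return data.frame with one row per candidate: `model_id`, `sex` (logical),
#'   `age_transform`, `education_transform` (`NA` when the predictor is absent).
#' @export
enumerate_models <- function(include_ln100 = FALSE) {
  at <- age_transforms(include_ln100)
  et <- education_transforms()
  row <- function(sex, a, e) data.frame(sex = sex, age_transform = a,
                                        education_transform = e,
                                        stringsAsFactors = FALSE)
  out <- list(row(FALSE, NA_character_, NA_character_),
              row(TRUE, NA_character_, NA_character_))
  for (a in at) out[[length(out) + 1]] <- row(FALSE, a, NA_character_)
  for (e in et) out[[length(out) + 1]] <- row(FALSE, NA_character_, e)
  for (a in at) out[[length(out) + 1]] <- row(TRUE, a, NA_character_)
  for (e in et) out[[length(out) + 1]] <- row(TRUE, NA_character_, e)
  for (a in at) for (e in et) out[[length(out) + 1]] <- row(FALSE, a, e)
  for (a in at) for (e in et) out[[length(out) + 1]] <- row(TRUE, a, e)
  out <- do.call(rbind, out)
  out <- cbind(model_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

transform_label <- function(covariate, transform) {
  switch(transform,
    identity = covariate,
    sqrt = paste0("sqrt(", covariate, ")"),
    square = paste0(covariate, "^2"),
    cube = paste0(covariate, "^3"),
    ln = paste0("ln(", covariate, ")"),
    reciprocal = paste0("1/", covariate),
    ln_100_minus_age = "ln(100 - age)")
}

#' @export
format.scwt_model <- function(x, ...) {
  terms <- character()
  if (isTRUE(x$sex)) terms <- c(terms, "sex")
  if (!is.na(x$age_transform))
    terms <- c(terms, transform_label("age", x$age_transform))
  if (!is.na(x$education_transform))
    terms <- c(terms, transform_label("education", x$education_transform))
  if (!length(terms)) "y ~ 1" else paste("y ~ 1 +", paste(terms, collapse = " + "))
}

as_scwt_model <- function(model) {
  m <- as.list(model)[c("sex", "age_transform", "education_transform")]
  class(m) <- "scwt_model"
  m
}

# Gaussian-likelihood BIC from a residual sum of squares, with k counting the
# intercept, the slopes and the residual variance.
gaussian_bic <- function(rss, n, k) {
  if (n <= k) stop("BIC undefined: n <= number of parameters", call. = FALSE)
  logl <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * logl + k * log(n)
}

#' BIC of a fitted candidate model
#'
#' Gaussian maximum-likelihood BIC, `-2 logL + k ln(n)`, with `k` counting the
#' intercept, the regression slopes and the residual variance.
#'
#' @param fit an `scwt_fit` from [fit_model()].
#' @return numeric BIC.
#' @export
model_bic <- function(fit) {
  stopifnot(inherits(fit, "scwt_fit"))
  gaussian_bic(fit$rss, fit$n, fit$k)
}

#' Fit one candidate model by ordinary least squares
#'
#' Continuous covariates enter transformed and centred at the cohort mean of
#' the transformed covariate; sex is a single binary contrast with female as
#' the reference. Returns the coefficients, normal-theory t-test p-values,
#' R-squared, and BIC.
#'
#' @param model one row of [enumerate_models()] (or an equivalent list).
#' @param cohort data.frame with `sex`, `age`, `education` and the response.
#' @param response name of the score column to model.
#' @return object of class `scwt_fit`.
#' @export
fit_model <- function(model, cohort, response) {
  m <- as_scwt_model(model)
  keep <- !is.na(cohort[[response]])
  dat <- cohort[keep, , drop = FALSE]
  y <- dat[[response]]
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  centring <- numeric(0)
  if (isTRUE(m$sex)) X <- cbind(X, sex = as.numeric(dat$sex == "male"))
  for (cv in c("age", "education")) {
    tf <- m[[paste0(if (cv == "age") "age" else "education", "_transform")]]
    if (!is.na(tf)) {
      z <- apply_transform(tf, dat[[cv]])
      ctr <- mean(z)
      X <- cbind(X, z - ctr)
      colnames(X)[ncol(X)] <- cv
      centring[cv] <- ctr
    }
  }
  fit_design(m, X, y, centring)
}

fit_design <- function(m, X, y, centring) {
  n <- length(y)
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design; collinear terms: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  k <- p + 1
  df <- n - p
  s2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  se <- sqrt(pmax(0, diag(xtx_inv)) * s2)
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  names(pval) <- colnames(X)
  out <- list(model = m, coefficients = coefs[-1], intercept = coefs[[1]],
              centring = centring, rss = rss, residual_variance = rss / n,
              n = n, k = k, r_squared = max(0, min(1, r2)),
              p_values = pval[-1],
              bic = gaussian_bic(rss, n, k))
  class(out) <- "scwt_fit"
  out
}

#' @export
print.scwt_fit <- function(x, ...) {
  cat(format(x$model), "\n")
  cat(sprintf("  n = %d, k = %d, BIC = %.3f, R^2 = %.3f\n",
              x$n, x$k, x$bic, x$r_squared))
  if (length(x$coefficients)) {
    cat("  intercept:", format(x$intercept), "\n")
    for (nm in names(x$coefficients))
      cat(sprintf("  %s: %.6g (p = %.3g)\n", nm, x$coefficients[[nm]],
                  x$p_values[[nm]]))
  }
  invisible(x)
}

#' Fit the whole candidate model space for one score
#'
#' @inheritParams fit_model
#' @param include_ln100 logical; see [enumerate_models()].
#' @return list of `scwt_fit` objects in canonical model order.
#' @export
fit_model_space <- function(cohort, response, include_ln100 = FALSE) {
  models <- enumerate_models(include_ln100)
  keep <- !is.na(cohort[[response]])
  dat <- cohort[keep, , drop = FALSE]
  y <- dat[[response]]
  # precompute transformed, centred covariate columns once
  cols <- list(sex = as.numeric(dat$sex == "male"))
  ctr <- list()
  for (tf in age_transforms(include_ln100)) {
    z <- apply_transform(tf, dat$age)
    ctr[[paste0("age.", tf)]] <- mean(z)
    cols[[paste0("age.", tf)]] <- z - mean(z)
  }
  for (tf in education_transforms()) {
    z <- apply_transform(tf, dat$education)
    ctr[[paste0("education.", tf)]] <- mean(z)
    cols[[paste0("education.", tf)]] <- z - mean(z)
  }
  lapply(seq_len(nrow(models)), function(i) {
    m <- as_scwt_model(models[i, ])
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    centring <- numeric(0)
    if (isTRUE(m$sex)) X <- cbind(X, sex = cols$sex)
    if (!is.na(m$age_transform)) {
      key <- paste0("age.", m$age_transform)
      X <- cbind(X, age = cols[[key]])
      centring["age"] <- ctr[[key]]
    }
    if (!is.na(m$education_transform)) {
      key <- paste0("education.", m$education_transform)
      X <- cbind(X, education = cols[[key]])
      centring["education"] <- ctr[[key]]
    }
    fit_design(m, X, y, centring)
  })
}

#' Select the optimal model by the BIC-with-parsimony rule
#'
#' The minimum-BIC fit wins outright when every other fit is more than 2 BIC
#' points above it. Otherwise the candidate set is every fit within 2 points
#' of the minimum, and the fewest-parameter candidate wins; remaining ties are
#' broken by lower BIC, then by canonical model order.
#'
#' @param fits non-empty list of `scwt_fit` objects.
#' @return the selected `scwt_fit`.
#' @export
select_best <- function(fits) {
  if (!length(fits)) stop("empty fit list", call. = FALSE)
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  cand <- which(bic - min(bic) <= 2)
  cand <- cand[order(k[cand], bic[cand], cand)]
  fits[[cand[1]]]
}

#' Bonferroni covariate significance flags
#'
#' A term is flagged significant when its p-value times the family size is at
#' most 0.05 (boundary inclusive).
#'
#' @param fit an `scwt_fit`.
#' @param family_size number of comparisons in the Bonferroni family; defaults
#'   to the number of terms in the fitted model.
#' @return named logical vector over the model terms.
#' @export
covariate_significance <- function(fit, family_size = length(fit$p_values)) {
  stopifnot(inherits(fit, "scwt_fit"), family_size >= 1)
  vapply(fit$p_values, function(p) p * family_size <= 0.05, logical(1))
}

#' Model-space report for one score
#'
#' @inheritParams fit_model_space
#' @return data.frame with one row per candidate model: formula, k, BIC,
#'   delta-BIC, R-squared, and whether the model is the selected one.
#' @export
model_space_report <- function(cohort, response, include_ln100 = FALSE) {
  fits <- fit_model_space(cohort, response, include_ln100)
  best <- select_best(fits)
  data.frame(
    score = response,
    model = vapply(fits, function(f) format(f$model), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    delta_bic = vapply(fits, function(f) f$bic, numeric(1)) -
      min(vapply(fits, function(f) f$bic, numeric(1))),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    selected = vapply(fits, function(f) identical(f, best), logical(1)),
    stringsAsFactors = FALSE)
}
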