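test_that("model-space enumeration has the expected size and no duplicates", {
  m98 <- enumerate_models(FALSE)
  m112 <- enumerate_models(TRUE)
  expect_equal(nrow(m98), 98)
  expect_equal(nrow(m112), 112)
  key <- function(m) paste(m$sex, m$age_transform, m$education_transform)
  expect_equal(anyDuplicated(key(m98)), 0)
  expect_equal(anyDuplicated(key(m112)), 0)
  # order-stable
  expect_identical(m98, enumerate_models(FALSE))
  # single-predictor age family: null + 6 transforms
  age_only <- m98[!m98$sex & !is.na(m98$age_transform) &
                    is.na(m98$education_transform), ]
  expect_equal(nrow(age_only), 6)
})

test_that("OLS fits match a brute-force normal-equations solve", {
  co <- random_cohort(30, seed = 4)
  co$y <- 3 * co$age + rnorm(30)
  for (i in c(2, 10, 55, 98)) {
    m <- enumerate_models(FALSE)[i, ]
    fit <- fit_model(m, co, "y")
    # independent oracle: explicit normal equations on the same design
    X <- matrix(1, 30, 1)
    if (m$sex) X <- cbind(X, as.numeric(co$sex == "male"))
    if (!is.na(m$age_transform)) {
      z <- apply_transform(m$age_transform, co$age)
      X <- cbind(X, z - mean(z))
    }
    if (!is.na(m$education_transform)) {
      z <- apply_transform(m$education_transform, co$education)
      X <- cbind(X, z - mean(z))
    }
    beta <- solve(t(X) %*% X, t(X) %*% co$y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), c(beta),
                 tolerance = 1e-8)
  }
})

test_that("noise-free responses are interpolated exactly", {
  co <- random_cohort(40, seed = 6)
  co$y <- 2 + 3 * (log(co$education) - mean(log(co$education)))
  m <- list(sex = FALSE, age_transform = NA_character_,
            education_transform = "ln")
  fit <- fit_model(m, co, "y")
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["education"]]), 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("the null model has R^2 zero and intercept the sample mean", {
  co <- random_cohort(25, seed = 8)
  fit <- fit_model(list(sex = FALSE, age_transform = NA_character_,
                        education_transform = NA_character_), co, "y")
  expect_equal(fit$intercept, mean(co$y))
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$k, 2)
})

test_that("BIC follows the Gaussian -2logL + k ln n convention", {
  co <- random_cohort(20, seed = 10)
  co$y <- 1 + 0.05 * co$age + rnorm(20)
  m <- list(sex = FALSE, age_transform = "identity",
            education_transform = NA_character_)
  fit <- fit_model(m, co, "y")
  # independent oracle: stats::BIC on the same centred regression
  ref <- lm(y ~ I(age - mean(age)), data = co)
  expect_equal(fit$bic, BIC(ref), tolerance = 1e-8)
  expect_equal(model_bic(fit), fit$bic)
  # monotone in RSS at fixed n, k; ln(n) penalty per extra parameter
  n <- 50
  expect_lt(stroopnorm:::gaussian_bic(10, n, 3),
            stroopnorm:::gaussian_bic(11, n, 3))
  expect_equal(stroopnorm:::gaussian_bic(10, n, 4) -
                 stroopnorm:::gaussian_bic(10, n, 3), log(n))
  expect_error(stroopnorm:::gaussian_bic(1, 3, 3), "n <= number")
})

test_that("rank-deficient designs are rejected naming the collinear term", {
  co <- random_cohort(30, seed = 12)
  co$education <- 7   # constant => centred column is all-zero
  m <- list(sex = FALSE, age_transform = NA_character_,
            education_transform = "identity")
  expect_error(fit_model(m, co, "y"), "collinear terms: education")
})

test_that("select_best applies the BIC-with-parsimony rule", {
  mk <- function(bic, k) structure(list(bic = bic, k = k), class = "scwt_fit")
  # gap > 2: minimum BIC wins outright
  expect_equal(select_best(list(mk(100, 5), mk(103, 3)))$bic, 100)
  # within 2 points: fewer parameters wins
  expect_equal(select_best(list(mk(100, 5), mk(101.5, 3)))$bic, 101.5)
  expect_error(select_best(list()), "empty")
  # randomized sets agree with an exhaustive application of the written rule
  set.seed(42)
  for (rep in 1:200) {
    nf <- sample(2:6, 1)
    fits <- lapply(seq_len(nf), function(i)
      mk(round(runif(1, 100, 106), 1), sample(2:5, 1)))
    got <- select_best(fits)
    bic <- vapply(fits, `[[`, numeric(1), "bic")
    k <- vapply(fits, `[[`, numeric(1), "k")
    cand <- which(bic <= min(bic) + 2)
    cand <- cand[k[cand] == min(k[cand])]
    cand <- cand[bic[cand] == min(bic[cand])]
    expect_equal(got$bic, bic[cand[1]])
    expect_equal(got$k, k[cand[1]])
  }
})

test_that("Bonferroni covariate significance uses p * family <= 0.05", {
  fit <- structure(list(p_values = c(age = 0.01, education = 0.001)),
                   class = "scwt_fit")
  expect_equal(unname(covariate_significance(fit, 12)), c(FALSE, TRUE))
  fit2 <- structure(list(p_values = c(age = 0.05)), class = "scwt_fit")
  expect_true(covariate_significance(fit2, 1)[["age"]])
})

test_that("R^2 is monotone non-decreasing over nested models", {
  co <- make_cohort(seed = 30, n_target = 300)
  fits <- fit_model_space(co, "t4")
  models <- enumerate_models(FALSE)
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  # age-only ln fit is nested in sex+age(ln) and in age(ln)+edu(any)
  i_age <- which(!models$sex & !is.na(models$age_transform) &
                   models$age_transform == "ln" &
                   is.na(models$education_transform))
  sup <- which((models$sex | !is.na(models$education_transform)) &
                 !is.na(models$age_transform) & models$age_transform == "ln")
  expect_true(all(r2[sup] >= r2[i_age] - 1e-12))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("model formulas render in canonical notation", {
  m <- enumerate_models(FALSE)
  labels <- vapply(seq_len(nrow(m)), function(i)
    format(stroopnorm:::as_scwt_model(m[i, ])), character(1))
  expect_equal(labels[1], "y ~ 1")
  expect_equal(labels[2], "y ~ 1 + sex")
  expect_true("y ~ 1 + ln(age) + sqrt(education)" %in% labels)
})
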