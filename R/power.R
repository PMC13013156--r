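#' Power of the multiple-regression F test at Cohen's f-squared
#'
#' Power of testing `u` regressors at level `alpha` with denominator degrees
#' of freedom `v`, using the noncentral F distribution with noncentrality
#' `lambda = f2 * (u + v + 1)`.
#'
#' @param u numerator degrees of freedom (number of tested regressors).
#' @param v denominator degrees of freedom.
#' @param f2 Cohen's f-squared effect size, `R^2 / (1 - R^2)`.
#' @param alpha significance level.
#' @return power in `(0, 1)`.
#' @export
power_f2 <- function(u, v, f2, alpha = 0.05) {
  lambda <- f2 * (u + v + 1)
  stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = lambda, lower.tail = FALSE)
}

#' A-priori sample size for a multiple-regression F test
#'
#' Solves for the denominator degrees of freedom `v` at which the F test of
#' `u` regressors with noncentrality `f2 * (u + v + 1)` attains the requested
#' power, by monotone root-finding on the noncentral-F power function. Two
#' sample-size conventions coexist in practice: the total sample size implied
#' by the design, `u + v + 1`, and the bare denominator df `v`, which is what
#' the usual solver output shows and what published power analyses often quote
#' as the suggested sample size. Both are returned, rounded, so either
#' convention is inspectable.
#'
#' @param u number of tested regressors (>= 1).
#' @param f2 Cohen's f-squared effect size, > 0.
#' @param alpha significance level in `(0, 1)`.
#' @param power target power in `(0, 1)`.
#' @return list with `v` (fractional denominator df), `n_suggested`
#'   (`round(v)`, the conventionally quoted figure) and `n_total`
#'   (`round(u + v + 1)`, the implied total sample size).
#' @export
required_n_f2 <- function(u, f2, alpha = 0.05, power = 0.80) {
  stopifnot(u >= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (f2 <= 0) stop("unattainable: f2 must be > 0", call. = FALSE)
  obj <- function(v) power_f2(u, v, f2, alpha) - power
  hi <- 100
  while (obj(hi) < 0 && hi < 1e9) hi <- hi * 10
  if (obj(hi) < 0) stop("unattainable power for the given f2", call. = FALSE)
  v <- stats::uniroot(obj, c(1 + 1e-10, hi), tol = 1e-8)$root
  list(v = v, n_suggested = as.integer(round(v)),
       n_total = as.integer(round(u + v + 1)))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor from the trace formula on the double-centred
#' covariance matrix of the `k` repeated conditions:
#' `epsilon = tr(S*)^2 / ((k - 1) * sum(S*^2))` with
#' `S* = C S C`, `C = I - J/k`. Equals 1 for `k = 2` and for any
#' compound-symmetric covariance; its lower bound is `1 / (k - 1)`.
#'
#' @param condition_covariance symmetric positive semi-definite `k x k`
#'   covariance matrix of the repeated conditions, `k >= 2`.
#' @return epsilon in `(1/(k-1), 1]`.
#' @export
gg_epsilon <- function(condition_covariance) {
  s <- as.matrix(condition_covariance)
  k <- nrow(s)
  if (k < 2 || ncol(s) != k) stop("need a k x k matrix, k >= 2", call. = FALSE)
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
    stop("covariance matrix must be symmetric", call. = FALSE)
  cmat <- diag(k) - matrix(1 / k, k, k)
  sstar <- cmat %*% s %*% cmat
  sum(diag(sstar))^2 / ((k - 1) * sum(sstar^2))
}

#' Paired Cohen's d
#'
#' Mean of the paired differences divided by their standard deviation, with
#' sign convention `x - y`. A zero-variance nonzero difference is reported as
#' an infinite effect.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return numeric effect size.
#' @export
cohens_d_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(0)
    return(sign(mean(d)) * Inf)
  }
  mean(d) / sd_d
}

#' Holm step-down p-value adjustment
#'
#' Order-preserving step-down Holm adjustment with monotonicity enforcement;
#' adjusted values never fall below the raw values and never exceed the
#' Bonferroni adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Pairwise task comparison summary
#'
#' For repeated task conditions (columns), returns the paired Cohen's d and
#' Holm-adjusted paired t-test p-value for every pair of tasks, together with
#' the Greenhouse-Geisser epsilon of the condition covariance.
#'
#' @param scores matrix or data.frame, one column per task condition, one row
#'   per participant (complete cases used).
#' @return list with a `pairs` data.frame (`a`, `b`, `d`, `p`, `p_holm`) and
#'   `epsilon`.
#' @export
task_comparisons <- function(scores) {
  m <- as.matrix(scores)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  stopifnot(k >= 2, nrow(m) >= 3)
  cmb <- utils::combn(k, 2)
  pairs <- data.frame(
    a = colnames(m)[cmb[1, ]], b = colnames(m)[cmb[2, ]],
    d = apply(cmb, 2, function(ij) cohens_d_paired(m[, ij[1]], m[, ij[2]])),
    p = apply(cmb, 2, function(ij) stats::t.test(m[, ij[1]], m[, ij[2]],
                                                 paired = TRUE)$p.value),
    stringsAsFactors = FALSE)
  pairs$p_holm <- holm_adjust(pairs$p)
  list(pairs = pairs, epsilon = gg_epsilon(stats::cov(m)))
}
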