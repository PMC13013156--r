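#' Order-statistic rank for a one-sided non-parametric tolerance limit
#'
#' Observations are ranked worst-to-best (rank 1 = worst). Writing `X` for the
#' number of population-tail observations in a sample of `n` -- that is,
#' `X ~ Binomial(n, 1 - coverage)` counting sample values worse than the
#' population quantile that cuts off the worst `1 - coverage` fraction -- the
#' outer limit is the largest rank `r` whose value is worse than that quantile
#' with the stated confidence, `P(X >= r) >= confidence`; the inner limit is
#' the smallest rank whose value is better than it with the stated confidence,
#' `P(X <= r - 1) >= confidence`. At the defaults (coverage 0.95, confidence
#' 0.95) an outer limit first exists at `n = 59`.
#'
#' @param n sample size.
#' @param coverage population fraction to be bounded (default 0.95: the limit
#'   controls the worst 5% of the population).
#' @param confidence confidence level of the guarantee.
#' @param side `"outer"` or `"inner"`.
#' @return integer rank (1-based, worst-to-best).
#' @export
tolerance_order_index <- function(n, coverage = 0.95, confidence = 0.95,
                                  side = c("outer", "inner")) {
  side <- match.arg(side)
  stopifnot(n >= 1, coverage > 0, coverage < 1, confidence > 0, confidence < 1)
  q <- 1 - coverage
  if (side == "outer") {
    # largest r with P(X >= r) >= confidence  <=>  P(X <= r-1) <= 1 - confidence
    r <- 0L
    for (cand in seq_len(n)) {
      if (stats::pbinom(cand - 1, n, q) <= 1 - confidence) r <- cand else break
    }
    if (r == 0L)
      stop(sprintf("insufficient n: no outer tolerance limit exists at n = %d",
                   n), call. = FALSE)
    r
  } else {
    for (cand in seq_len(n)) {
      if (stats::pbinom(cand - 1, n, q) >= confidence) return(cand)
    }
    stop(sprintf("insufficient n: no inner tolerance limit exists at n = %d",
                 n), call. = FALSE)
  }
}

new_tolerance_bands <- function(score_name, direction, otl, itl, cutoff_es1,
                                cutoff_es2, cutoff_es3, coverage = 0.95,
                                confidence = 0.95, degenerate = FALSE,
                                n = NA_integer_) {
  structure(list(score_name = score_name, direction = direction, otl = otl,
                 itl = itl, cutoff_es1 = cutoff_es1, cutoff_es2 = cutoff_es2,
                 cutoff_es3 = cutoff_es3, coverage = coverage,
                 confidence = confidence, degenerate = degenerate, n = n),
            class = "tolerance_bands")
}

#' Tolerance limits and Equivalent Score cut-offs for an adjusted score
#'
#' Sorts the adjusted scores worst-to-best, takes the outer and inner
#' tolerance limits at the [tolerance_order_index()] ranks, and derives the
#' five-level Equivalent Score cut-offs by rank subdivision: scores worse than
#' the outer limit are ES = 0, scores better than the sample median are
#' ES = 4, and the ranks strictly between the outer-limit rank and the median
#' rank are split into three contiguous blocks of equal count (within one;
#' surplus ranks go to the worse blocks). Cut-offs take the sample value at
#' the boundary rank, so tied observations fall in the better class.
#'
#' @param adjusted numeric vector of demographically adjusted scores
#'   (missing values are dropped).
#' @param score_name label carried into the result.
#' @param direction `"higher_is_worse"` (times, errors) or
#'   `"lower_is_worse"`.
#' @param coverage,confidence tolerance-limit parameters; see
#'   [tolerance_order_index()].
#' @return object of class `tolerance_bands` with elements `otl`, `itl`,
#'   `cutoff_es1`, `cutoff_es2`, `cutoff_es3` (the median) and a `degenerate`
#'   flag (set when all scores are equal and every cut-off collapses).
#' @export
compute_bands <- function(adjusted, score_name = "score",
                          direction = c("higher_is_worse", "lower_is_worse"),
                          coverage = 0.95, confidence = 0.95) {
  direction <- match.arg(direction)
  x <- adjusted[!is.na(adjusted)]
  n <- length(x)
  r_otl <- tolerance_order_index(n, coverage, confidence, "outer")
  r_itl <- tolerance_order_index(n, coverage, confidence, "inner")
  worst_first <- sort(x, decreasing = (direction == "higher_is_worse"))
  med <- stats::median(x)
  if (length(unique(x)) == 1L) {
    return(new_tolerance_bands(score_name, direction, x[1], x[1], x[1], x[1],
                               x[1], coverage, confidence, degenerate = TRUE,
                               n = n))
  }
  worse_than <- function(a, b) {
    if (direction == "higher_is_worse") a > b else a < b
  }
  r_med <- sum(worse_than(x, med))
  m <- r_med - r_otl
  if (m < 0) m <- 0
  sizes <- rep(m %/% 3, 3) + c(m %% 3 >= 1, m %% 3 >= 2, FALSE)
  r1 <- r_otl + sizes[1]
  r2 <- r1 + sizes[2]
  val_at <- function(r) if (r >= 1 && r <= n) worst_first[r] else NA_real_
  new_tolerance_bands(score_name, direction,
                      otl = val_at(r_otl), itl = val_at(r_itl),
                      cutoff_es1 = if (m > 0) val_at(r1) else val_at(r_otl),
                      cutoff_es2 = if (m > 0) val_at(r2) else val_at(r_otl),
                      cutoff_es3 = med, coverage = coverage,
                      confidence = confidence, n = n)
}

#' @export
print.tolerance_bands <- function(x, ...) {
  cat(sprintf("Equivalent-Score bands for %s (%s)%s\n", x$score_name,
              x$direction, if (x$degenerate) " [degenerate]" else ""))
  op <- if (x$direction == "higher_is_worse") ">" else "<"
  cat(sprintf("  ITL %.2f | ES0 %s %.2f | ES1 %s %.2f | ES2 %s %.2f | ES3 %s %.2f | ES4 otherwise\n",
              x$itl, op, x$otl, op, x$cutoff_es1, op, x$cutoff_es2, op,
              x$cutoff_es3))
  invisible(x)
}

#' Assign an Equivalent Score
#'
#' For `higher_is_worse`: ES 0 when the adjusted value is strictly beyond the
#' outer-limit cut-off, ES 4 when at or better than the median cut-off, with
#' the three intermediate classes bounded by the rank-subdivision cut-offs
#' (strict on the worse side, inclusive on the better side). The five classes
#' partition the real line; collapsed classes (adjacent equal cut-offs, legal
#' in the published bands) are simply skipped.
#'
#' @param adjusted numeric vector of adjusted scores.
#' @param bands a `tolerance_bands` object.
#' @return integer vector of Equivalent Scores 0-4 (`NA` for missing input).
#' @export
assign_es <- function(adjusted, bands) {
  stopifnot(inherits(bands, "tolerance_bands"))
  worse <- function(a, b) {
    if (bands$direction == "higher_is_worse") a > b else a < b
  }
  cuts <- c(bands$otl, bands$cutoff_es1, bands$cutoff_es2, bands$cutoff_es3)
  vapply(adjusted, function(v) {
    if (is.na(v)) return(NA_integer_)
    if (worse(v, cuts[1])) 0L
    else if (worse(v, cuts[2])) 1L
    else if (worse(v, cuts[3])) 2L
    else if (worse(v, cuts[4])) 3L
    else 4L
  }, integer(1))
}

#' Export tolerance bands as a one-row table
#'
#' Mirrors the published cut-off table layout: ITL, then the ES = 0..3 strict
#' cut-offs and the ES = 4 boundary.
#'
#' @param bands a `tolerance_bands` object or list of them.
#' @return data.frame with one row per score.
#' @export
bands_table <- function(bands) {
  if (inherits(bands, "tolerance_bands")) bands <- list(bands)
  do.call(rbind, lapply(bands, function(b) {
    data.frame(score = b$score_name, itl = b$itl, es0 = b$otl,
               es1 = b$cutoff_es1, es2 = b$cutoff_es2, es3 = b$cutoff_es3,
               es4 = b$cutoff_es3, direction = b$direction,
               stringsAsFactors = FALSE)
  }))
}
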