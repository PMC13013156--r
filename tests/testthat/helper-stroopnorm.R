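# shared fixtures, built in code

# reference stratum table scaled by an integer-ish factor to target n
scaled_stratum_table <- function(n_target) {
  st <- reference_stratum_table()
  k <- n_target / (sum(st$male) + sum(st$female))
  st$male <- round(st$male * k)
  st$female <- round(st$female * k)
  st
}

make_cohort <- function(seed = 1, n_target = NULL) {
  if (is.null(n_target)) {
    generate_cohort(cohort_spec(seed = seed))
  } else {
    st <- scaled_stratum_table(n_target)
    generate_cohort(cohort_spec(sum(st$male) + sum(st$female), st, seed = seed))
  }
}

# small random cohort with unstructured demographics, for regression oracles
random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = as.character(seq_len(n)),
             sex = sample(c("male", "female"), n, replace = TRUE),
             age = sample(20:90, n, replace = TRUE),
             education = sample(1:19, n, replace = TRUE),
             group = "healthy",
             y = rnorm(n), stringsAsFactors = FALSE)
}

# brute-force one-sided tolerance rank by direct binomial tail sums
brute_tolerance_rank <- function(n, coverage, confidence, side) {
  q <- 1 - coverage
  tail_ge <- function(r) sum(dbinom(r:n, n, q))      # P(X >= r)
  tail_le <- function(r) sum(dbinom(0:r, n, q))      # P(X <= r)
  if (side == "outer") {
    ok <- which(vapply(1:n, function(r) tail_ge(r) >= confidence, logical(1)))
    if (!length(ok)) return(NA_integer_)
    max(ok)
  } else {
    ok <- which(vapply(1:n, function(r) tail_le(r - 1) >= confidence, logical(1)))
    if (!length(ok)) return(NA_integer_)
    min(ok)
  }
}
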