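#' Reference demographic stratum table of the normative sample
#'
#' Frequencies of the 452 healthy participants by 5-year age band (20-90),
#' education band (0-4, 5-8, 9-13, 14-19 years) and sex. Row order is age band
#' within education band; zero cells are included so the table is a complete
#' 14 x 4 x 2 layout.
#'
#' @return data.frame with columns `age_lo`, `age_hi`, `edu_lo`, `edu_hi`,
#'   `male`, `female`.
#' @export
reference_stratum_table <- function() {
  age_lo <- c(20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85)
  age_hi <- c(24, 29, 34, 39, 44, 49, 54, 59, 64, 69, 74, 79, 84, 90)
  edu_lo <- c(0, 5, 9, 14)
  edu_hi <- c(4, 8, 13, 19)
  # counts by age band (rows) for each education band, males then females
  m <- list(
    `0-4`   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 1, 1, 2, 0),
    `5-8`   = c(0, 0, 0, 0, 1, 2, 1, 8, 4, 7, 5, 4, 1, 2),
    `9-13`  = c(0, 4, 5, 4, 5, 7, 5, 7, 5, 4, 5, 2, 4, 1),
    `14-19` = c(8, 5, 7, 9, 10, 7, 15, 9, 5, 5, 10, 5, 3, 3)
  )
  f <- list(
    `0-4`   = c(0, 0, 0, 0, 1, 0, 0, 1, 1, 1, 3, 3, 1, 3),
    `5-8`   = c(0, 0, 0, 0, 3, 3, 9, 6, 6, 7, 6, 9, 7, 2),
    `9-13`  = c(0, 2, 3, 7, 4, 7, 6, 6, 7, 6, 7, 2, 2, 1),
    `14-19` = c(6, 11, 8, 9, 16, 9, 17, 10, 9, 6, 9, 5, 3, 2)
  )
  out <- do.call(rbind, lapply(seq_along(edu_lo), function(j) {
    data.frame(age_lo = age_lo, age_hi = age_hi,
               edu_lo = edu_lo[j], edu_hi = edu_hi[j],
               male = m[[j]], female = f[[j]])
  }))
  rownames(out) <- NULL
  out
}

scwt_time_scores <- c("t1", "t2", "t3", "t4")
scwt_error_scores <- c("e1", "e2", "e3", "e4")

gen_term <- function(covariate, transform, coefficient, centring) {
  data.frame(covariate = covariate, transform = transform,
             coefficient = coefficient, centring = centring,
             stringsAsFactors = FALSE)
}

#' Default generating parameters for synthetic score panels
#'
#' Completion times are drawn as a linear predictor in transformed, centred
#' demographics plus Gaussian noise; error counts from a bounded beta-binomial
#' mechanism over the 50 items of a task. The default demographic effects are
#' the published correction-formula coefficients (for the scores whose printed
#' formula is internally consistent) or coefficients back-fitted to the
#' published band-midpoint correction grids; residual SDs follow from the
#' printed total SDs and model R-squared. Task 1 errors are constantly zero.
#'
#' @param group_shifts named list of additive shifts (on the linear predictor /
#'   mean count) applied to tasks 3 and 4 for the clinical groups.
#' @param time_floor lower truncation bound for simulated times, seconds.
#' @return list of per-score generating parameters, class `generator_params`.
#' @export
default_generator_params <- function(
    group_shifts = list(
      AD  = c(t3 = 15, t4 = 35, e3 = 2,   e4 = 8),
      MCI = c(t3 = 6,  t4 = 15, e3 = 0.7, e4 = 3)),
    time_floor = 0.5) {
  c_lned <- 2.3589319665131
  c_age3 <- 170912.989789193
  p <- list(
    t1 = list(type = "time", intercept = 24.701, sigma = 4.835,
              terms = rbind(gen_term("education", "ln", -3.3535984, c_lned),
                            gen_term("age", "cube", 1.71e-05, c_age3))),
    t2 = list(type = "time", intercept = 30.732, sigma = 7.027,
              terms = rbind(gen_term("education", "ln", -4.4905181, c_lned),
                            gen_term("age", "cube", 3.34e-05, c_age3))),
    t3 = list(type = "time", intercept = 28.907, sigma = 8.395,
              terms = rbind(gen_term("education", "ln", -5.8994342, c_lned),
                            gen_term("age", "cube", 3.48e-05, c_age3))),
    t4 = list(type = "time", intercept = 61.252, sigma = 13.627,
              terms = rbind(gen_term("education", "ln", -11.3886, c_lned),
                            gen_term("age", "cube", 7.5801e-05, c_age3))),
    e1 = list(type = "error", intercept = 0, rho = 0, terms = NULL),
    e2 = list(type = "error", intercept = 0.126, rho = 0.011,
              terms = gen_term("age", "cube", 1.2e-06, 170575.099525605)),
    e3 = list(type = "error", intercept = 0.175, rho = 0.04,
              terms = gen_term("age", "cube", 1.2e-06, c_age3)),
    e4 = list(type = "error", intercept = 1.918, rho = 0.04,
              terms = rbind(gen_term("education", "ln", -1.00938, c_lned),
                            gen_term("age", "cube", 5.50008e-06, c_age3)))
  )
  out <- list(scores = p, group_shifts = group_shifts, time_floor = time_floor)
  class(out) <- "generator_params"
  out
}

validate_generator_params <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  for (nm in scwt_time_scores) {
    if (params$scores[[nm]]$sigma < 0)
      stop("residual SD must be >= 0 for score ", nm, call. = FALSE)
  }
  for (nm in scwt_error_scores) {
    sc <- params$scores[[nm]]
    if (sc$intercept < 0) stop("error mean must be >= 0 for ", nm, call. = FALSE)
    if (sc$rho < 0 || sc$rho >= 1) stop("rho must be in [0, 1) for ", nm, call. = FALSE)
  }
  if (params$time_floor <= 0) stop("time_floor must be > 0", call. = FALSE)
  invisible(params)
}

#' Specify a synthetic cohort
#'
#' @param n_total number of participants; must equal the stratum table total.
#' @param stratum_counts data.frame as [reference_stratum_table()].
#' @param group `"healthy"`, `"AD"` or `"MCI"`. Clinical groups receive the
#'   configured additive deficits on tasks 3/4 and carry tasks 1/2 as missing
#'   (the retrospective patient records only include tasks 3 and 4).
#' @param seed integer seed; cohort generation is a pure function of
#'   (spec, seed).
#' @param score_params a `generator_params` object.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 452L,
                        stratum_counts = reference_stratum_table(),
                        group = c("healthy", "AD", "MCI"),
                        seed = 1L,
                        score_params = default_generator_params()) {
  group <- match.arg(group)
  validate_generator_params(score_params)
  total <- sum(stratum_counts$male) + sum(stratum_counts$female)
  if (total != n_total) {
    stop(sprintf("stratum counts sum to %d but n_total is %d", total, n_total),
         call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total), stratum_counts = stratum_counts,
                 group = group, seed = as.integer(seed),
                 score_params = score_params),
            class = "cohort_spec")
}

# linear predictor over transformed, centred demographics
linear_predictor <- function(intercept, terms, age, education) {
  lp <- rep(intercept, length(age))
  if (!is.null(terms)) {
    for (i in seq_len(nrow(terms))) {
      x <- if (terms$covariate[i] == "age") age else education
      lp <- lp + terms$coefficient[i] *
        (apply_transform(terms$transform[i], x) - terms$centring[i])
    }
  }
  lp
}

simulate_times <- function(sc, age, education, shift, floor) {
  lp <- linear_predictor(sc$intercept, sc$terms, age, education) + shift
  pmax(floor, lp + sc$sigma * stats::rnorm(length(age)))
}

simulate_errors <- function(sc, age, education, shift, n_items = 50L) {
  m <- pmax(0, linear_predictor(sc$intercept, sc$terms, age, education) + shift)
  p <- pmin(1, m / n_items)
  n <- length(age)
  if (sc$rho > 0) {
    nu <- 1 / sc$rho - 1
    pos <- p > 0 & p < 1
    pdraw <- p
    if (any(pos)) {
      pdraw[pos] <- stats::rbeta(sum(pos), p[pos] * nu, (1 - p[pos]) * nu)
    }
    p <- pdraw
  }
  stats::rbinom(n, n_items, p)
}

#' Simulate one raw score panel for a participant
#'
#' Draws the four completion times (linear predictor plus Gaussian noise,
#' truncated below at the configured floor) and four error counts (bounded
#' beta-binomial over 50 items) for a single participant, using the current
#' RNG state. With the residual SD at zero and all covariate coefficients at
#' zero the simulated time equals the configured intercept exactly.
#'
#' @param record one-row data.frame with `age`, `education`, `group`.
#' @param params a `generator_params` object.
#' @return one-row data.frame `t1, e1, t2, e2, t3, e3, t4, e4`.
#' @export
simulate_score_panel <- function(record, params = default_generator_params()) {
  simulate_panels(record$age, record$education, record$group, params)
}

simulate_panels <- function(age, education, group, params) {
  validate_generator_params(params)
  shifts <- if (group[1] != "healthy") params$group_shifts[[group[1]]] else NULL
  shift_of <- function(nm) if (!is.null(shifts) && nm %in% names(shifts)) shifts[[nm]] else 0
  out <- data.frame(row.names = seq_along(age))
  for (task in 1:4) {
    tn <- paste0("t", task); en <- paste0("e", task)
    out[[tn]] <- simulate_times(params$scores[[tn]], age, education,
                                shift_of(tn), params$time_floor)
    out[[en]] <- simulate_errors(params$scores[[en]], age, education,
                                 shift_of(en))
  }
  # retrospective clinical records only carry tasks 3 and 4
  if (group[1] != "healthy") {
    out[c("t1", "e1", "t2", "e2")] <- NA_real_
  }
  out[c("t1", "e1", "t2", "e2", "t3", "e3", "t4", "e4")]
}

#' Generate a synthetic cohort
#'
#' Demographics reproduce the stratum table exactly (no sampling slack): each
#' participant's age is drawn uniformly over the integer years of their age
#' band and education uniformly over the integer years of their education band
#' (with a lower bound of 1 year, since the generating models take the log of
#' education). Score panels are then simulated per [simulate_score_panel()].
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id, sex, age, education, group,
#'   t1, e1, t2, e2, t3, e3, t4, e4`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  st <- spec$stratum_counts
  rows <- list()
  for (i in seq_len(nrow(st))) {
    for (sex in c("male", "female")) {
      k <- st[[sex]][i]
      if (k == 0) next
      age <- sample(seq(st$age_lo[i], st$age_hi[i]), k, replace = TRUE)
      edu <- sample(seq(max(1, st$edu_lo[i]), st$edu_hi[i]), k, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(sex = sex, age = age,
                                             education = edu,
                                             stringsAsFactors = FALSE)
    }
  }
  demo <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sex = character(), age = numeric(), education = numeric())
  n <- nrow(demo)
  out <- data.frame(id = sprintf("%s-%04d", spec$group, seq_len(n)),
                    sex = demo$sex, age = demo$age, education = demo$education,
                    group = rep(spec$group, n), stringsAsFactors = FALSE)
  if (n > 0) {
    out <- cbind(out, simulate_panels(out$age, out$education, spec$group,
                                      spec$score_params))
  } else {
    for (nm in c("t1", "e1", "t2", "e2", "t3", "e3", "t4", "e4"))
      out[[nm]] <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic clinical (AD or MCI) cohort
#'
#' Convenience sampler for validation studies: demographics are drawn from
#' truncated normal distributions matching the retrospective patient samples
#' (AD: age 75.5 (6.6), education 8.2 (4.5), 63% female, MMSE 18.8 (4.3);
#' MCI: age 72.2 (9.5), education 9.0 (4.2), 49% female, MMSE 25.9 (2.4)),
#' and score panels carry the configured group deficits on tasks 3 and 4,
#' with tasks 1 and 2 missing.
#'
#' @param n number of patients.
#' @param group `"AD"` or `"MCI"`.
#' @param seed integer seed.
#' @param score_params a `generator_params` object.
#' @return data.frame as [generate_cohort()], plus an `mmse` column.
#' @export
generate_clinical_cohort <- function(n, group = c("AD", "MCI"), seed = 1L,
                                     score_params = default_generator_params()) {
  group <- match.arg(group)
  validate_generator_params(score_params)
  set.seed(seed)
  par <- switch(group,
    AD  = list(age = c(75.5, 6.6), edu = c(8.2, 4.5), pf = 0.63, mmse = c(18.8, 4.3)),
    MCI = list(age = c(72.2, 9.5), edu = c(9.0, 4.2), pf = 0.49, mmse = c(25.9, 2.4)))
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  age <- clip(round(stats::rnorm(n, par$age[1], par$age[2])), 50, 90)
  edu <- clip(round(stats::rnorm(n, par$edu[1], par$edu[2])), 1, 19)
  sex <- ifelse(stats::runif(n) < par$pf, "female", "male")
  mmse <- clip(round(stats::rnorm(n, par$mmse[1], par$mmse[2]), 1), 0, 30)
  out <- data.frame(id = sprintf("%s-%04d", group, seq_len(n)), sex = sex,
                    age = age, education = edu, group = rep(group, n),
                    stringsAsFactors = FALSE)
  out <- cbind(out, simulate_panels(age, edu, group, score_params))
  out$mmse <- mmse
  out
}
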