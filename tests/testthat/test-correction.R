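test_that("published formulas reproduce spot-checked grid cells at 2 d.p.", {
  rha <- stroopnorm:::round_half_away
  expect_equal(rha(published_correction("t1", 22, 2)), -2.85)
  expect_equal(rha(published_correction("t2", 22, 2)), -2.13)
  expect_equal(rha(published_correction("t2", 87.5, 16.5)), -14.67)
  expect_equal(rha(published_correction("t3", 22, 2)), -4.25)
  expect_equal(rha(published_correction("e3", 87.5)), -0.60)
  expect_equal(rha(published_correction("e2", 22)), 6.14)
  expect_equal(rha(published_correction("t3_t1", 22, 2)), -4.81)
  expect_equal(rha(published_correction("t4_t2", 22, 2)), 4.26)
  expect_equal(rha(published_correction("e4_e2", 87.5, 16.5)), -2.08)
})

test_that("correction is exactly zero at the centring covariates", {
  norms <- load_published_norms()
  m <- norms$t1$model
  age0 <- m$terms$centring[m$terms$covariate == "age"]^(1 / 3)
  edu0 <- exp(m$terms$centring[m$terms$covariate == "education"])
  expect_equal(correction_term(m, age0, edu0), 0, tolerance = 1e-12)
  expect_equal(apply_correction(30, m, age0, edu0), 30, tolerance = 1e-12)
})

test_that("grids regenerate every printed cell of the consistent scores", {
  norms <- load_published_norms()
  consistent <- c("t1", "t2", "t3", "e2", "e3", "t4_t2", "t3_t1", "e4_e2")
  for (key in consistent) {
    entry <- norms[[key]]
    expect_true(entry$consistent)
    regen <- build_norm_grid(entry$model, round = 2)
    expect_equal(unclass(regen), unclass(entry$grid),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the four flagged scores keep the as-published formula and a grid mode", {
  norms <- load_published_norms()
  for (key in c("t4", "e4", "t4_t3", "e4_e3")) {
    entry <- norms[[key]]
    expect_false(entry$consistent)
    regen <- build_norm_grid(entry$model, round = 2)
    expect_gt(max(abs(unclass(regen) - unclass(entry$grid))), 0.01)
    # grid-lookup mode serves the printed cells
    expect_equal(published_correction(key, 22, 2, mode = "grid"),
                 unclass(entry$grid)[1, 1])
  }
})

test_that("grid lookup assigns the nearest band, inside and beyond the range", {
  norms <- load_published_norms()
  g <- norms$t4$grid
  expect_equal(grid_correction(g, age = c(20, 24, 90), education = c(2, 4, 19)),
               c(unclass(g)[1, 1], unclass(g)[1, 1], unclass(g)[4, 14]))
  # age 19 (below range) maps to the first band; education 25 to the last
  expect_equal(grid_correction(g, 19, 25), unclass(g)[4, 1])
})

test_that("corrections remove the predicted demographic (dis)advantage", {
  m <- load_published_norms()$t1$model
  # old age, low education: predicted slow, so the expected excess time is
  # subtracted (negative correction, cf. the printed -14.12 cell)
  expect_lt(correction_term(m, 87.5, 2), 0)
  # young, highly educated: predicted fast, so time is added back (+4.23 cell)
  expect_gt(correction_term(m, 22, 16.5), 0)
  # the correction is minus the centred linear prediction, exactly
  pred <- function(age, edu) {
    t <- m$terms
    sum(t$coefficient * c(log(edu) - t$centring[1], age^3 - t$centring[2]))
  }
  expect_equal(correction_term(m, 70, 8), -pred(70, 8), tolerance = 1e-12)
  # monotone in age within an education row (monotone age transform)
  grid <- build_norm_grid(m, round = NULL)
  for (i in seq_len(nrow(grid)))
    expect_true(all(diff(unclass(grid)[i, ]) < 0))
})

test_that("apply_correction inverts exactly and honours the error floor", {
  m <- load_published_norms()$e3$model
  raw <- c(0, 1.2, 7)
  adj <- apply_correction(raw, m, age = 70, education = 10)
  expect_equal(adj - correction_term(m, 70, 10), raw, tolerance = 1e-12)
  floored <- apply_correction(0, m, age = 87.5, education = 10,
                              floor_at_zero = TRUE)
  expect_equal(floored, 0)  # correction -0.60 would go negative
})

test_that("correction models from fits round-trip the fitted coefficients", {
  co <- make_cohort(seed = 17, n_target = 400)
  fit <- fit_model(list(sex = FALSE, age_transform = "cube",
                        education_transform = "ln"), co, "t4")
  attr(fit, "response") <- "t4"
  m <- as_correction_model(fit)
  # at the centring values the correction vanishes; slope signs flip
  expect_equal(correction_term(m, mean(co$age^3)^(1 / 3),
                               exp(mean(log(co$education)))),
               0, tolerance = 1e-10)
  expect_equal(m$terms$coefficient[m$terms$covariate == "age"],
               unname(fit$coefficients[["age"]]))
})

test_that("unknown published score names error", {
  expect_error(published_correction("t9", 40, 10), "unknown published score")
})

test_that("half-away-from-zero display rounding", {
  rha <- stroopnorm:::round_half_away
  # 0.125 is exactly representable: half-away gives 0.13 where half-to-even
  # (base round) gives 0.12
  expect_equal(rha(c(0.125, -0.125, 1.4, -1.4)), c(0.13, -0.13, 1.4, -1.4))
})
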