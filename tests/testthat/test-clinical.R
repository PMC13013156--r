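test_that("AUC matches brute-force pair counting", {
  brute_auc <- function(pos, neg) {
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(3, 5, 7), c(2, 4, 6)), brute_auc(c(3, 5, 7), c(2, 4, 6)))
  expect_equal(roc_auc(c(10, 11), c(1, 2)), 1.0)
  expect_equal(roc_auc(rep(4, 5), rep(4, 3)), 0.5)
  set.seed(31)
  for (r in 1:20) {
    pos <- sample(0:20, sample(3:40, 1), replace = TRUE)
    neg <- sample(0:20, sample(3:40, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1:3), "empty group")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  pos <- rnorm(60, 1)
  neg <- rnorm(80)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 60), rep(0, 80)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(pos, neg), ref, tolerance = 1e-12)
})

test_that("Youden cut-point matches an exhaustive candidate scan", {
  brute_youden <- function(pos, neg) {
    v <- sort(unique(c(pos, neg)))
    cand <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
    best <- NULL
    for (c0 in cand) {
      sens <- mean(pos > c0); spec <- mean(neg <= c0)
      j <- sens + spec - 1
      if (is.null(best) || j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && (spec > best$spec + 1e-12 ||
            (abs(spec - best$spec) <= 1e-12 && c0 < best$c)))) {
        best <- list(c = c0, j = j, spec = spec)
      }
    }
    best
  }
  set.seed(13)
  for (r in 1:20) {
    pos <- round(rnorm(sample(4:25, 1), 1.2), 1)
    neg <- round(rnorm(sample(4:25, 1)), 1)
    got <- youden_cutpoint(pos, neg)
    want <- brute_youden(pos, neg)
    expect_equal(got$cut_point, want$c)
    expect_equal(got$youden, want$j, tolerance = 1e-12)
  }
})

test_that("perfect and degenerate separations are handled at the boundaries", {
  rep1 <- youden_cutpoint(c(8, 9, 10), c(1, 2, 3))
  expect_equal(rep1$youden, 1)
  expect_gt(rep1$cut_point, 3)
  expect_lt(rep1$cut_point, 8)
  # pathological group entirely below the controls: J maximised at a boundary,
  # returned without error
  rep2 <- youden_cutpoint(c(0.5), c(1, 2, 3))
  expect_true(is.finite(rep2$youden))
  expect_true(rep2$specificity == 1 || rep2$sensitivity == 1)
})

test_that("confusion metrics follow the standard definitions", {
  m <- confusion_metrics(tp = 8, fp = 1, tn = 9, fn = 2)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$ppv, 8 / 9)
  expect_equal(m$npv, 9 / 11)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$prevalence, 0.5)
  expect_equal(confusion_metrics(3, 0, 5, 1)$ppv, 1.0)
  expect_true(is.na(confusion_metrics(0, 0, 5, 2)$ppv))
  expect_error(confusion_metrics(0, 0, 5, 0), "at least one positive")
})

test_that("accuracy identity holds over random confusion tables", {
  set.seed(19)
  for (r in 1:50) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (tab[1] + tab[4] == 0 || tab[2] + tab[3] == 0) next
    m <- confusion_metrics(tab[1], tab[2], tab[3], tab[4])
    expect_equal(m$accuracy,
                 m$prevalence * m$sensitivity +
                   (1 - m$prevalence) * m$specificity,
                 tolerance = 1e-12)
  }
})

test_that("youden_cutpoint report is internally consistent", {
  set.seed(23)
  pos <- rnorm(40, 1.5)
  neg <- rnorm(60)
  rep <- youden_cutpoint(pos, neg)
  expect_equal(rep$youden, rep$sensitivity + rep$specificity - 1,
               tolerance = 1e-12)
  expect_equal(rep$auc, roc_auc(pos, neg), tolerance = 1e-12)
})

test_that("AUC and the cut-point are invariant to increasing transforms", {
  set.seed(29)
  pos <- rnorm(30, 1)
  neg <- rnorm(30)
  f <- function(x) exp(x / 2)
  expect_equal(roc_auc(f(pos), f(neg)), roc_auc(pos, neg), tolerance = 1e-12)
  r1 <- youden_cutpoint(pos, neg)
  r2 <- youden_cutpoint(f(pos), f(neg))
  expect_equal(r2$youden, r1$youden, tolerance = 1e-12)
  expect_equal(r2$sensitivity, r1$sensitivity)
  expect_equal(r2$specificity, r1$specificity)
})

test_that("ES frequency tables count levels on the non-missing n", {
  es <- data.frame(t4 = c(0, 0, 0, 0), t3 = c(1, 4, NA, 0))
  tab <- es_frequency_table(es, group = "AD")
  t4row <- tab[tab$score == "t4" & tab$es == 0, ]
  expect_equal(t4row$n, 4)
  expect_equal(t4row$pct, 100)
  t3 <- tab[tab$score == "t3", ]
  expect_equal(sum(t3$n), 3)
  expect_equal(sum(t3$pct), 100, tolerance = 0.02)
  empty <- es_frequency_table(data.frame(t4 = NA_integer_), "none")
  expect_true(all(empty$n == 0))
})

test_that("percentile table recovers closed-form tail shares", {
  # identical distributions: ~ (100 - p)% worse than the pth percentile
  set.seed(37)
  h <- rnorm(20000)
  tab <- percentile_table(h, list(same = h), probs = c(0.25, 0.75))
  expect_equal(tab$worse_same, c(0.75, 0.25), tolerance = 0.01)
  # everyone worse
  tab2 <- percentile_table(c(1, 2, 3), list(bad = c(10, 11)))
  expect_true(all(tab2$worse_bad == 1))
  # shifted normal patients match the analytic tail probability
  pat <- rnorm(20000, mean = 1)
  tab3 <- percentile_table(h, list(ad = pat), probs = 0.95)
  expect_equal(tab3$worse_ad, pnorm(1 - qnorm(0.95)), tolerance = 0.02)
})

test_that("synthetic AD separates from healthy more than MCI does", {
  healthy <- make_cohort(seed = 51, n_target = 300)
  wins <- 0
  for (r in 1:10) {
    ad <- generate_clinical_cohort(80, "AD", seed = 700 + r)
    mci <- generate_clinical_cohort(80, "MCI", seed = 800 + r)
    if (roc_auc(ad$t4, healthy$t4) > roc_auc(mci$t4, healthy$t4))
      wins <- wins + 1
  }
  expect_gte(wins, 10 * 0.95 - 1)
})
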