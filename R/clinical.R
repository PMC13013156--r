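#' Area under the ROC curve by the rank-statistic definition
#'
#' `AUC = P(pos > neg) + 0.5 P(pos = neg)` over all pathological/healthy
#' pairs, computed from midranks; higher scores indicate pathology.
#'
#' @param scores_pos adjusted scores of the pathological group.
#' @param scores_neg adjusted scores of the comparison (healthy) group.
#' @return numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) stop("empty group in ROC comparison", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from a confusion table
#'
#' Standard definitions: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' prevalence `(tp+fn)/total`, accuracy `(tp+tn)/total`, `ppv = tp/(tp+fp)`,
#' `npv = tn/(tn+fn)`. A zero-denominator ratio is reported as `NA`, not 0.
#'
#' @param tp,fp,tn,fn non-negative counts; at least one positive and one
#'   negative case overall.
#' @return named list of proportions.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one positive and one negative case", call. = FALSE)
  total <- tp + fp + tn + fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       prevalence = (tp + fn) / total, accuracy = (tp + tn) / total,
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn))
}

#' Youden-optimal ROC cut-point
#'
#' Evaluates the Youden index `J(c) = sensitivity(c) + specificity(c) - 1`
#' at every candidate cut-point -- the midpoints between adjacent distinct
#' pooled values, plus the two infinities -- with a value above the cut-point
#' classified as pathological (strict `>`). Ties in `J` are broken toward
#' higher specificity, then toward the lower cut-point. Degenerate contrasts
#' where the maximiser sits at an infinite boundary are returned without
#' error.
#'
#' @inheritParams roc_auc
#' @param contrast optional label for the group comparison.
#' @param score_name optional score label.
#' @return object of class `roc_report`: cut-point, Youden index, AUC, and
#'   the full metrics bundle at the cut-point.
#' @export
youden_cutpoint <- function(scores_pos, scores_neg, contrast = "pos/neg",
                            score_name = "score") {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (!length(scores_pos) || !length(scores_neg))
    stop("empty group in ROC comparison", call. = FALSE)
  v <- sort(unique(c(scores_pos, scores_neg)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(cand, function(c) mean(scores_pos > c), numeric(1))
  spec <- vapply(cand, function(c) mean(scores_neg <= c), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -spec, cand)[1]
  tp <- sum(scores_pos > cand[best]); fn <- length(scores_pos) - tp
  tn <- sum(scores_neg <= cand[best]); fp <- length(scores_neg) - tn
  metrics <- confusion_metrics(tp, fp, tn, fn)
  out <- c(list(contrast = contrast, score_name = score_name,
                cut_point = cand[best], youden = j[best],
                auc = roc_auc(scores_pos, scores_neg)),
           metrics)
  class(out) <- "roc_report"
  out
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC %s, %s: cut-point %.3f (score > cut-point = pathological)\n",
              x$score_name, x$contrast, x$cut_point))
  cat(sprintf("  Youden %.3f | AUC %.3f | sens %.3f | spec %.3f | acc %.3f | prev %.3f | PPV %s | NPV %s\n",
              x$youden, x$auc, x$sensitivity, x$specificity, x$accuracy,
              x$prevalence, format(round(x$ppv, 3)), format(round(x$npv, 3))))
  invisible(x)
}

#' Equivalent-Score frequency table for a clinical group
#'
#' Counts and percentages of ES levels 0-4, per score, over the group's
#' non-missing assignments.
#'
#' @param es data.frame of ES assignments (columns = scores, rows =
#'   participants; values 0-4 or `NA`).
#' @param group group label for the table.
#' @return data.frame with one row per (score, ES level): `n`, `pct`
#'   (percentage of the score's non-missing n, rounded to 2 decimals).
#' @export
es_frequency_table <- function(es, group = "group") {
  out <- list()
  for (score in names(es)) {
    x <- es[[score]]
    x <- x[!is.na(x)]
    counts <- vapply(0:4, function(l) sum(x == l), numeric(1))
    tot <- length(x)
    out[[score]] <- data.frame(
      group = group, score = score, es = 0:4, n = counts,
      pct = if (tot > 0) round_half_away(100 * counts / tot, 2) else rep(0, 5),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentiles of the healthy distribution and patient exceedance shares
#'
#' For each requested percentile of the healthy adjusted distribution,
#' reports the share of each patient group with a worse score
#' (direction-aware).
#'
#' @param healthy_adjusted adjusted scores of the normative sample.
#' @param patient_adjusted named list of adjusted-score vectors, one per
#'   clinical group.
#' @param probs percentile levels in `(0, 1)`.
#' @param direction score polarity, as in [compute_bands()].
#' @return data.frame with the percentile level, the healthy quantile, and
#'   one exceedance-share column per patient group.
#' @export
percentile_table <- function(healthy_adjusted, patient_adjusted,
                             probs = c(.05, .10, .25, .50, .75, .90, .95),
                             direction = c("higher_is_worse", "lower_is_worse")) {
  direction <- match.arg(direction)
  healthy_adjusted <- healthy_adjusted[!is.na(healthy_adjusted)]
  if (!length(healthy_adjusted)) stop("empty healthy sample", call. = FALSE)
  qs <- stats::quantile(healthy_adjusted, probs, names = FALSE, type = 7)
  out <- data.frame(percentile = 100 * probs, healthy_quantile = qs)
  for (g in names(patient_adjusted)) {
    x <- patient_adjusted[[g]]
    x <- x[!is.na(x)]
    out[[paste0("worse_", g)]] <- vapply(qs, function(q) {
      if (!length(x)) return(NA_real_)
      if (direction == "higher_is_worse") mean(x > q) else mean(x < q)
    }, numeric(1))
  }
  out
}
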