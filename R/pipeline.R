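norming_scores_default <- c("t1", "t2", "t3", "t4", "e2", "e3", "e4",
                            "t3_t1", "t4_t2", "t4_t3", "e4_e2", "e4_e3")

#' Derive a norm set from a normative cohort
#'
#' Runs the full norming procedure per score: exhaustive transformed-covariate
#' model space, BIC-with-parsimony selection, conversion of the selected fit
#' into a demographic correction model, band-midpoint correction grid,
#' demographic adjustment of the cohort, and non-parametric tolerance limits
#' with Equivalent-Score cut-offs on the adjusted scores.
#'
#' @param cohort healthy cohort data.frame ([generate_cohort()] layout).
#' @param scores score names to norm (raw tasks and difference indices).
#' @param include_ln100 include the `ln(100 - age)` age transform in the
#'   model space (112 candidate models instead of 98).
#' @param coverage,confidence tolerance-limit parameters.
#' @param bonferroni_family Bonferroni family size for covariate significance;
#'   `NULL` uses the number of terms in each selected model.
#' @return object of class `scwt_norms`: per score, the selected fit, the
#'   correction model, the norm grid, the tolerance bands and the covariate
#'   significance flags.
#' @export
derive_norms <- function(cohort, scores = norming_scores_default,
                         include_ln100 = FALSE, coverage = 0.95,
                         confidence = 0.95, bonferroni_family = NULL) {
  dat <- add_indices(cohort)
  entries <- lapply(scores, function(score) {
    fits <- fit_model_space(dat, score, include_ln100)
    best <- select_best(fits)
    attr(best, "response") <- score
    model <- as_correction_model(best)
    adj <- dat[[score]] + correction_term(model, dat$age, dat$education,
                                          dat$sex)
    bands <- compute_bands(adj, score, "higher_is_worse", coverage, confidence)
    fam <- if (is.null(bonferroni_family)) max(1, length(best$p_values)) else
      bonferroni_family
    list(key = score, label = toupper(gsub("_", "-", score)),
         direction = "higher_is_worse", consistent = TRUE,
         fit = best, model = model,
         grid = build_norm_grid(model), bands = bands,
         significance = covariate_significance(best, fam))
  })
  names(entries) <- scores
  structure(entries, class = "scwt_norms")
}

#' @export
print.scwt_norms <- function(x, ...) {
  cat("Derived norm set for", length(x), "scores\n")
  for (e in x) {
    cat(sprintf("  %-6s %s  (BIC %.1f, R^2 %.2f)\n", e$key,
                format(e$fit$model), e$fit$bic, e$fit$r_squared))
  }
  invisible(x)
}

#' Selected-model summary of a derived norm set
#'
#' @param norms an `scwt_norms` object.
#' @return data.frame: score, selected model formula, BIC, R-squared, k.
#' @export
selected_models_table <- function(norms) {
  stopifnot(inherits(norms, "scwt_norms"))
  do.call(rbind, lapply(norms, function(e) {
    data.frame(score = e$key, model = format(e$fit$model), bic = e$fit$bic,
               r_squared = e$fit$r_squared, k = e$fit$k,
               stringsAsFactors = FALSE)
  }))
}

#' Adjust raw scores and assign Equivalent Scores
#'
#' Applies a norm set -- the frozen published norms by default, or a set
#' derived by [derive_norms()] -- to participant records: raw scores and
#' difference indices are demographically corrected, and each corrected score
#' receives an Equivalent Score from the norm set's cut-offs.
#'
#' @param records data.frame in the cohort layout (raw task scores; the six
#'   difference indices are computed on the fly).
#' @param norms a norm set: [load_published_norms()] output or `scwt_norms`.
#' @param floor_errors floor corrected error scores at zero.
#' @return list with `adjusted` and `es` data.frames (one column per normed
#'   score, rows aligned to `records`).
#' @export
score_records <- function(records, norms = load_published_norms(),
                          floor_errors = FALSE) {
  dat <- add_indices(records)
  adjusted <- data.frame(row.names = seq_len(nrow(dat)))
  es <- data.frame(row.names = seq_len(nrow(dat)))
  for (key in names(norms)) {
    entry <- norms[[key]]
    if (!key %in% names(dat)) next
    corr <- if (isTRUE(entry$consistent)) {
      correction_term(entry$model, dat$age, dat$education, dat$sex)
    } else {
      grid_correction(entry$grid, dat$age, dat$education)
    }
    adj <- dat[[key]] + corr
    if (floor_errors && startsWith(key, "e")) adj <- pmax(0, adj)
    adjusted[[key]] <- adj
    es[[key]] <- assign_es(adj, entry$bands)
  }
  rownames(adjusted) <- rownames(es) <- NULL
  list(adjusted = adjusted, es = es)
}

clinical_scores_default <- c("t4", "t3", "e4", "e3", "t4_t3", "e4_e3")

#' Clinical validation of a norm set
#'
#' Scores the healthy and patient groups against the norm set, then reports
#' the Equivalent-Score frequency tables per clinical group, Youden-optimal
#' ROC analyses for each group contrast (patients coded as the positive,
#' higher-scoring class), and the percentile table of healthy adjusted scores
#' with patient exceedance shares.
#'
#' @param healthy healthy cohort data.frame.
#' @param patients patient data.frame with a `group` column (`"AD"`, `"MCI"`).
#' @param norms a norm set, as in [score_records()].
#' @param scores scores to validate (the clinical records carry tasks 3/4).
#' @return list with `es_tables`, `roc` (list of `roc_report` by contrast and
#'   score) and `percentiles`.
#' @export
validate_clinical <- function(healthy, patients, norms = load_published_norms(),
                              scores = clinical_scores_default) {
  h <- score_records(healthy, norms)
  groups <- split(patients, patients$group)
  scored <- lapply(groups, score_records, norms = norms)
  es_tables <- list()
  for (g in names(scored))
    es_tables[[g]] <- es_frequency_table(scored[[g]]$es[scores], g)
  if (length(scored) > 1) {
    pooled <- do.call(rbind, lapply(scored, function(s) s$es[scores]))
    es_tables$combined <- es_frequency_table(pooled, "combined")
  }
  contrasts <- list()
  for (g in names(scored))
    contrasts[[paste0(g, "/healthy")]] <- list(pos = scored[[g]]$adjusted,
                                               neg = h$adjusted)
  if (all(c("AD", "MCI") %in% names(scored)))
    contrasts[["AD/MCI"]] <- list(pos = scored$AD$adjusted,
                                  neg = scored$MCI$adjusted)
  roc <- lapply(names(contrasts), function(cn) {
    cc <- contrasts[[cn]]
    out <- lapply(scores, function(s)
      youden_cutpoint(cc$pos[[s]], cc$neg[[s]], contrast = cn, score_name = s))
    names(out) <- scores
    out
  })
  names(roc) <- names(contrasts)
  percentiles <- lapply(scores, function(s)
    percentile_table(h$adjusted[[s]],
                     lapply(scored, function(x) x$adjusted[[s]])))
  names(percentiles) <- scores
  list(es_tables = es_tables, roc = roc, percentiles = percentiles)
}

#' Serialise a derived norm set to JSON
#'
#' Writes the selected model per score (transforms, coefficients, centring
#' constants, fit summary) and the tolerance bands; [read_norms_json()]
#' restores a norm set usable by [score_records()].
#'
#' @param norms an `scwt_norms` object.
#' @param path output file.
#' @export
write_norms_json <- function(norms, path) {
  stopifnot(inherits(norms, "scwt_norms"))
  out <- list(package = "stroopnorm",
              version = as.character(utils::packageVersion("stroopnorm")),
              scores = lapply(norms, function(e) {
                t <- e$model$terms
                list(label = e$label, direction = e$direction,
                     model = format(e$fit$model),
                     intercept = e$fit$intercept, bic = e$fit$bic,
                     r_squared = e$fit$r_squared, n = e$fit$n, k = e$fit$k,
                     terms = lapply(seq_len(nrow(t)), function(i)
                       as.list(t[i, ])),
                     bands = list(itl = e$bands$itl, es0 = e$bands$otl,
                                  es1 = e$bands$cutoff_es1,
                                  es2 = e$bands$cutoff_es2,
                                  es3 = e$bands$cutoff_es3,
                                  coverage = e$bands$coverage,
                                  confidence = e$bands$confidence))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norms_json
#' @export
read_norms_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(names(raw$scores), function(key) {
    sc <- raw$scores[[key]]
    terms <- do.call(rbind, lapply(sc$terms, function(t)
      gen_term(t$covariate, t$transform, t$coefficient, t$centring)))
    model <- correction_model(key, terms)
    bands <- new_tolerance_bands(key, sc$direction, otl = sc$bands$es0,
                                 itl = sc$bands$itl,
                                 cutoff_es1 = sc$bands$es1,
                                 cutoff_es2 = sc$bands$es2,
                                 cutoff_es3 = sc$bands$es3,
                                 coverage = sc$bands$coverage,
                                 confidence = sc$bands$confidence)
    list(key = key, label = sc$label, direction = sc$direction,
         consistent = TRUE, model = model, grid = build_norm_grid(model),
         bands = bands)
  })
  names(entries) <- names(raw$scores)
  entries
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  opts
}

cli_usage <- function() {
  paste(
    "usage: stroopnorm <command> [options]",
    "commands:",
    "  simulate --out FILE [--seed N] [--group healthy|AD|MCI] [--n N]",
    "  fit      --in FILE --score NAME [--ln100] --out FILE",
    "  norm     --in FILE --out-dir DIR [--ln100]",
    "  score    --in FILE --out FILE [--norms FILE]",
    "  validate --healthy FILE --patients FILE --out-dir DIR [--norms FILE]",
    "options may also be supplied via --config FILE (YAML); flags override it",
    sep = "\n")
}

#' Command-line entry point
#'
#' Thin shell over the pipeline functions; see `inst/cli/stroopnorm.R` for
#' the executable wrapper. Subcommands: `simulate` (synthetic cohort CSV),
#' `fit` (model-space report for one score), `norm` (derive and export a norm
#' set: selected models JSON, grids and bands CSV), `score` (corrected scores
#' and Equivalent Scores for records), `validate` (clinical validation
#' tables). Every run logs the seed, the configuration and the package
#' version to standard error; identical configuration and seed give
#' identical artifacts.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args) {
  if (!length(args) || args[[1]] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(args)) 0L else 1L))
  }
  cmd <- args[[1]]
  status <- tryCatch({
    opts <- parse_cli_args(args[-1])
    if (!is.null(opts$config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("--config requires the 'yaml' package", call. = FALSE)
      cfg <- yaml::read_yaml(opts$config)
      # command-line flags override the config file
      for (key in setdiff(names(cfg), names(opts))) opts[[key]] <- cfg[[key]]
    }
    log_run(cmd, opts)
    switch(cmd,
      simulate = cli_simulate(opts),
      fit = cli_fit(opts),
      norm = cli_norm(opts),
      score = cli_score(opts),
      validate = cli_validate(opts),
      {
        message("unknown subcommand: ", cmd)
        cat(cli_usage(), "\n")
        return(invisible(1L))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

log_run <- function(cmd, opts) {
  cfg <- paste(names(opts), vapply(opts, as.character, character(1)),
               sep = "=", collapse = " ")
  message(sprintf("[stroopnorm %s] %s seed=%s config-hash=%08x",
                  utils::packageVersion("stroopnorm"), cmd,
                  opts$seed %||% "1",
                  sum(utf8ToInt(paste(cmd, cfg)) *
                        seq_along(utf8ToInt(paste(cmd, cfg)))) %% 0xffffffff))
}

req <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key, call. = FALSE)
  opts[[key]]
}

cli_simulate <- function(opts) {
  seed <- as.integer(opts$seed %||% 1)
  group <- opts$group %||% "healthy"
  if (group == "healthy") {
    cohort <- generate_cohort(cohort_spec(seed = seed))
  } else {
    cohort <- generate_clinical_cohort(as.integer(opts$n %||% 130), group,
                                       seed = seed)
  }
  write_cohort(cohort, req(opts, "out"))
}

cli_fit <- function(opts) {
  cohort <- read_cohort(req(opts, "in"))
  report <- model_space_report(add_indices(cohort), req(opts, "score"),
                               include_ln100 = isTRUE(opts$ln100))
  utils::write.csv(report, req(opts, "out"), row.names = FALSE)
}

cli_norm <- function(opts) {
  cohort <- read_cohort(req(opts, "in"))
  dir <- req(opts, "out-dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norms <- derive_norms(cohort, include_ln100 = isTRUE(opts$ln100),
                        coverage = as.numeric(opts$coverage %||% 0.95),
                        confidence = as.numeric(opts$confidence %||% 0.95))
  write_norms_json(norms, file.path(dir, "norms.json"))
  utils::write.csv(selected_models_table(norms),
                   file.path(dir, "selected_models.csv"), row.names = FALSE)
  utils::write.csv(bands_table(lapply(norms, function(e) e$bands)),
                   file.path(dir, "bands.csv"), row.names = FALSE)
  for (e in norms) {
    utils::write.csv(as.data.frame(unclass(e$grid)),
                     file.path(dir, paste0("grid_", e$key, ".csv")))
  }
}

cli_score <- function(opts) {
  records <- read_cohort(req(opts, "in"))
  norms <- if (is.null(opts$norms)) load_published_norms() else
    read_norms_json(opts$norms)
  scored <- score_records(records, norms)
  out <- cbind(records[c("id", "sex", "age", "education", "group")],
               stats::setNames(scored$adjusted,
                               paste0(names(scored$adjusted), "_adj")),
               stats::setNames(scored$es, paste0(names(scored$es), "_es")))
  utils::write.csv(out, req(opts, "out"), row.names = FALSE, na = "")
}

cli_validate <- function(opts) {
  healthy <- read_cohort(req(opts, "healthy"))
  patients <- read_cohort(req(opts, "patients"))
  norms <- if (is.null(opts$norms)) load_published_norms() else
    read_norms_json(opts$norms)
  dir <- req(opts, "out-dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  val <- validate_clinical(healthy, patients, norms)
  utils::write.csv(do.call(rbind, val$es_tables),
                   file.path(dir, "es_frequencies.csv"), row.names = FALSE)
  roc_rows <- do.call(rbind, lapply(names(val$roc), function(cn)
    do.call(rbind, lapply(val$roc[[cn]], function(r)
      data.frame(contrast = cn, score = r$score_name, cut_point = r$cut_point,
                 youden = r$youden, auc = r$auc, sensitivity = r$sensitivity,
                 specificity = r$specificity, accuracy = r$accuracy,
                 prevalence = r$prevalence, ppv = r$ppv, npv = r$npv)))))
  utils::write.csv(roc_rows, file.path(dir, "roc.csv"), row.names = FALSE)
  for (s in names(val$percentiles))
    utils::write.csv(val$percentiles[[s]],
                     file.path(dir, paste0("percentiles_", s, ".csv")),
                     row.names = FALSE)
}
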