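.norms_cache <- new.env(parent = emptyenv())

parse_band_labels <- function(labels) {
  lo <- as.numeric(sub("-.*", "", labels))
  hi <- as.numeric(sub(".*-", "", labels))
  data.frame(lo = lo, hi = hi, mid = (lo + hi) / 2, label = labels,
             stringsAsFactors = FALSE)
}

#' Load the frozen published norm set
#'
#' Returns, for each of the twelve published performance indices, the exact
#' correction formula (coefficients and centring constants transcribed
#' digit-for-digit), the printed band-midpoint correction grid, and the inner
#' tolerance limit with the Equivalent-Score cut-offs. Four scores (`t4`,
#' `e4`, `t4_t3`, `e4_e3`) carry `consistent = FALSE`: their as-published
#' exact formula does not regenerate their printed grid, so grid lookup (see
#' [published_correction()]) is the recommended correction mode for them.
#'
#' @return named list; each element has `label`, `direction`, `model`
#'   (a [correction_model()]), `grid` (a `norm_grid` holding the printed
#'   cells) and `bands` (a `tolerance_bands` with the published cut-offs).
#' @export
load_published_norms <- function() {
  if (!is.null(.norms_cache$norms)) return(.norms_cache$norms)
  path <- system.file("extdata", "published_norms.json",
                      package = "stroopnorm", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  norms <- lapply(names(raw$scores), function(key) {
    sc <- raw$scores[[key]]
    terms <- do.call(rbind, lapply(sc$terms, function(t) {
      gen_term(t$covariate, t$transform, t$coefficient, t$centring)
    }))
    model <- correction_model(key, terms, consistent = sc$consistent)
    ab <- parse_band_labels(unlist(sc$grid$age_bands))
    eb <- if (!is.null(sc$grid$education_bands))
      parse_band_labels(unlist(sc$grid$education_bands)) else NULL
    cells <- do.call(rbind, lapply(sc$grid$cells, unlist))
    dimnames(cells) <- list(if (is.null(eb)) "all" else eb$label, ab$label)
    grid <- structure(cells, class = c("norm_grid", class(cells)),
                      score_name = key, age_bands = ab, education_bands = eb)
    bands <- new_tolerance_bands(key, sc$direction,
                                 otl = sc$bands$es0, itl = sc$bands$itl,
                                 cutoff_es1 = sc$bands$es1,
                                 cutoff_es2 = sc$bands$es2,
                                 cutoff_es3 = sc$bands$es3, n = 452L)
    list(key = key, label = sc$label, direction = sc$direction,
         consistent = sc$consistent, model = model, grid = grid,
         bands = bands)
  })
  names(norms) <- names(raw$scores)
  .norms_cache$norms <- norms
  norms
}

#' Correction from the published norms
#'
#' @param score published score key (`"t1"` ... `"t4"`, `"e2"` ... `"e4"`,
#'   `"t3_t1"`, `"t4_t2"`, `"t4_t3"`, `"e4_e2"`, `"e4_e3"`).
#' @param age,education demographics in years.
#' @param mode `"formula"` evaluates the published exact formula;
#'   `"grid"` looks up the printed correction grid by nearest band;
#'   `"auto"` (default) uses the formula for the internally consistent scores
#'   and the grid for the four flagged ones.
#' @return correction value(s) in the units of the score.
#' @export
published_correction <- function(score, age, education = NULL,
                                 mode = c("auto", "formula", "grid")) {
  mode <- match.arg(mode)
  norms <- load_published_norms()
  if (!score %in% names(norms))
    stop("unknown published score '", score, "'; expected one of: ",
         paste(names(norms), collapse = ", "), call. = FALSE)
  entry <- norms[[score]]
  if (mode == "auto") mode <- if (entry$consistent) "formula" else "grid"
  if (mode == "formula") {
    needs_edu <- "education" %in% entry$model$terms$covariate
    if (needs_edu && is.null(education))
      stop("score '", score, "' requires education", call. = FALSE)
    correction_term(entry$model, age, if (is.null(education)) 10 else education)
  } else {
    grid_correction(entry$grid, age, education)
  }
}
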