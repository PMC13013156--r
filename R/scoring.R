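scwt_index_pairs <- list(
  t3_t1 = c("t3", "t1"), t4_t2 = c("t4", "t2"), t4_t3 = c("t4", "t3"),
  e3_e1 = c("e3", "e1"), e4_e2 = c("e4", "e2"), e4_e3 = c("e4", "e3")
)

#' Names of the twelve performance indices
#'
#' The four raw task scores per measure (times `t1`-`t4`, errors `e1`-`e4`,
#' with `e1` excluded from norming as it is constantly zero) plus the six
#' difference indices: reading interference (task 3 - task 1), naming
#' interference (task 4 - task 2) and resistance to interference
#' (task 4 - task 3), each for times and errors.
#'
#' @return character vector of normed score names.
#' @export
scwt_scores <- function() {
  c("t1", "t2", "t3", "t4", "e2", "e3", "e4",
    "t3_t1", "t4_t2", "t4_t3", "e3_e1", "e4_e2", "e4_e3")
}

validate_panel <- function(panel) {
  for (nm in scwt_time_scores) {
    x <- panel[[nm]]
    if (any(!is.na(x) & x <= 0))
      stop("completion time ", nm, " must be strictly positive", call. = FALSE)
  }
  for (nm in scwt_error_scores) {
    x <- panel[[nm]]
    if (any(!is.na(x) & (x < 0 | x > 50)))
      stop("error count ", nm, " must be within [0, 50]", call. = FALSE)
  }
  invisible(panel)
}

#' Compute the six derived difference indices
#'
#' Each index is the difference between the harder and the easier task
#' (`t3 - t1`, `t4 - t2`, `t4 - t3` and the corresponding error differences),
#' floored at zero: negative differences are recorded as zero. Missing raw
#' scores propagate to missing indices; values are kept as reals even for
#' error differences since demographic adjustment downstream is non-integer.
#'
#' @param panel data.frame with columns `t1, e1, ..., t4, e4` (one row per
#'   participant).
#' @return data.frame with columns `t3_t1, t4_t2, t4_t3, e3_e1, e4_e2, e4_e3`.
#' @export
compute_indices <- function(panel) {
  validate_panel(panel)
  out <- data.frame(row.names = seq_len(nrow(panel)))
  for (nm in names(scwt_index_pairs)) {
    pr <- scwt_index_pairs[[nm]]
    out[[nm]] <- pmax(0, panel[[pr[1]]] - panel[[pr[2]]])
  }
  rownames(out) <- NULL
  out
}

#' Append derived indices to a cohort table
#'
#' @param cohort data.frame as returned by [generate_cohort()].
#' @return the cohort with the six index columns added.
#' @export
add_indices <- function(cohort) {
  cbind(cohort, compute_indices(cohort))
}

cohort_columns <- c("id", "sex", "age", "education", "group",
                    "t1", "e1", "t2", "e2", "t3", "e3", "t4", "e4")

#' Read a cohort CSV
#'
#' Expects the declared dialect: header
#' `id,sex,age,education,group,t1,e1,t2,e2,t3,e3,t4,e4` (an optional trailing
#' `mmse` column is accepted); missing scores are empty fields. Rows with a
#' malformed or missing mandatory demographic field are rejected with a
#' diagnostic naming the row; partial score panels (e.g. patients assessed
#' only on tasks 3 and 4) are retained with explicit `NA` markers.
#'
#' @param path file path.
#' @return data.frame in the cohort layout.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  problems <- character()
  for (col in c("age", "education")) {
    v <- num(raw[[col]])
    bad <- which(is.na(v) | raw[[col]] == "")
    if (length(bad))
      problems <- c(problems, sprintf("row %d: invalid %s '%s'",
                                      bad, col, raw[[col]][bad]))
    raw[[col]] <- v
  }
  bad_group <- which(!raw$group %in% c("healthy", "AD", "MCI"))
  if (length(bad_group))
    problems <- c(problems, sprintf("row %d: unknown group '%s'",
                                    bad_group, raw$group[bad_group]))
  if (length(problems))
    stop("rejected records:\n", paste(problems, collapse = "\n"), call. = FALSE)
  for (col in c(scwt_time_scores, scwt_error_scores, intersect("mmse", names(raw))))
    raw[[col]] <- num(raw[[col]])
  validate_panel(raw)
  raw
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing values are written as empty fields.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  keep <- c(cohort_columns, intersect("mmse", names(cohort)))
  utils::write.csv(cohort[keep], path, row.names = FALSE, na = "")
  invisible(path)
}
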