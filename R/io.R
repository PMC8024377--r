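# Cohort tables: long-format per-visit records with typed validation.

cohort_key_cols <- c("subject_id", "dataset_id", "arm", "visit_time",
                     "age", "sex", "tiv")

#' Validate and classify a cohort table
#'
#' Checks the long-format per-visit contract: required key columns, EDSS on
#' the half-point lattice in 0-10, non-decreasing visit times within
#' subject, no EDSS/relapse values for controls, and at least one visit per
#' subject. Offending rows are named in the error.
#'
#' @param x a data.frame.
#' @return `x` with class `c("cohort_table", "data.frame")`.
#' @export
as_cohort_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(cohort_key_cols, names(x))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0) stop("empty cohort table")
  if ("edss" %in% names(x)) {
    bad <- which(!is.na(x$edss) &
                   (x$edss < 0 | x$edss > 10 | x$edss * 2 != round(x$edss * 2)))
    if (length(bad))
      stop("EDSS off the 0-10 half-point lattice in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    ctrl <- x$arm == "control"
    if (any(ctrl & !is.na(x$edss)))
      stop("controls must not carry EDSS values (rows ",
           paste(utils::head(which(ctrl & !is.na(x$edss)), 10), collapse = ", "), ")")
  }
  ord <- order(x$subject_id, x$visit_time)
  vt <- x$visit_time[ord]
  sid <- x$subject_id[ord]
  nonmono <- which(diff(vt) < 0 & sid[-1] == sid[-length(sid)])
  if (length(nonmono))
    stop("visit_time decreases within subject for: ",
         paste(utils::head(unique(sid[nonmono + 1]), 5), collapse = ", "))
  class(x) <- unique(c("cohort_table", class(x)))
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", length(unique(x$subject_id)), " subjects, ",
      nrow(x), " visits, ", length(unique(x$dataset_id)), " dataset(s)\n",
      sep = "")
  NextMethod()
}

#' Write a cohort table to CSV
#'
#' UTF-8 CSV, header row, one row per visit, missing values empty. Numeric
#' columns are written with 17 significant digits so a write/read
#' round-trip reproduces every double exactly.
#'
#' @param x a cohort table (or any data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      s <- sprintf("%.17g", y[[j]])
      s[is.na(y[[j]])] <- NA_character_
      y[[j]] <- s
    }
  }
  utils::write.csv(y, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Parses and validates a cohort CSV written by [write_cohort()] (or any
#' file honouring the same contract). Validation failures name the
#' offending rows; an empty file raises a clear error.
#'
#' @param path CSV file.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty cohort file: ", path)
  x <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("cohort file is empty or unreadable: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (nrow(x) == 0) stop("cohort file has a header but no rows: ", path)
  num_cols <- setdiff(names(x), c("subject_id", "dataset_id", "arm"))
  for (j in num_cols) {
    if (is.character(x[[j]])) {
      v <- suppressWarnings(as.numeric(x[[j]]))
      bad <- which(is.na(v) & !is.na(x[[j]]) & nzchar(x[[j]]))
      if (length(bad))
        stop("malformed numeric in column '", j, "', rows: ",
             paste(utils::head(bad, 10), collapse = ", "))
      x[[j]] <- v
    }
  }
  as_cohort_table(x)
}

#' Baseline visits of a cohort
#'
#' The earliest visit per subject (ties broken by row order).
#'
#' @param x a cohort table.
#' @return A `cohort_table` with one row per subject.
#' @export
baseline_visits <- function(x) {
  ord <- order(x$subject_id, x$visit_time)
  y <- x[ord, ]
  y <- y[!duplicated(y$subject_id), ]
  rownames(y) <- NULL
  y
}
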