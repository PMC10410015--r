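#' Cohort tables
#'
#' A cohort table is a plain `data.frame` with one row per individual and the
#' reserved columns `id` (unique identifier), `age` (integer years, 12-79),
#' `sex` (factor, female/male), `cycle` (year of inclusion) and, when survival
#' information is present, `followup_time` (years) and `death` (0/1). Every
#' other numeric column is treated as a continuous biomarker. Missing biomarker
#' values are allowed and encoded as `NA`.
#'
#' `as_cohort()` validates a data frame and records which columns are
#' biomarkers; `biomarker_names()` and `biomarker_matrix()` retrieve them.
#'
#' @param x A data frame with at least `id` and `age` columns.
#' @param biomarkers Character vector naming the biomarker columns. Defaults to
#'   every non-reserved column of `x`.
#' @return `as_cohort()` returns `x` with class `cohort_table` and a
#'   `biomarkers` attribute; `biomarker_matrix()` returns a numeric matrix with
#'   individuals as rows (rownames = ids).
#' @examples
#' cohort <- as_cohort(data.frame(id = 1:4, age = c(20, 30, 40, 50),
#'                                glucose = c(4.8, 5.1, 5.5, 6.0)))
#' biomarker_names(cohort)
#' @export
as_cohort <- function(x, biomarkers = NULL) {
  if (!is.data.frame(x)) stopf("a cohort must be a data frame")
  if (nrow(x) == 0L) stopf("cohort is empty")
  for (col in c("id", "age")) {
    if (!col %in% names(x)) stopf("cohort lacks required column '%s'", col)
  }
  if (anyDuplicated(x$id)) stopf("cohort ids must be unique")
  if (!is.numeric(x$age) || anyNA(x$age)) stopf("`age` must be numeric without missing values")
  biomarkers <- biomarkers %||% setdiff(names(x), .reserved_cols)
  if (length(biomarkers)) {
    missing_cols <- setdiff(biomarkers, names(x))
    if (length(missing_cols)) stopf("biomarker column(s) not found: %s",
                                    paste(missing_cols, collapse = ", "))
    non_num <- biomarkers[!vapply(x[biomarkers], is.numeric, logical(1))]
    if (length(non_num)) stopf("biomarker column(s) not numeric: %s",
                               paste(non_num, collapse = ", "))
  }
  attr(x, "biomarkers") <- biomarkers
  class(x) <- unique(c("cohort_table", class(x)))
  x
}

#' @rdname as_cohort
#' @export
biomarker_names <- function(x) {
  attr(x, "biomarkers") %||% setdiff(names(x), .reserved_cols)
}

#' @rdname as_cohort
#' @export
biomarker_matrix <- function(x, biomarkers = NULL) {
  biomarkers <- biomarkers %||% biomarker_names(x)
  m <- as.matrix(as.data.frame(x)[biomarkers])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x$id)
  m
}

# Re-wrap a data.frame as cohort after subsetting (attributes are dropped by
# `[.data.frame`), keeping only biomarkers still present.
rewrap_cohort <- function(x, template) {
  as_cohort(as.data.frame(x), intersect(biomarker_names(template), names(x)))
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as CSV (always available) or Parquet (when the
#' `arrow` package is installed). The format is chosen from the file
#' extension.
#'
#' @param cohort A cohort table.
#' @param path File path ending in `.csv` or `.parquet`.
#' @param biomarkers Passed to [as_cohort()] when reading.
#' @return `read_cohort()` returns a cohort table; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(cohort)
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stopf("writing parquet requires the 'arrow' package")
    }
    arrow::write_parquet(df, path)
  } else stopf("unsupported cohort format '%s'", ext)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, biomarkers = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stopf("reading parquet requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else stopf("unsupported cohort format '%s'", ext)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)
  as_cohort(df, biomarkers)
}
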