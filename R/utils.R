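#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom generics tidy glance
#' @importFrom Rcpp evalCpp
#' @useDynLib panelomics, .registration = TRUE
#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head
NULL

# Column names every cohort tibble reserves for metadata; everything else is a
# feature column.
.meta_cols <- c("sample_id", "subtype", "partition")

#' Feature column names of a cohort tibble
#'
#' A cohort tibble holds one sample per row: a `sample_id` column, a `subtype`
#' label column, optionally a `partition` column, and one numeric column per
#' feature.
#'
#' @param data A cohort tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(data) {
  setdiff(names(data), .meta_cols)
}

#' Extract the sample-by-feature value matrix from a cohort tibble
#'
#' @param data A cohort tibble.
#' @param features Optional character vector restricting the columns.
#' @return A numeric matrix with `sample_id` rownames and feature colnames.
#' @export
cohort_matrix <- function(data, features = NULL) {
  feats <- features %||% feature_names(data)
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) {
    abort(paste0("features absent from data: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(data[feats])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_cohort <- function(data) {
  if (!is.data.frame(data)) abort("expected a data frame")
  if (!all(c("sample_id", "subtype") %in% names(data))) {
    abort("cohort data must have `sample_id` and `subtype` columns")
  }
  if (anyDuplicated(data$sample_id)) abort("sample_id values must be unique")
  invisible(data)
}

# Derive a stage-specific 32-bit seed from one master seed, by hashing the
# stage name. Keeps all per-stage streams independent but reproducible.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% .Machine$integer.max)
}
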