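# Reading expression tables, redundancy removal, stratified hold-out
# splitting, and the two normalisations (z-score and min-max) with parameters
# estimated on training data only.

#' Read a delimited expression table into a cohort tibble
#'
#' Accepts samples-in-rows tables (with an embedded `subtype` column or a
#' sidecar label file) and features-in-rows tables (TCGA orientation: first
#' column feature IDs, one column per sample; labels from `label_source`, which
#' defaults to `<path>.labels.tsv`).
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples"` or `"features"` — which entities occupy rows.
#' @param label_source Path to a two-column (`sample_id`, `subtype`) label TSV.
#'   Ignored when labels are embedded.
#' @return A cohort tibble (features as columns).
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples", "features"),
                                  label_source = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (orientation == "samples") {
    if (!"sample_id" %in% names(raw)) abort("samples-in-rows table needs a sample_id column")
    if (!"subtype" %in% names(raw)) {
      labels <- .read_labels(label_source, path)
      raw <- dplyr::left_join(raw, labels, by = "sample_id")
    }
    feats <- setdiff(names(raw), c("sample_id", "subtype"))
    values <- .parse_numeric(raw[feats], raw$sample_id)
    data <- dplyr::bind_cols(raw[c("sample_id", "subtype")], values)
  } else {
    feature_id <- raw[[1]]
    sample_ids <- names(raw)[-1]
    m <- .parse_numeric(raw[-1], feature_id)
    m <- t(as.matrix(m))
    colnames(m) <- feature_id
    labels <- .read_labels(label_source, path)
    data <- dplyr::left_join(
      dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                       tibble::as_tibble(m)),
      labels, by = "sample_id"
    )
    data <- data[c("sample_id", "subtype", feature_id)]
  }
  if (anyNA(data$subtype)) {
    abort(paste0("label missing for sample(s): ",
                 paste(head(data$sample_id[is.na(data$subtype)], 5), collapse = ", ")))
  }
  .assert_cohort(tibble::as_tibble(data))
}

.read_labels <- function(label_source, path) {
  src <- label_source %||% paste0(path, ".labels.tsv")
  if (!file.exists(src)) abort(paste0("label file not found: ", src))
  readr::read_tsv(src, col_types = "cc", progress = FALSE)
}

# Parse a character data frame to numeric, naming the offending row/column on
# failure.
.parse_numeric <- function(df, row_ids) {
  out <- lapply(names(df), function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | !is.finite(x))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric or non-finite value at row '%s', column '%s'",
                    row_ids[bad[1]], col))
    }
    x
  })
  names(out) <- names(df)
  tibble::as_tibble(out)
}

#' Remove redundant features
#'
#' Drops zero-variance features and exact duplicate columns (keeping the first
#' by feature-ID order). The removed IDs are attached as the sorted
#' `removed_features` attribute and returned by [removed_features()].
#'
#' @param data A cohort tibble.
#' @return The cohort tibble without the redundant columns.
#' @export
remove_redundant_features <- function(data) {
  .assert_cohort(data)
  m <- cohort_matrix(data)
  if (ncol(m) == 0) abort("cohort has no feature columns")
  variances <- matrixStats_colVars(m)
  constant <- colnames(m)[variances == 0]
  keep <- setdiff(colnames(m), constant)
  # exact duplicates among the survivors; first feature (by ID order) kept
  dup <- character(0)
  if (length(keep) > 1) {
    keys <- vapply(keep, function(f) paste(m[, f], collapse = "\r"), character(1))
    dup <- keep[duplicated(keys)]
    keep <- setdiff(keep, dup)
  }
  if (length(keep) == 0) abort("all features are redundant; nothing left")
  removed <- sort(c(constant, dup))
  out <- data[c(intersect(.meta_cols, names(data)), keep)]
  for (a in c("provenance", "sim_config")) attr(out, a) <- attr(data, a)
  attr(out, "removed_features") <- removed
  out
}

# colVars without an extra dependency.
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

#' Removed feature IDs recorded by [remove_redundant_features()]
#' @param data A cohort tibble.
#' @return Sorted character vector (empty if nothing was removed).
#' @export
removed_features <- function(data) {
  attr(data, "removed_features") %||% character(0)
}

#' Stratified hold-out split
#'
#' Adds a `partition` column (`train` / `validation` / `test`) by drawing a
#' per-class random split at the given fractions. Per-class counts use
#' largest-remainder rounding so realised fractions are within one sample of
#' the targets; every partition receives at least one sample per class.
#'
#' @param data A cohort tibble.
#' @param fractions Numeric vector of length 3 summing to 1 (train,
#'   validation, test).
#' @param seed Integer seed controlling membership.
#' @return The cohort tibble with a `partition` column.
#' @export
split_holdout <- function(data, fractions = c(train = 0.70, validation = 0.10, test = 0.20),
                          seed = 1L) {
  .assert_cohort(data)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be three numbers summing to 1")
  }
  names(fractions) <- c("train", "validation", "test")
  sizes <- table(data$subtype)
  if (any(sizes < 3)) {
    abort(paste0("every class needs >= 3 samples to populate all partitions; too small: ",
                 paste(names(sizes)[sizes < 3], collapse = ", ")))
  }
  partition <- rep(NA_character_, nrow(data))
  with_seed(seed, {
    for (cls in sort(names(sizes))) {
      idx <- which(data$subtype == cls)
      counts <- largest_remainder(length(idx), fractions)
      shuffled <- sample(idx)
      partition[shuffled] <- rep(names(fractions), counts)
    }
  })
  out <- dplyr::mutate(data, partition = partition,
                       .after = "subtype")
  for (a in c("provenance", "sim_config")) attr(out, a) <- attr(data, a)
  attr(out, "split_seed") <- as.integer(seed)
  out
}

# Integer apportionment: floor each target, then hand out the remaining
# samples by descending fractional remainder (ties by position). Every
# partition is guaranteed at least one sample.
largest_remainder <- function(n, fractions) {
  target <- n * fractions
  counts <- floor(target)
  rem <- target - counts
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(-rem, seq_along(rem))
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  # guarantee non-empty partitions (classes have >= 3 samples)
  while (any(counts == 0)) {
    i <- which(counts == 0)[1]
    j <- which.max(counts)
    counts[i] <- counts[i] + 1
    counts[j] <- counts[j] - 1
  }
  as.integer(counts)
}

#' Estimate normalisation parameters on (training) data
#'
#' @param data A cohort tibble; when a `partition` column is present only the
#'   `train` rows are used, so validation/test values never leak into the
#'   parameters.
#' @param features Optional feature subset.
#' @return Tibble with `feature_id`, `mu`, `sigma` (population SD), `min`, `max`.
#' @export
normalization_params <- function(data, features = NULL) {
  .assert_cohort(data)
  use <- if ("partition" %in% names(data)) dplyr::filter(data, .data$partition == "train") else data
  m <- cohort_matrix(use, features)
  n <- nrow(m)
  mu <- colMeans(m)
  sigma <- sqrt(colSums((m - rep(mu, each = n))^2) / n)
  tibble::tibble(
    feature_id = colnames(m),
    mu = unname(mu),
    sigma = unname(sigma),
    min = unname(apply(m, 2, min)),
    max = unname(apply(m, 2, max))
  )
}

.apply_params <- function(data, params, fn) {
  .assert_cohort(data)
  feats <- params$feature_id
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) abort(paste0("params cover absent features: ",
                                        paste(head(missing, 5), collapse = ", ")))
  m <- cohort_matrix(data, feats)
  out <- fn(m, params)
  res <- dplyr::bind_cols(data[intersect(.meta_cols, names(data))],
                          tibble::as_tibble(out))
  for (a in c("provenance", "sim_config")) attr(res, a) <- attr(data, a)
  res
}

#' Z-score normalisation, y = (x - mu) / sigma
#'
#' Applies train-estimated parameters to every partition; on the training rows
#' each feature then has mean 0 and (population) SD 1.
#'
#' @param data A cohort tibble.
#' @param params Output of [normalization_params()].
#' @return The transformed cohort tibble (only the features in `params`).
#' @export
zscore_normalize <- function(data, params) {
  if (any(params$sigma == 0)) {
    abort(paste0("zero standard deviation for feature(s): ",
                 paste(head(params$feature_id[params$sigma == 0], 5), collapse = ", ")))
  }
  .apply_params(data, params, function(m, p) {
    sweep(sweep(m, 2, p$mu), 2, p$sigma, "/")
  })
}

#' Min-max normalisation, y = (x - min) / (max - min)
#'
#' Train values land in [0, 1]; out-of-range validation/test values are
#' clipped to [0, 1] so downstream discretisation stays well defined.
#'
#' @inheritParams zscore_normalize
#' @return The transformed cohort tibble (only the features in `params`).
#' @export
minmax_normalize <- function(data, params) {
  span <- params$max - params$min
  if (any(span == 0)) {
    abort(paste0("max equals min for feature(s): ",
                 paste(head(params$feature_id[span == 0], 5), collapse = ", ")))
  }
  .apply_params(data, params, function(m, p) {
    y <- sweep(sweep(m, 2, p$min), 2, p$max - p$min, "/")
    pmin(pmax(y, 0), 1)
  })
}
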