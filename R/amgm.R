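# AMGM dispersion filtering. The arithmetic-to-geometric-mean ratio of a
# feature is >= 1 with equality iff the feature is constant; the larger the
# ratio, the more dispersed (and, for expression data, the more informative)
# the feature. The modified variant exponentiates values first so zeros do not
# collapse the geometric mean:
#   classic:   R = mean(x) / prod(x)^(1/n)              (x > 0 required)
#   modified:  R = mean(exp(x)) / exp(mean(x))

#' AMGM dispersion score of a single feature vector
#'
#' @param values Numeric vector of one feature's values across samples.
#' @param variant `"modified"` (default; tolerates zeros) or `"classic"`.
#' @return A single number >= 1; exactly 1 for a constant vector.
#' @export
amgm_score <- function(values, variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  if (length(values) == 0 || !all(is.finite(values))) {
    abort("values must be a non-empty finite numeric vector")
  }
  if (variant == "classic") {
    if (any(values <= 0)) {
      abort("classic AMGM requires strictly positive values (geometric mean would vanish)")
    }
    # log-space geometric mean for numerical stability
    exp(log(mean(values)) - mean(log(values)))
  } else {
    mean(exp(values - mean(values)))
  }
}

#' AMGM scores for every feature of a cohort
#'
#' Scores are computed on the training partition when a `partition` column is
#' present, keeping selection blind to validation/test samples. Inputs are
#' expected on a bounded scale (min-max normalised) for the modified variant,
#' which exponentiates raw values.
#'
#' @param data A cohort tibble.
#' @param variant `"modified"` or `"classic"`.
#' @return Tibble with `feature_id`, `am` (arithmetic mean of the scored
#'   values), `gm` (geometric mean), `xbar` (plain mean of the raw values) and
#'   the ratio `r`, one row per feature, in feature order.
#' @export
amgm_scores <- function(data, variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  .assert_cohort(data)
  use <- if ("partition" %in% names(data)) dplyr::filter(data, .data$partition == "train") else data
  m <- cohort_matrix(use)
  xbar <- colMeans(m)
  if (variant == "classic") {
    if (any(m <= 0)) abort("classic AMGM requires strictly positive values")
    am <- xbar
    gm <- exp(colMeans(log(m)))
  } else {
    am <- colMeans(exp(m))
    gm <- exp(xbar)
  }
  tibble::tibble(
    feature_id = colnames(m),
    am = unname(am),
    gm = unname(gm),
    xbar = unname(xbar),
    r = unname(am / gm),
    variant = variant
  )
}

#' Keep the k features with the largest AMGM scores
#'
#' @param scores Tibble from [amgm_scores()].
#' @param k Number of features to keep, 1 <= k <= nrow(scores).
#' @return Tibble of the selected rows sorted by descending `r` (ties broken
#'   by feature-ID order).
#' @export
select_top_k <- function(scores, k) {
  if (k <= 0) abort("k must be positive")
  if (k > nrow(scores)) abort("k exceeds the number of features")
  ord <- order(-scores$r, scores$feature_id)
  out <- scores[ord[seq_len(k)], ]
  out$rank <- seq_len(k)
  out
}
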