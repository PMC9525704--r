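# Synthetic labeled expression cohorts with the statistical structure the
# discovery pipeline assumes: a minority of subtype-informative features,
# blocks of mutually redundant features, constant features, and planted
# item-co-occurrence patterns that rule mining should recover.

#' Configuration for a synthetic expression cohort
#'
#' Defaults mirror the mRNA arm of a three-subtype renal-carcinoma cohort:
#' 611/321/89 samples for the clear-cell, papillary and chromophobe subtypes.
#' Intensities are log-normal: `exp(base + class_offset + noise)`, so
#' `effect_size` is a mean shift on the log scale and `noise_sd` a log-scale
#' standard deviation.
#'
#' @param n_features Total number of feature columns.
#' @param class_sizes Named integer vector of samples per subtype.
#' @param frac_informative Fraction of features carrying subtype signal, in (0,1).
#' @param n_redundant_blocks Number of correlated blocks; each block is one
#'   informative template feature plus `block_size - 1` perturbed copies.
#' @param block_size Features per redundant block (template included), >= 2.
#' @param n_constant Number of identically-zero features.
#' @param effect_size Log-scale mean separation between adjacent subtypes.
#' @param noise_sd Log-scale standard deviation of the within-class noise.
#' @param planted_rules List of planted co-occurrence patterns; each element a
#'   list with `features` (character), `levels` (character, one of
#'   `"low"/"medium"/"high"` per feature) and `subtype`. Samples of that subtype
#'   are forced into the named discretisation levels with probability
#'   `rule_prob`.
#' @param rule_prob Per-sample probability that a planted rule is realised.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features,
                       class_sizes = c(KIRC = 611, KIRP = 321, KICH = 89),
                       frac_informative = 0.10,
                       n_redundant_blocks = 10,
                       block_size = 5,
                       n_constant = 10,
                       effect_size = 3,
                       noise_sd = 0.3,
                       planted_rules = list(),
                       rule_prob = 0.95,
                       seed = 1L) {
  if (length(class_sizes) == 0) abort("class_sizes must be non-empty")
  if (any(class_sizes < 1)) abort("class_sizes must all be >= 1")
  if (frac_informative <= 0 || frac_informative >= 1) {
    abort("frac_informative must lie in (0, 1)")
  }
  if (n_redundant_blocks > 0 && block_size < 2) abort("block_size must be >= 2")
  if (rule_prob < 0.9 || rule_prob > 1) abort("rule_prob must lie in [0.9, 1]")
  if (is.null(names(class_sizes))) {
    names(class_sizes) <- paste0("class", seq_along(class_sizes))
  }
  n_informative <- max(n_redundant_blocks, round(frac_informative * n_features))
  n_redundant <- n_redundant_blocks * max(block_size - 1, 0)
  if (n_informative + n_redundant + n_constant > n_features) {
    abort("n_features is smaller than the implied archetype counts")
  }
  structure(
    list(
      n_features = as.integer(n_features),
      class_sizes = stats::setNames(as.integer(class_sizes), names(class_sizes)),
      frac_informative = frac_informative,
      n_informative = as.integer(n_informative),
      n_redundant_blocks = as.integer(n_redundant_blocks),
      block_size = as.integer(block_size),
      n_constant = as.integer(n_constant),
      effect_size = effect_size,
      noise_sd = noise_sd,
      planted_rules = planted_rules,
      rule_prob = rule_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Run code under a temporary RNG state so generation never disturbs (or is
# disturbed by) the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# The subtype mean profiles: all permutations of the per-class log-offsets
# 0, effect, 2*effect, ... Each informative feature follows one profile; a
# redundant copy inherits its template's profile.
.class_offset_profiles <- function(n_classes, effect_size) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  lapply(perms(seq_len(n_classes) - 1L), function(p) p * effect_size)
}

# Signal groups collapse mirrored profiles (a profile and its negation carry
# the same subtype information, and the absolute-correlation redundancy of
# the graph stage treats them as one): group id = equivalence class of a
# profile under offset reversal.
.profile_groups <- function(profiles) {
  key <- vapply(profiles, paste, character(1), collapse = ",")
  mirror_key <- vapply(profiles, function(p) paste(max(p) - p, collapse = ","),
                       character(1))
  canonical <- pmin(match(key, key), match(mirror_key, key))
  as.integer(factor(canonical, levels = unique(canonical)))
}

#' Generate a synthetic labeled expression cohort
#'
#' Produces a tibble with one sample per row: `sample_id`, `subtype`, and one
#' non-negative numeric column per feature. Per-feature archetype tags
#' (informative / redundant / constant / noise) and signal-group membership are
#' attached as a provenance table (see [cohort_provenance()]).
#'
#' @param config A [sim_config()].
#' @return A cohort tibble with `provenance` and `sim_config` attributes.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$class_sizes)
  p <- config$n_features
  labels <- rep(names(config$class_sizes), config$class_sizes)
  class_idx <- rep(seq_along(config$class_sizes), config$class_sizes)

  n_inf <- config$n_informative
  n_red <- config$n_redundant_blocks * (config$block_size - 1L)
  n_con <- config$n_constant
  n_noise <- p - n_inf - n_red - n_con

  archetype <- rep(
    c("informative", "redundant", "constant", "noise"),
    c(n_inf, n_red, n_con, n_noise)
  )
  feature_id <- sprintf("f%05d", seq_len(p))

  profiles <- .class_offset_profiles(length(config$class_sizes), config$effect_size)
  group_of_profile <- .profile_groups(profiles)
  profile <- rep(NA_integer_, p)
  profile[seq_len(n_inf)] <- ((seq_len(n_inf) - 1L) %% length(profiles)) + 1L

  with_seed(config$seed, {
    values <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, feature_id))
    base <- runif(p, min = 1, max = 3)
    for (j in seq_len(n_inf)) {
      off <- profiles[[profile[j]]][class_idx]
      values[, j] <- exp(base[j] + off + rnorm(n, sd = config$noise_sd))
    }
    if (n_red > 0) {
      # perturbed copies of the first n_redundant_blocks informative templates
      k <- n_inf
      for (b in seq_len(config$n_redundant_blocks)) {
        for (m in seq_len(config$block_size - 1L)) {
          k <- k + 1L
          values[, k] <- values[, b] * exp(rnorm(n, sd = 0.02))
          profile[k] <- profile[b]
        }
      }
    }
    if (n_noise > 0) {
      jj <- (n_inf + n_red + n_con + 1L):p
      for (j in jj) values[, j] <- exp(base[j] + rnorm(n, sd = config$noise_sd))
    }
    values <- .plant_rules(values, labels, config)
    values
  }) -> values

  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)), subtype = labels),
    tibble::as_tibble(values)
  )
  attr(data, "provenance") <- tibble::tibble(
    feature_id = feature_id, archetype = archetype, profile = profile,
    group = ifelse(is.na(profile), NA_integer_, group_of_profile[profile])
  )
  attr(data, "sim_config") <- config
  data
}

# Force samples of the named subtype into the named discretisation level's
# value range (relative to the feature's own min-max span) with probability
# rule_prob. Values stay inside the observed span so bin membership after
# later min-max scaling is preserved.
.plant_rules <- function(values, labels, config) {
  level_center <- c(low = 1 / 6, medium = 1 / 2, high = 5 / 6)
  for (rule in config$planted_rules) {
    feats <- rule$features
    levs <- rule$levels
    if (length(levs) == 1) levs <- rep(levs, length(feats))
    if (!all(feats %in% colnames(values))) {
      abort("planted rule names a feature that does not exist")
    }
    if (!all(levs %in% names(level_center))) {
      abort("planted rule levels must be low/medium/high")
    }
    rows <- which(labels == rule$subtype)
    if (length(rows) == 0) abort("planted rule names an unknown subtype")
    hit <- rows[runif(length(rows)) < config$rule_prob]
    for (i in seq_along(feats)) {
      col <- values[, feats[i]]
      lo <- min(col); hi <- max(col)
      q <- level_center[[levs[i]]] + runif(length(hit), -1, 1) / 12
      values[hit, feats[i]] <- lo + q * (hi - lo)
    }
  }
  values
}

#' Per-feature provenance of a synthetic cohort
#'
#' @param data A cohort tibble produced by [generate_cohort()].
#' @return Tibble with `feature_id`, `archetype`, mean-`profile` index and
#'   sign-collapsed signal `group`.
#' @export
cohort_provenance <- function(data) {
  prov <- attr(data, "provenance")
  if (is.null(prov)) abort("data carries no provenance (not a generated cohort?)")
  prov
}

#' Write a cohort to a TSV file
#'
#' With `orientation = "samples"` the table has one sample per row and an
#' embedded `subtype` column. With `orientation = "features"` the matrix is
#' transposed (features in rows, one column per sample) and the labels go to a
#' sidecar file `<path>.labels.tsv` with columns `sample_id`, `subtype`.
#'
#' @param data A cohort tibble.
#' @param path Output TSV path.
#' @param orientation `"samples"` (default) or `"features"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  .assert_cohort(data)
  if (nrow(data) == 0) abort("refusing to write a cohort with 0 samples")
  if (orientation == "samples") {
    readr::write_tsv(data[c("sample_id", "subtype", feature_names(data))], path)
  } else {
    m <- cohort_matrix(data)
    wide <- dplyr::bind_cols(
      tibble::tibble(feature_id = colnames(m)),
      tibble::as_tibble(t(m), .name_repair = "minimal")
    )
    readr::write_tsv(wide, path)
    readr::write_tsv(data[c("sample_id", "subtype")], paste0(path, ".labels.tsv"))
  }
  invisible(path)
}
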