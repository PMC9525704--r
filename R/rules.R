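# From a min-max-scaled candidate panel to class-consequent association
# rules: equal-width low/medium/high discretisation, class-anchored rule
# selection, repeat-count ranking of molecules, and anchor-feature dependency
# networks.

#' Class item label for a subtype
#' @param subtype Subtype name.
#' @return The item string used in transactions (e.g. `"class=KIRC"`).
#' @export
class_item <- function(subtype) paste0("class=", subtype)

#' Discretise a min-max-scaled panel into a transaction database
#'
#' Values must lie in [0, 1]. Equal-width bins map [0, 1/3) to `low`,
#' [1/3, 2/3) to `medium` and [2/3, 1] to `high` (upper bins left-closed, so a
#' value of exactly 1/3 is `medium`). Every transaction holds one level item
#' per panel feature plus exactly one class item.
#'
#' @param data Cohort tibble with `subtype` labels and values in [0, 1].
#' @param features Panel feature IDs (default: all feature columns).
#' @param breaks Two increasing bin edges inside (0, 1).
#' @return A [transaction_db()].
#' @export
discretize_panel <- function(data, features = feature_names(data),
                             breaks = c(1 / 3, 2 / 3)) {
  .assert_cohort(data)
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  m <- cohort_matrix(data, features)
  if (any(m < 0 | m > 1)) abort("panel values must lie in [0, 1]; min-max scale first")
  level <- matrix(c("low", "medium", "high")[findInterval(m, breaks) + 1L],
                  nrow = nrow(m))
  transactions <- lapply(seq_len(nrow(m)), function(i) {
    c(paste0(features, "=", level[i, ]), class_item(data$subtype[i]))
  })
  transaction_db(transactions)
}

#' Keep rules whose consequent is exactly one subtype's class item
#'
#' An empty result is legitimate: a subtype whose prevalence is below the
#' mining min-support can never appear in a frequent itemset, so it yields no
#' class rules at all (the chromophobe-minority situation).
#'
#' @param rules Rule tibble from [generate_rules()].
#' @param subtype Subtype name.
#' @return The matching rules.
#' @export
filter_class_rules <- function(rules, subtype) {
  target <- class_item(subtype)
  keep <- vapply(rules$consequent, function(c_) identical(c_, target), logical(1))
  rules[keep, ]
}

.item_feature <- function(items) sub("=(low|medium|high)$", "", items)

#' Repeat-count table of a subtype's class rules
#'
#' Counts, for every panel feature, the number of selected class-consequent
#' rules whose antecedent contains any level item of that feature (all levels
#' of a molecule pool into one count).
#'
#' @param class_rules Rules filtered to one subtype ([filter_class_rules()]).
#' @return Tibble `feature_id`, `repeat_count`, sorted by descending count
#'   (ties by feature ID).
#' @export
repeat_counts <- function(class_rules) {
  if (nrow(class_rules) == 0) {
    return(tibble::tibble(feature_id = character(0), repeat_count = integer(0)))
  }
  # a frequent antecedent can hold at most one level item per feature (two
  # levels of one feature never co-occur in a transaction), so no per-rule
  # deduplication is needed
  feats <- .item_feature(unlist(class_rules$antecedent, use.names = FALSE))
  tab <- table(feats)
  out <- tibble::tibble(feature_id = names(tab), repeat_count = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$repeat_count), .data$feature_id)
}

#' Dependency network around an anchor feature
#'
#' Among the class rules whose antecedent contains the anchor feature (at any
#' level) and which pass the support/lift cuts, counts how often each
#' co-feature shares an antecedent with the anchor.
#'
#' @param class_rules Rules filtered to one subtype.
#' @param anchor_feature Feature ID anchoring the network.
#' @param min_support_cut,min_lift_cut Strict lower cuts applied to the rules
#'   before counting (0 keeps everything).
#' @return Tibble of edges `anchor`, `feature_id`, `n_rules`, ranked by
#'   descending count; empty (with a warning) when the anchor appears in no
#'   rule.
#' @export
dependency_network <- function(class_rules, anchor_feature,
                               min_support_cut = 0, min_lift_cut = 0) {
  empty <- tibble::tibble(anchor = character(0), feature_id = character(0),
                          n_rules = integer(0))
  if (nrow(class_rules) == 0) {
    warn("no rules supplied; empty dependency network")
    return(empty)
  }
  rule_id <- rep(seq_len(nrow(class_rules)), lengths(class_rules$antecedent))
  feats <- .item_feature(unlist(class_rules$antecedent, use.names = FALSE))
  anchored <- unique(rule_id[feats == anchor_feature])
  if (length(anchored) == 0) {
    warn(paste0("anchor feature '", anchor_feature, "' appears in no rule"))
    return(empty)
  }
  pass <- anchored[class_rules$support[anchored] > min_support_cut &
                     class_rules$lift[anchored] > min_lift_cut]
  keep <- rule_id %in% pass & feats != anchor_feature
  co <- feats[keep]
  if (length(co) == 0) return(empty)
  tab <- table(co)
  out <- tibble::tibble(anchor = anchor_feature, feature_id = names(tab),
                        n_rules = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n_rules), .data$feature_id)
}
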