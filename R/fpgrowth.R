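# Frequent-itemset mining with FP-Growth. Transactions are item sets
# (feature-level items such as "f00017=high" plus one class item per sample).
# After items are reordered by descending global support (ties alphabetical)
# and infrequent items dropped, identical transaction prefixes merge into
# weighted branches (the FP-tree in branch form) and mining proceeds by the
# conditional-pattern-base recursion, implemented in C++ (src/fpgrowth.cpp).

#' Build a transaction database
#'
#' @param transactions List of character vectors, one item set per sample.
#' @return A `transaction_db` object (`transactions`, `n`, sorted `items`).
#' @export
transaction_db <- function(transactions) {
  if (length(transactions) == 0) abort("empty transaction database")
  transactions <- lapply(transactions, function(t) sort(unique(as.character(t))))
  structure(
    list(transactions = transactions, n = length(transactions),
         items = sort(unique(unlist(transactions)))),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("<transaction_db> %d transactions, %d distinct items\n",
              x$n, length(x$items)))
  invisible(x)
}

.itemset_key <- function(items) paste(sort(items), collapse = "\t")

#' Mine frequent itemsets with FP-Growth
#'
#' Returns all itemsets with support fraction >= `min_support` and at most
#' `max_length` items. With `focus_items`, only itemsets containing at least
#' one focus item are enumerated (the focus items are ranked last so their
#' conditional trees cover exactly those itemsets); this is how class-anchored
#' mining stays tractable on large panels without changing any reported
#' support.
#'
#' @param db A [transaction_db()].
#' @param min_support Minimum support fraction in (0, 1].
#' @param max_length Maximum itemset size, >= 1.
#' @param focus_items Optional character vector restricting output to itemsets
#'   containing at least one of these items.
#' @return Tibble with list-column `items` (sorted character vectors),
#'   `support_count` and `support`, plus a `key` column for joins.
#' @export
mine_frequent <- function(db, min_support, max_length = 4L, focus_items = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  if (min_support <= 0 || min_support > 1) abort("min_support must lie in (0, 1]")
  if (max_length < 1) abort("max_length must be >= 1")
  n <- db$n
  min_count <- min_support * n - 1e-9

  counts <- table(unlist(db$transactions))
  frequent_items <- names(counts)[counts >= min_count]
  empty <- tibble::tibble(items = list(), support_count = integer(0),
                          support = numeric(0), key = character(0))
  if (length(frequent_items) == 0) return(empty)

  # rank by descending support, ties alphabetical; focus items pushed last so
  # their conditional trees enumerate every itemset containing them
  ord <- frequent_items[order(-as.integer(counts[frequent_items]), frequent_items)]
  if (!is.null(focus_items)) {
    foc <- intersect(ord, focus_items)
    ord <- c(setdiff(ord, foc), foc)
  }
  rank_of <- stats::setNames(seq_along(ord), ord)
  trans <- lapply(db$transactions, function(t) {
    r <- rank_of[t]
    sort(unname(r[!is.na(r)]))
  })
  focus_ranks <- if (is.null(focus_items)) integer(0) else
    as.integer(rank_of[intersect(ord, focus_items)])

  res <- .fpg_mine(lapply(trans, as.integer), length(ord), min_count,
                   as.integer(max_length), focus_ranks)
  if (length(res$sizes) == 0) return(empty)
  decoded <- ord[res$flat]
  items <- lapply(unname(split(decoded, rep(seq_along(res$sizes), res$sizes))),
                  sort)
  tibble::tibble(
    items = items,
    support_count = as.integer(round(res$counts)),
    support = res$counts / n,
    key = vapply(items, paste, character(1), collapse = "\t")
  )
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset, all splits into non-empty disjoint antecedent
#' and consequent are scored with support (joint fraction), confidence
#' (support(A u C) / support(A)) and lift (confidence / P(C)); rules with lift
#' >= `min_lift` are kept. Subset supports missing from `itemsets` (possible
#' under focused mining) are counted directly from `db`.
#'
#' @param itemsets Output of [mine_frequent()].
#' @param db The [transaction_db()] the itemsets were mined from.
#' @param min_lift Minimum lift, > 0.
#' @param consequent_items Optional item vector; only consequents fully drawn
#'   from it are generated (e.g. the class items for class-consequent rules).
#' @return Tibble with list-columns `antecedent`, `consequent` and numeric
#'   `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(itemsets, db, min_lift = 1.1, consequent_items = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  if (min_lift <= 0) abort("min_lift must be positive")
  empty <- tibble::tibble(antecedent = list(), consequent = list(),
                          support = numeric(0), confidence = numeric(0),
                          lift = numeric(0))
  if (nrow(itemsets) == 0) return(empty)

  vocab <- db$items
  flat <- match(unlist(itemsets$items), vocab)
  sizes <- lengths(itemsets$items)
  tid_list <- lapply(vocab, function(it) {
    which(vapply(db$transactions, function(t) it %in% t, logical(1)))
  })
  consequent_ok <- if (is.null(consequent_items)) rep(TRUE, length(vocab)) else
    vocab %in% consequent_items

  res <- .fpg_rules(as.integer(flat), as.integer(sizes),
                    as.numeric(itemsets$support_count), tid_list,
                    db$n, min_lift, consequent_ok)
  if (length(res$a_sizes) == 0) return(empty)
  tibble::tibble(
    antecedent = unname(split(vocab[res$a_flat],
                              rep(seq_along(res$a_sizes), res$a_sizes))),
    consequent = unname(split(vocab[res$c_flat],
                              rep(seq_along(res$c_sizes), res$c_sizes))),
    support = res$support,
    confidence = res$confidence,
    lift = res$lift
  )
}
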