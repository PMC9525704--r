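test_that("discretisation uses left-closed equal-width bins and appends one class item", {
  m <- cbind(g1 = c(0, 0.5, 1, 1 / 3, 2 / 3, 0.32),
             g2 = c(0.1, 0.9, 0.4, 0, 1, 2 / 3 - 1e-9))
  coh <- manual_cohort(m, rep(c("A", "B"), 3), colnames(m))
  db <- discretize_panel(coh)
  expect_equal(db$n, 6)
  expect_true(all(lengths(db$transactions) == 3))   # 2 features + 1 class item
  lv <- function(i) sort(db$transactions[[i]])
  expect_equal(lv(1), c("class=A", "g1=low", "g2=low"))
  expect_equal(lv(2), c("class=B", "g1=medium", "g2=high"))
  expect_equal(lv(3), c("class=A", "g1=high", "g2=medium"))
  expect_equal(lv(4), c("class=B", "g1=medium", "g2=low"))   # exactly 1/3 -> medium
  expect_equal(lv(5), c("class=A", "g1=high", "g2=high"))    # exactly 2/3 -> high
  expect_error(discretize_panel(manual_cohort(cbind(g1 = c(-0.1, 0.5)), c("A", "B"))),
               "\\[0, 1\\]")
})

test_that("FP-Growth equals the brute-force Apriori oracle on a frozen example", {
  db <- transactions_db(c("a", "b"), c("a", "b"), c("a", "c"), "b")
  got <- mine_frequent(db, 0.5, 2)
  expect_setequal(got$key, c("a", "b", "a\tb"))
  expect_equal(got$support[match(c("a", "b", "a\tb"), got$key)],
               c(0.75, 0.75, 0.5))
  expect_equal(nrow(mine_frequent(db, 1, 2)), 0)
  expect_error(mine_frequent(db, 1.5, 2), "min_support")
  expect_error(transaction_db(list()), "empty")
})

test_that("FP-Growth matches Apriori on random databases, including focused mining", {
  set.seed(404)
  for (i in 1:25) {
    n_items <- sample(4:10, 1)
    pool <- letters[seq_len(n_items)]
    db <- transaction_db(lapply(seq_len(sample(5:30, 1)), function(j) {
      sample(pool, sample(seq_len(n_items), 1))
    }))
    ms <- runif(1, 0.05, 0.5)
    ml <- sample(1:4, 1)
    got <- mine_frequent(db, ms, ml)
    oracle <- apriori_enumerate(db, ms, ml)
    expect_setequal(got$key, oracle$key)
    expect_equal(got$support_count[order(got$key)],
                 oracle$count[order(oracle$key)], ignore_attr = TRUE)
    # anti-monotonicity: every subset of a frequent itemset is frequent
    for (k in got$key[lengths(got$items) > 1]) {
      its <- strsplit(k, "\t")[[1]]
      for (drop in seq_along(its)) {
        expect_true(paste(its[-drop], collapse = "\t") %in% got$key)
      }
    }
    # focused mining returns exactly the itemsets containing a focus item
    foc <- sample(pool, 2)
    focused <- mine_frequent(db, ms, ml, focus_items = foc)
    expect_setequal(
      focused$key,
      got$key[vapply(got$items, function(s) any(foc %in% s), logical(1))]
    )
  }
})

test_that("rule metrics satisfy the support/confidence/lift identities", {
  # 5 transactions: A u C in 2, A in 4, C in 2
  db <- transactions_db(c("a", "c"), c("a", "c"), c("a"), c("a"), c("b"))
  its <- mine_frequent(db, 0.2, 2)
  rules <- generate_rules(its, db, min_lift = 0.01)
  r <- rules[vapply(rules$antecedent, identical, logical(1), "a") &
               vapply(rules$consequent, identical, logical(1), "c"), ]
  expect_equal(r$support, 0.4)
  expect_equal(r$confidence, 0.5)
  expect_equal(r$lift, 1.25)

  # identities on every rule of random databases
  set.seed(77)
  for (i in 1:10) {
    pool <- letters[1:6]
    db <- transaction_db(lapply(1:20, function(j) sample(pool, sample(1:6, 1))))
    its <- mine_frequent(db, 0.15, 3)
    rules <- generate_rules(its, db, min_lift = 0.01)
    if (nrow(rules) == 0) next
    count_of <- function(s) sum(vapply(db$transactions, function(t) all(s %in% t),
                                       logical(1)))
    for (j in seq_len(nrow(rules))) {
      a <- rules$antecedent[[j]]; c_ <- rules$consequent[[j]]
      expect_length(intersect(a, c_), 0)
      expect_equal(rules$confidence[j], count_of(c(a, c_)) / count_of(a))
      expect_equal(rules$lift[j] * count_of(c_) / db$n, rules$confidence[j])
      expect_lte(rules$support[j], rules$confidence[j] + 1e-12)
    }
    # lift symmetry: the reversed rule carries the identical lift
    keys <- paste(vapply(rules$antecedent, paste, character(1), collapse = ","),
                  vapply(rules$consequent, paste, character(1), collapse = ","),
                  sep = "->")
    rev_keys <- paste(vapply(rules$consequent, paste, character(1), collapse = ","),
                      vapply(rules$antecedent, paste, character(1), collapse = ","),
                      sep = "->")
    m <- match(rev_keys, keys)
    expect_false(anyNA(m))
    expect_equal(rules$lift, rules$lift[m])
  }
})

test_that("independent itemsets are excluded at the published lift threshold", {
  # "a" and "c" both occur in every transaction: lift exactly 1
  db <- transactions_db(c("a", "c"), c("a", "c"), c("a", "c"))
  its <- mine_frequent(db, 0.5, 2)
  rules <- generate_rules(its, db, min_lift = 1.1)
  expect_equal(nrow(rules), 0)
  # at min_lift = 1 they pass
  expect_gt(nrow(generate_rules(its, db, min_lift = 1)), 0)
})

test_that("class-rule filtering keeps only exact single-class consequents", {
  db <- transactions_db(c("f1=high", "f2=high", "class=A"),
                        c("f1=high", "f2=high", "class=A"),
                        c("f1=low", "class=B"),
                        c("f1=high", "f2=high", "class=A"))
  its <- mine_frequent(db, 0.25, 4)
  rules <- generate_rules(its, db, min_lift = 1.01)
  cls_a <- filter_class_rules(rules, "A")
  expect_gt(nrow(cls_a), 0)
  expect_true(all(vapply(cls_a$consequent, identical, logical(1), "class=A")))
  # mixed consequents such as {class item, feature item} are excluded
  mixed <- vapply(rules$consequent,
                  function(c_) "class=A" %in% c_ && length(c_) > 1, logical(1))
  expect_false(any(vapply(cls_a$consequent, function(c_) length(c_) > 1, logical(1))))
  expect_equal(nrow(filter_class_rules(rules, "Z")), 0)
})

test_that("subtypes rarer than min-support generate no class rules (analytic suppression)", {
  # minority prevalence 0.088 < min_support 0.1, mirroring the chromophobe arm
  coh <- generate_cohort(sim_config(
    n_features = 60, class_sizes = c(KIRC = 62, KIRP = 31, KICH = 9),
    n_redundant_blocks = 2, block_size = 3, n_constant = 2, seed = 33
  ))
  expect_equal(unname(sum(coh$subtype == "KICH") / nrow(coh)), 9 / 102)
  coh <- remove_redundant_features(coh)
  sc <- minmax_normalize(coh, normalization_params(coh))
  feats <- feature_names(sc)[1:20]
  db <- discretize_panel(sc, feats)
  its <- mine_frequent(db, 0.1, 4,
                       focus_items = paste0("class=", c("KIRC", "KIRP", "KICH")))
  # no frequent itemset can contain the rare class item at all
  expect_false(any(vapply(its$items, function(s) "class=KICH" %in% s, logical(1))))
  rules <- generate_rules(its, db, 1.1,
                          consequent_items = paste0("class=", c("KIRC", "KIRP", "KICH")))
  expect_equal(nrow(filter_class_rules(rules, "KICH")), 0)
  # the abundant subtypes do generate class rules on the same cohort
  expect_gt(nrow(filter_class_rules(rules, "KIRC")), 0)
})

test_that("repeat counts pool a molecule's levels and sort deterministically", {
  rules <- tibble::tibble(
    antecedent = list(c("a=high", "b=low"), c("a=high", "c=high")),
    consequent = list("class=K", "class=K"),
    support = c(0.2, 0.2), confidence = c(0.9, 0.8), lift = c(1.5, 1.4)
  )
  rc <- repeat_counts(rules)
  expect_equal(rc$feature_id, c("a", "b", "c"))
  expect_equal(rc$repeat_count, c(2L, 1L, 1L))
  empty <- repeat_counts(rules[0, ])
  expect_equal(nrow(empty), 0)
  # different levels of one molecule pool into a single count
  rules2 <- tibble::tibble(
    antecedent = list("a=high", "a=low"),
    consequent = list("class=K", "class=K"),
    support = c(0.2, 0.2), confidence = c(0.9, 0.8), lift = c(1.5, 1.4)
  )
  expect_equal(repeat_counts(rules2)$repeat_count, 2L)
})

test_that("dependency networks count antecedent co-occurrences around the anchor", {
  rules <- tibble::tibble(
    antecedent = list(c("a=high", "b=low"), c("a=high", "b=low", "c=high"), "a=low"),
    consequent = list("class=K", "class=K", "class=K"),
    support = c(0.3, 0.25, 0.2), confidence = c(0.9, 0.85, 0.7),
    lift = c(1.5, 1.4, 1.2)
  )
  net <- dependency_network(rules, "a")
  expect_equal(net$feature_id, c("b", "c"))
  expect_equal(net$n_rules, c(2L, 1L))
  # an anchor that only appears alone has no edges
  lonely <- dependency_network(rules[3, ], "a")
  expect_equal(nrow(lonely), 0)
  expect_warning(dependency_network(rules, "zz"), "appears in no rule")
  # support cut prunes rules before counting
  cut <- dependency_network(rules, "a", min_support_cut = 0.27)
  expect_equal(cut$n_rules, 1L)
})
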