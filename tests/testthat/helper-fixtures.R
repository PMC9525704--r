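# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small three-class cohort with known structure.
tiny_cohort <- function(seed = 7, n_features = 120, class_sizes = c(A = 40, B = 25, C = 10),
                        ...) {
  generate_cohort(sim_config(
    n_features = n_features, class_sizes = class_sizes,
    n_redundant_blocks = 3, block_size = 4, n_constant = 4,
    effect_size = 3, noise_sd = 0.3, seed = seed, ...
  ))
}

# A cohort tibble built by hand from a matrix.
manual_cohort <- function(m, labels, feature_ids = NULL) {
  feature_ids <- feature_ids %||% colnames(m) %||% sprintf("g%02d", seq_len(ncol(m)))
  colnames(m) <- feature_ids
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(m))), subtype = labels),
    tibble::as_tibble(m)
  )
}

# Brute-force Apriori: enumerate every itemset up to max_length and count
# support by scanning transactions. The independent oracle for FP-Growth.
apriori_enumerate <- function(db, min_support, max_length) {
  n <- db$n
  keep <- list()
  for (len in seq_len(min(max_length, length(db$items)))) {
    for (s in utils::combn(db$items, len, simplify = FALSE)) {
      cnt <- sum(vapply(db$transactions, function(t) all(s %in% t), logical(1)))
      if (cnt / n >= min_support - 1e-9) {
        keep[[length(keep) + 1]] <- list(items = s, count = cnt)
      }
    }
  }
  tibble::tibble(
    key = vapply(keep, function(x) paste(sort(x$items), collapse = "\t"), character(1)),
    count = vapply(keep, function(x) x$count, numeric(1))
  )
}

# Exhaustive maximum independent set by subset enumeration (n <= ~16).
mis_enumerate <- function(a) {
  n <- nrow(a)
  best <- integer(0)
  for (mask in 0:(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(s) > length(best) && (length(s) < 2 || !any(a[s, s]))) best <- s
  }
  best
}

# Random symmetric logical adjacency matrix with edge probability p.
random_adjacency <- function(n, p) {
  a <- matrix(FALSE, n, n)
  if (n >= 2) {
    up <- upper.tri(a)
    a[up] <- stats::runif(sum(up)) < p
    a <- a | t(a)
  }
  a
}

# Wrap a logical matrix as the package's adjacency object.
as_adjacency <- function(a, gamma = 0.3, nodes = sprintf("n%02d", seq_len(nrow(a)))) {
  dimnames(a) <- list(nodes, nodes)
  structure(list(a = a, gamma = gamma, nodes = nodes), class = "adjacency_matrix")
}

# Hand-built feature_graph with a prescribed scaled weight matrix, for
# community/selection tests that need exact graph topology.
as_feature_graph <- function(w_hat, beta = 0.5,
                             nodes = sprintf("n%02d", seq_len(nrow(w_hat)))) {
  dimnames(w_hat) <- list(nodes, nodes)
  structure(
    list(nodes = nodes, w = w_hat, w_hat = w_hat,
         amgm = stats::setNames(rep(1.1, length(nodes)), nodes), beta = beta),
    class = "feature_graph"
  )
}

transactions_db <- function(...) transaction_db(list(...))
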