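test_that("weight matrix blends relevancy and redundancy with unit diagonal", {
  # orthogonal features: cosine 0, so W = beta * mean AMGM
  m <- cbind(g1 = c(1, 0, 0), g2 = c(0, 1, 0))
  coh <- manual_cohort(m, c("A", "B", "B"), colnames(m))
  scores <- tibble::tibble(feature_id = c("g1", "g2"), r = c(1.2, 1.4))
  g <- build_feature_graph(coh, scores, beta = 0.5)
  expect_equal(g$w["g1", "g2"], 0.5 * 1.3)
  expect_equal(diag(g$w), c(g1 = 1, g2 = 1))
  expect_equal(g$w, t(g$w))

  # identical features: |cos| = 1
  m2 <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
  coh2 <- manual_cohort(m2, c("A", "B", "B"), colnames(m2))
  g2 <- build_feature_graph(coh2, tibble::tibble(feature_id = c("g1", "g2"),
                                                 r = c(1.2, 1.2)), beta = 0.6)
  expect_equal(g2$w["g1", "g2"], 0.6 * 1.2 - 0.4)

  # anti-correlated features still count as redundant (absolute cosine)
  m3 <- cbind(g1 = c(1, -1), g2 = c(-2, 2))
  coh3 <- manual_cohort(m3, c("A", "B"), colnames(m3))
  g3 <- build_feature_graph(coh3, tibble::tibble(feature_id = c("g1", "g2"),
                                                 r = c(1.2, 1.2)), beta = 0.6)
  expect_equal(g3$w["g1", "g2"], 0.6 * 1.2 - 0.4)

  zero <- manual_cohort(cbind(g1 = c(0, 0), g2 = c(1, 2)), c("A", "B"))
  expect_error(build_feature_graph(zero, tibble::tibble(feature_id = c("g1", "g2"),
                                                        r = c(1, 1)), 0.5),
               "zero-norm")
  expect_error(build_feature_graph(coh, scores, beta = 1), "beta")
})

test_that("edge count includes all unordered pairs plus self-pairs", {
  expect_equal(edge_count(1), 1)
  expect_equal(edge_count(4), 10)
  coh <- remove_redundant_features(
    tiny_cohort(seed = 1, n_features = 30, class_sizes = c(A = 5, B = 5, C = 5)))
  sc_data <- minmax_normalize(coh, normalization_params(coh))
  g <- build_feature_graph(sc_data, amgm_scores(sc_data), 0.5)
  n <- length(feature_names(coh))
  expect_equal(edge_count(g), n * (n + 1) / 2)
  expect_equal(nrow(tidy(g)) + length(g$nodes), edge_count(g))
})

test_that("SoftMax scaling is the centred logistic and preserves order", {
  coh <- remove_redundant_features(
    tiny_cohort(seed = 17, n_features = 40, class_sizes = c(A = 10, B = 10, C = 10)))
  sc <- minmax_normalize(coh, normalization_params(coh))
  g <- softmax_scale(build_feature_graph(sc, amgm_scores(sc), 0.5))
  off <- upper.tri(g$w)
  mu <- mean(g$w[off]); s <- sd(g$w[off])
  # frozen logistic values at the centre and one sd above it
  expect_equal(unname(1 / (1 + exp(-(mu - mu) / s))), 0.5)
  expect_equal(max(abs(g$w_hat - 1 / (1 + exp(-(g$w - mu) / s)))), 0)
  w_at <- mu + s
  expect_equal(1 / (1 + exp(-(w_at - mu) / s)), 0.7310586, tolerance = 1e-6)
  expect_true(all(g$w_hat > 0 & g$w_hat < 1))
  expect_equal(order(g$w_hat[off]), order(g$w[off]))

  flat <- as_feature_graph(matrix(1, 3, 3))
  flat$w <- matrix(0.5, 3, 3)
  expect_error(softmax_scale(flat), "zero spread")
})

test_that("Louvain recovers planted communities and maximises modularity on a small graph", {
  # two 4-cliques with strong internal weight, faint cross weights
  w_hat <- matrix(0.01, 8, 8)
  w_hat[1:4, 1:4] <- 0.9
  w_hat[5:8, 5:8] <- 0.9
  diag(w_hat) <- 1
  g <- as_feature_graph(w_hat)
  part <- louvain_partition(g, seed = 1)
  expect_equal(attr(part, "n_communities"), 2)
  expect_length(unique(part$community[1:4]), 1)
  expect_length(unique(part$community[5:8]), 1)

  # oracle: enumerate every partition of the 8 nodes; none beats Louvain
  adj <- w_hat; diag(adj) <- 0
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  best <- -Inf
  part_of <- function(assignment) igraph::modularity(ig, assignment,
                                                     weights = igraph::E(ig)$weight)
  assignments <- list(1)
  for (i in 2:8) {
    assignments <- unlist(lapply(assignments, function(a) {
      lapply(seq_len(max(a) + 1), function(k) c(a, k))
    }), recursive = FALSE)
  }
  best <- max(vapply(assignments, part_of, numeric(1)))
  expect_equal(attr(part, "modularity"), best, tolerance = 1e-12)

  single <- as_feature_graph(matrix(1, 1, 1))
  expect_equal(nrow(louvain_partition(single, 1)), 1)
})

test_that("Louvain partition is deterministic under a seed and beats singletons", {
  coh <- remove_redundant_features(
    tiny_cohort(seed = 23, n_features = 60, class_sizes = c(A = 15, B = 15, C = 15)))
  sc <- minmax_normalize(coh, normalization_params(coh))
  g <- softmax_scale(build_feature_graph(sc, amgm_scores(sc), 0.5))
  p1 <- louvain_partition(g, seed = 42)
  p2 <- louvain_partition(g, seed = 42)
  expect_identical(p1$community, p2$community)
  adj <- g$w_hat; diag(adj) <- 0
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  singleton <- igraph::modularity(ig, seq_along(g$nodes), weights = igraph::E(ig)$weight)
  expect_gte(attr(p1, "modularity"), singleton)
})

test_that("adjacency thresholding is strict, symmetric and zero-diagonal", {
  w_hat <- matrix(c(1, 0.3, 0.31, 0.3, 1, 0.29, 0.31, 0.29, 1), 3, 3)
  g <- as_feature_graph(w_hat)
  a <- threshold_adjacency(g, 0.3)
  expect_false(a$a[1, 2])      # exactly gamma is not an edge
  expect_true(a$a[1, 3])
  expect_false(any(diag(a$a)))
  expect_equal(a$a, t(a$a))
  hi <- threshold_adjacency(g, 0.999)
  expect_false(any(hi$a))
  expect_error(threshold_adjacency(g, 1), "gamma")
})

test_that("candidate selection keeps per-community independence and panel provenance", {
  # community 1: path n01-n02-n03; community 2: edgeless pair
  a <- matrix(FALSE, 5, 5)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- TRUE
  adj <- as_adjacency(a)
  w_hat <- matrix(0.1, 5, 5); diag(w_hat) <- 1
  g <- as_feature_graph(w_hat, beta = 0.6, nodes = adj$nodes)
  part <- tibble::tibble(feature_id = adj$nodes, community = c(1L, 1L, 1L, 2L, 2L))
  class(part) <- c("community_partition", class(part))
  panel <- select_candidates(g, part, adj)
  expect_setequal(panel$feature_id, c("n01", "n03", "n04", "n05"))
  expect_equal(attr(panel, "beta"), 0.6)
  expect_equal(attr(panel, "gamma"), 0.3)
  for (cm in unique(panel$community)) {
    expect_true(is_independent_set(adj, panel$feature_id[panel$community == cm]))
  }
})

test_that("a fully redundant block above gamma contributes one member per community", {
  # four mutual near-duplicates whose pairwise scaled weight exceeds gamma
  w_hat <- matrix(0.8, 4, 4); diag(w_hat) <- 1
  g <- as_feature_graph(w_hat)
  adj <- threshold_adjacency(g, 0.3)
  part <- tibble::tibble(feature_id = g$nodes, community = rep(1L, 4))
  class(part) <- c("community_partition", class(part))
  panel <- select_candidates(g, part, adj)
  expect_equal(nrow(panel), 1)
  expect_equal(panel$feature_id, "n01")
})
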