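# The weighted feature graph. Every pair of features carries a weight
# blending relevancy (mean AMGM of the endpoints) against redundancy
# (absolute cosine similarity):
#   W_ij = beta * (AMGM_i + AMGM_j)/2 - (1 - beta) * |cos(F_i, F_j)|, W_ii = 1.
# Weights are squashed to (0, 1) with a SoftMax (logistic) scaling centred on
# the weight mean; the scaled matrix is the edge weight used by community
# detection and, thresholded at gamma, the adjacency fed to MIS selection.

#' Build the weighted feature graph
#'
#' @param data Cohort tibble on the scale used for selection (min-max
#'   normalised training data). When a `partition` column is present only
#'   `train` rows contribute to the cosine similarities.
#' @param scores AMGM score tibble covering every feature of `data` (see
#'   [amgm_scores()]); raw modified-AMGM values (>= 1) are used as relevancy.
#' @param beta Blend parameter in (0, 1): weight of relevancy vs redundancy.
#' @return A `feature_graph` object holding the node IDs, the raw weight
#'   matrix `W`, the AMGM values and `beta`.
#' @export
build_feature_graph <- function(data, scores, beta) {
  .assert_cohort(data)
  if (beta <= 0 || beta >= 1) abort("beta must lie in (0, 1)")
  use <- if ("partition" %in% names(data)) dplyr::filter(data, .data$partition == "train") else data
  m <- cohort_matrix(use)
  amgm <- scores$r[match(colnames(m), scores$feature_id)]
  if (anyNA(amgm)) abort("scores must cover every feature of the data")
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    abort(paste0("zero-norm feature vector(s), cosine undefined: ",
                 paste(head(colnames(m)[norms == 0], 5), collapse = ", ")))
  }
  cosine <- abs(crossprod(m) / tcrossprod(norms))
  relevancy <- outer(amgm, amgm, "+") / 2
  w <- beta * relevancy - (1 - beta) * cosine
  diag(w) <- 1
  dimnames(w) <- list(colnames(m), colnames(m))
  structure(
    list(nodes = colnames(m), w = w, w_hat = NULL, amgm = stats::setNames(amgm, colnames(m)),
         beta = beta),
    class = "feature_graph"
  )
}

#' Number of edges of a fully weighted feature graph
#'
#' All unordered node pairs plus the self-pairs carry a weight, so a graph on
#' n nodes has n(n+1)/2 edges.
#'
#' @param graph A `feature_graph`, or a node count.
#' @return Edge count as a double (exact for any practical n).
#' @export
edge_count <- function(graph) {
  n <- if (inherits(graph, "feature_graph")) length(graph$nodes) else as.numeric(graph)
  n * (n + 1) / 2
}

#' SoftMax-scale the graph weights into (0, 1)
#'
#' Applies the logistic map `1 / (1 + exp(-(W - mean) / sd))`, with mean and
#' standard deviation computed over the off-diagonal upper-triangle weights
#' (the diagonal is the fixed constant 1 and would bias the scaling). The map
#' is strictly increasing, so weight orderings are preserved.
#'
#' @param graph A `feature_graph` from [build_feature_graph()].
#' @return The graph with the scaled matrix filled in as `w_hat`.
#' @export
softmax_scale <- function(graph) {
  stopifnot(inherits(graph, "feature_graph"))
  w <- graph$w
  off <- w[upper.tri(w)]
  if (length(off) < 2 || sd(off) == 0) {
    abort("weights have zero spread; SoftMax scaling undefined")
  }
  mu <- mean(off)
  s <- sd(off)
  graph$w_hat <- 1 / (1 + exp(-(w - mu) / s))
  graph$w_stats <- c(mean = mu, sd = s)
  graph
}

#' Louvain community detection on the scaled feature graph
#'
#' Runs modularity-maximising Louvain clustering on the SoftMax-scaled weights
#' (self-loops dropped). Deterministic under a fixed seed.
#'
#' @param graph A `feature_graph` with `w_hat` (see [softmax_scale()]).
#' @param seed Integer seed fixing the node-visiting randomisation.
#' @return A `community_partition`: tibble of `feature_id`, `community`, with
#'   the partition `modularity` and community count as attributes.
#' @export
louvain_partition <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "feature_graph"))
  if (is.null(graph$w_hat)) abort("run softmax_scale() before louvain_partition()")
  if (length(graph$nodes) == 0) abort("empty graph")
  adj <- graph$w_hat
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  comm <- with_seed(seed, igraph::cluster_louvain(g))
  membership <- as.integer(igraph::membership(comm))
  out <- tibble::tibble(feature_id = graph$nodes, community = membership)
  attr(out, "modularity") <- igraph::modularity(g, membership,
                                                weights = igraph::E(g)$weight)
  attr(out, "n_communities") <- length(unique(membership))
  class(out) <- c("community_partition", class(out))
  out
}

#' Threshold the scaled weights into a Boolean adjacency matrix
#'
#' `a_ij = 1` iff `w_hat_ij > gamma` and `i != j` (strict inequality, zero
#' diagonal).
#'
#' @param graph A `feature_graph` with `w_hat`.
#' @param gamma Threshold in (0, 1).
#' @return An `adjacency_matrix` object (logical matrix plus `gamma`).
#' @export
threshold_adjacency <- function(graph, gamma) {
  stopifnot(inherits(graph, "feature_graph"))
  if (is.null(graph$w_hat)) abort("run softmax_scale() before threshold_adjacency()")
  if (gamma <= 0 || gamma >= 1) abort("gamma must lie in (0, 1)")
  a <- graph$w_hat > gamma
  diag(a) <- FALSE
  structure(list(a = a, gamma = gamma, nodes = graph$nodes),
            class = "adjacency_matrix")
}

#' Candidate panel: union of per-community maximum independent sets
#'
#' Within every Louvain community the induced adjacency subgraph is reduced to
#' a (maximum or approximately maximum) independent set — no two selected
#' features may be adjacent, i.e. carry a scaled weight above gamma — and the
#' panel is the union over communities.
#'
#' @param graph A `feature_graph` with `w_hat`.
#' @param partition A `community_partition` from [louvain_partition()].
#' @param adjacency An `adjacency_matrix` from [threshold_adjacency()].
#' @param exact_cap Communities with at most this many nodes are solved with
#'   exact branch-and-bound; larger ones with Boppana-Halldorsson clique
#'   removal.
#' @return A `candidate_panel` tibble: `feature_id`, `community`, `amgm`,
#'   sorted by community then feature ID, with `beta`/`gamma` attributes.
#' @export
select_candidates <- function(graph, partition, adjacency, exact_cap = 25L) {
  stopifnot(inherits(graph, "feature_graph"),
            inherits(partition, "community_partition"),
            inherits(adjacency, "adjacency_matrix"))
  if (!identical(sort(partition$feature_id), sort(graph$nodes)) ||
      !identical(adjacency$nodes, graph$nodes)) {
    abort("graph, partition and adjacency must cover the same node set")
  }
  picked <- lapply(split(partition$feature_id, partition$community), function(nodes) {
    mis_select(adjacency, nodes, exact_cap = exact_cap)
  })
  out <- tibble::tibble(
    feature_id = unlist(picked, use.names = FALSE),
    community = rep(as.integer(names(picked)), lengths(picked))
  )
  out$amgm <- unname(graph$amgm[out$feature_id])
  out <- dplyr::arrange(out, .data$community, .data$feature_id)
  attr(out, "beta") <- graph$beta
  attr(out, "gamma") <- adjacency$gamma
  class(out) <- c("candidate_panel", class(out))
  out
}

#' Feature graph as a weighted edge list
#'
#' @param x A `feature_graph` (scaled weights included when available).
#' @param ... Unused.
#' @return Tibble of upper-triangle edges: `from`, `to`, `w`, `w_hat`.
#' @method tidy feature_graph
#' @export
tidy.feature_graph <- function(x, ...) {
  ut <- upper.tri(x$w)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    w = x$w[ut],
    w_hat = if (is.null(x$w_hat)) NA_real_ else x$w_hat[ut]
  )
}

#' Graph-level summary
#' @param x A `feature_graph`.
#' @param ... Unused.
#' @method glance feature_graph
#' @export
glance.feature_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = edge_count(x),
    beta = x$beta,
    scaled = !is.null(x$w_hat)
  )
}
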