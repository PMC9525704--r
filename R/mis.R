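# Maximum-independent-set selection inside communities. Small communities are
# solved exactly by branch and bound; larger ones with the
# Boppana-Halldorsson clique-removal approximation (repeated Ramsey splits,
# removing the found clique each round and keeping the best independent set).
# All choices (pivot vertex, Ramsey vertex) are by lowest feature-ID, so the
# output is deterministic.

#' Independent feature set within one community
#'
#' Returns a set of community nodes no two of which are adjacent under the
#' thresholded adjacency matrix: the exact maximum independent set for
#' communities of at most `exact_cap` nodes, a clique-removal approximation
#' above that.
#'
#' @param adjacency An `adjacency_matrix` from [threshold_adjacency()].
#' @param community_nodes Character vector of feature IDs in the community.
#' @param exact_cap Size cap for the exact branch-and-bound solver.
#' @return Character vector of selected feature IDs, in feature-ID order.
#' @export
mis_select <- function(adjacency, community_nodes, exact_cap = 25L) {
  stopifnot(inherits(adjacency, "adjacency_matrix"))
  if (length(community_nodes) == 0) abort("community_nodes must be non-empty")
  missing <- setdiff(community_nodes, adjacency$nodes)
  if (length(missing) > 0) abort("community nodes absent from adjacency matrix")
  nodes <- sort(community_nodes)
  a <- adjacency$a[nodes, nodes, drop = FALSE]
  if (!any(a)) return(nodes)
  idx <- if (length(nodes) <= exact_cap) mis_exact(a) else mis_clique_removal(a)
  nodes[sort(idx)]
}

#' Exact maximum independent set by branch and bound
#'
#' Branches on the highest-degree vertex (include first, lowest index on
#' ties), pruning branches that cannot beat the incumbent. Intended for small
#' graphs (<= ~25 nodes); used as the exact reference the approximation is
#' validated against.
#'
#' @param a Square logical adjacency matrix (symmetric, FALSE diagonal).
#' @return Integer indices of a maximum independent set.
#' @export
mis_exact <- function(a) {
  n <- nrow(a)
  best <- integer(0)
  rec <- function(avail, current) {
    if (length(avail) + length(current) <= length(best)) return(invisible())
    if (length(avail) == 0) {
      if (length(current) > length(best)) best <<- current
      return(invisible())
    }
    deg <- rowSums(a[avail, avail, drop = FALSE])
    if (max(deg) == 0) { # remaining graph edgeless: take everything
      cand <- c(current, avail)
      if (length(cand) > length(best)) best <<- cand
      return(invisible())
    }
    v <- avail[which.max(deg)] # which.max takes the first (lowest index) on ties
    nb <- which(a[v, ])
    rec(setdiff(avail, c(v, nb)), c(current, v))
    rec(setdiff(avail, v), current)
  }
  rec(seq_len(n), integer(0))
  sort(best)
}

# One Ramsey split: returns list(is =, cl =) — an independent set and a
# clique, both on integer indices of `a`. Picks the lowest-index vertex,
# recurses into its neighbourhood (extending the clique) and its
# non-neighbourhood (extending the independent set), and keeps the larger of
# the two candidates on each side.
.ramsey <- function(a, avail) {
  if (length(avail) == 0) return(list(is = integer(0), cl = integer(0)))
  v <- avail[1]
  nb <- avail[a[v, avail]]
  nn <- avail[!a[v, avail] & avail != v]
  r1 <- .ramsey(a, nb)
  r2 <- .ramsey(a, nn)
  is1 <- r1$is
  is2 <- c(v, r2$is)
  cl1 <- c(v, r1$cl)
  cl2 <- r2$cl
  list(
    is = if (length(is2) >= length(is1)) is2 else is1,
    cl = if (length(cl1) >= length(cl2)) cl1 else cl2
  )
}

#' Boppana-Halldorsson clique-removal independent set
#'
#' Repeatedly applies the Ramsey split to the remaining graph, removes the
#' returned clique, and keeps the largest independent set seen across rounds.
#' The output is always an independent set of the input graph; on graphs with
#' small clique cover it approaches the optimum.
#'
#' @param a Square logical adjacency matrix (symmetric, FALSE diagonal).
#' @return Integer indices of an independent set.
#' @export
mis_clique_removal <- function(a) {
  avail <- seq_len(nrow(a))
  best <- integer(0)
  while (length(avail) > 0) {
    r <- .ramsey(a, avail)
    if (length(r$is) > length(best)) best <- r$is
    drop <- if (length(r$cl) > 0) r$cl else avail[1]
    avail <- setdiff(avail, drop)
  }
  sort(best)
}

#' Verify that a node set is independent under an adjacency matrix
#'
#' @param adjacency An `adjacency_matrix`.
#' @param nodes Character vector of feature IDs.
#' @return TRUE iff no two nodes are adjacent.
#' @export
is_independent_set <- function(adjacency, nodes) {
  stopifnot(inherits(adjacency, "adjacency_matrix"))
  if (length(nodes) < 2) return(TRUE)
  !any(adjacency$a[nodes, nodes])
}
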