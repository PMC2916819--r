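#' Interaction graph of a network
#'
#' The interaction graph has one vertex per node and a directed arc
#' `j -> i` wherever `w[j, i] != 0`, carrying the weight as an edge
#' attribute.  It is the structural object behind the boundary, centre and
#' component analyses.
#'
#' @param net A [tban()] network.
#' @return An [igraph][igraph::graph_from_adjacency_matrix] directed graph
#'   with a `weight` edge attribute and node names as vertex names.
#' @export
interaction_graph <- function(net) {
  stopifnot(is_tban(net))
  g <- igraph::graph_from_adjacency_matrix(
    (net$W != 0) * 1, mode = "directed", diag = TRUE
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- net$W[el]
  g
}

#' Boundary of the interaction graph
#'
#' The boundary is the set of source vertices: vertices with no incoming
#' arcs from other vertices than themselves.  A self-loop does not
#' disqualify a node from the boundary.  Boundary nodes model external
#' regulators (hormone flows, micro-RNAs, fields) whose state constrains
#' the network without being constrained by it.
#'
#' @param net A [tban()] network (or an interaction graph).
#' @return Character vector of boundary node names.
#' @examples
#' boundary_nodes(mendoza_original())   # emf1, lug, ufo, sup
#' boundary_nodes(toy_model())          # rga joins the boundary
#' @export
boundary_nodes <- function(net) {
  W <- if (is_tban(net)) net$W else
    as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  indeg <- colSums(W != 0) - (diag(W) != 0)
  rownames(W)[indeg == 0]
}

#' Eccentricity, radius, diameter and centre
#'
#' The eccentricity of a vertex is the maximum shortest-path length from
#' it to any other vertex, infinite when some vertex is unreachable.  The
#' radius is the minimum non-null finite eccentricity, the diameter the
#' maximum eccentricity, and the centre the set of vertices attaining the
#' radius.  All arcs count length 1 (paths are computed by breadth-first
#' search).  A graph with no finite non-null eccentricity has an undefined
#' radius: `graph_radius()` returns `NA` with a warning and the centre is
#' empty.
#'
#' @param net A [tban()] network.
#' @param v Optional vertex names; defaults to all.
#' @return `node_eccentricity()`: a tibble with `node` and `eccentricity`
#'   (possibly `Inf`).  `graph_radius()`, `graph_diameter()`: a single
#'   number.  `graph_centre()`: character vector of central vertices.
#' @export
node_eccentricity <- function(net, v = NULL) {
  g <- if (is_tban(net)) interaction_graph(net) else net
  D <- igraph::distances(g, mode = "out", weights = NA)
  out <- tibble::tibble(node = rownames(D),
                        eccentricity = unname(apply(D, 1, max)))
  if (!is.null(v)) out <- out[out$node %in% v, ]
  out
}

#' @rdname node_eccentricity
#' @export
graph_radius <- function(net) {
  ecc <- node_eccentricity(net)$eccentricity
  ok <- is.finite(ecc) & ecc > 0
  if (!any(ok)) {
    warning("no finite non-null eccentricity: radius undefined")
    return(NA_real_)
  }
  min(ecc[ok])
}

#' @rdname node_eccentricity
#' @export
graph_diameter <- function(net) max(node_eccentricity(net)$eccentricity)

#' @rdname node_eccentricity
#' @export
graph_centre <- function(net) {
  ecc <- node_eccentricity(net)
  r <- suppressWarnings(graph_radius(net))
  if (is.na(r)) return(character(0))
  ecc$node[ecc$eccentricity == r]
}

#' Strongly connected components and weight symmetry
#'
#' Decomposes the interaction graph into strongly connected components and
#' flags, for each, whether the restriction of the weight matrix to the
#' component is symmetric (`w[j, i] == w[i, j]` for all member pairs).
#' Symmetric components matter dynamically: a network whose dynamics is
#' governed by symmetric components has attractor periods at most 2 under
#' any block-sequential mode, and exactly 1 under sequential modes when the
#' component diagonals are non-negative.
#'
#' @param net A [tban()] network.
#' @return A tibble with one row per component: `component`, `nodes`
#'   (list-column of names), `size`, `symmetric`, `nonneg_diagonal`.
#' @export
network_sccs <- function(net) {
  g <- interaction_graph(net)
  comp <- igraph::components(g, mode = "strong")
  purrr::map_dfr(seq_len(comp$no), function(k) {
    members <- net$nodes[comp$membership == k]
    tibble::tibble(
      component = k,
      nodes = list(members),
      size = length(members),
      symmetric = is_symmetric_component(net, members),
      nonneg_diagonal = all(diag(net$W[members, members, drop = FALSE]) >= 0)
    )
  })
}

#' @rdname network_sccs
#' @param nodes Character vector of member node names.
#' @export
is_symmetric_component <- function(net, nodes) {
  sub <- net$W[nodes, nodes, drop = FALSE]
  all(sub == t(sub))
}

#' Number of block-sequential iteration modes
#'
#' The block-sequential modes of an `n`-node network are the ordered
#' partitions of its node set, counted by the ordered Bell (Fubini)
#' numbers via the recurrence
#' \deqn{T(0) = 1,\qquad T(n) = \sum_{k=1}^{n} \binom{n}{k}\, T(n-k).}
#' Computed in exact integer arithmetic; refused for `n > 17`, beyond
#' which the result no longer fits exactly in a double.
#'
#' @param n Number of nodes (non-negative).
#' @return The exact count as a double (integer-valued).
#' @examples
#' count_block_sequential_modes(3)   # 13
#' count_block_sequential_modes(12)  # the mode count of the floral network
#' @export
count_block_sequential_modes <- function(n) {
  if (length(n) != 1 || n < 0 || n != round(n))
    stop("`n` must be a single non-negative integer", call. = FALSE)
  if (n > 17)
    stop("ordered Bell number for n > 17 exceeds exact double precision",
         call. = FALSE)
  T <- numeric(n + 1)
  T[1] <- 1
  for (m in seq_len(n))
    T[m + 1] <- sum(choose(m, seq_len(m)) * T[m - seq_len(m) + 1])
  T[n + 1]
}

#' Enumerate all block-sequential iteration modes
#'
#' Yields every ordered partition of `{1, ..., n}` exactly once; the total
#' count equals [count_block_sequential_modes()].  Intended for
#' exhaustive classification of small networks and property testing;
#' refused for `n > 6` (the count grows super-exponentially).
#'
#' @param n Number of nodes (at most 6).
#' @return List of modes, each a list of integer index blocks.
#' @export
enumerate_block_sequential_modes <- function(n) {
  if (n > 6)
    stop("mode enumeration is refused for n > 6 (",
         format(count_block_sequential_modes(min(n, 17)), big.mark = ","),
         "+ modes)", call. = FALSE)
  if (n == 0) return(list(list()))
  items <- seq_len(n)
  recurse <- function(remaining) {
    if (length(remaining) == 0) return(list(list()))
    out <- list()
    m <- length(remaining)
    ## non-empty subsets of `remaining` as the first block
    for (s in seq_len(2^m - 1)) {
      pick <- bitwAnd(s %/% 2^(seq_len(m) - 1), 1L) == 1L
      first <- remaining[pick]
      for (rest in recurse(remaining[!pick]))
        out[[length(out) + 1L]] <- c(list(first), rest)
    }
    out
  }
  recurse(items)
}
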