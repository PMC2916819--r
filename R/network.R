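#' Threshold Boolean automata networks
#'
#' A threshold Boolean automata network (TBAN) is a set of `n` binary nodes
#' whose states evolve by the rule
#' \deqn{x_i(t+1) = H\Big(\sum_j w_{ji}\, x_j(t) - \theta_i\Big),}
#' where `W = (w_ji)` is an integer interaction matrix (entry `w[j, i]` is
#' the weight of the action of node `j` on node `i`, 0 meaning "no arc"),
#' `theta` an integer vector of activation thresholds and `H` the Heaviside
#' step function.  By default `H(u) = 1` iff `u >= 0`, i.e. a node activates
#' when its interaction potential reaches its threshold; setting
#' `strict_threshold = TRUE` switches to `H(u) = 1` iff `u > 0`, which is
#' exposed for sensitivity checks only.
#'
#' Nodes may be *clamped* to a fixed state to model a boundary condition
#' (for instance a hormone flow forcing a boundary gene inactive).  A
#' clamped node never changes state under any operation of the package:
#' it is excluded from iteration-mode blocks and from perturbation flips,
#' and the effective dimension used in size and passage formulas is the
#' number of free nodes.
#'
#' @param weights Square integer matrix; `weights[j, i]` is the weight of
#'   the action of node `j` on node `i`.
#' @param thresholds Integer vector of activation thresholds, one per node.
#' @param nodes Character vector of node names.  Defaults to the dimnames
#'   of `weights`, or `v1 ... vn`.
#' @param clamps Named list or vector mapping node names to fixed states in
#'   `{0, 1}`.  May be empty.
#' @param strict_threshold Logical; use the strict Heaviside convention.
#'
#' @return An object of class `"tban"`: a list with elements `nodes`,
#'   `W`, `theta`, `clamps` (named integer vector) and `strict_threshold`.
#' @examples
#' # a two-node mutual-activation network
#' net <- tban(matrix(c(0, 1, 1, 0), 2, 2), c(1, 1), nodes = c("a", "b"))
#' step_mode(net, c(1, 1), mode_parallel(net))
#' @seealso [step_mode()], [enumerate_basins()], [clamp()]
#' @export
tban <- function(weights, thresholds, nodes = NULL, clamps = NULL,
                 strict_threshold = FALSE) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("`weights` must be a square matrix (got ",
         paste(dim(weights), collapse = " x "), ")", call. = FALSE)
  n <- nrow(weights)
  if (length(thresholds) != n)
    stop("`thresholds` has length ", length(thresholds),
         " but `weights` is ", n, " x ", n, call. = FALSE)
  if (any(weights != round(weights)) || any(thresholds != round(thresholds)))
    stop("weights and thresholds must be integers", call. = FALSE)
  if (is.null(nodes)) nodes <- rownames(weights) %||% paste0("v", seq_len(n))
  if (length(nodes) != n || anyDuplicated(nodes))
    stop("`nodes` must give one distinct name per node", call. = FALSE)
  W <- matrix(as.integer(weights), n, n, dimnames = list(nodes, nodes))
  theta <- stats::setNames(as.integer(thresholds), nodes)
  cl <- stats::setNames(integer(0), character(0))
  if (length(clamps)) {
    cl <- unlist(clamps)
    if (is.null(names(cl)) || !all(names(cl) %in% nodes))
      stop("clamp names must be node names", call. = FALSE)
    if (!all(cl %in% c(0, 1)))
      stop("clamp values must be 0 or 1", call. = FALSE)
    cl <- stats::setNames(as.integer(cl), names(cl))
  }
  structure(
    list(nodes = nodes, W = W, theta = theta, clamps = cl,
         strict_threshold = isTRUE(strict_threshold)),
    class = "tban"
  )
}

#' @export
print.tban <- function(x, ...) {
  n <- length(x$nodes)
  cat("Threshold Boolean automata network: ", n, " nodes, ",
      sum(x$W != 0), " arcs\n", sep = "")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  if (length(x$clamps))
    cat("  clamped: ",
        paste(names(x$clamps), x$clamps, sep = " = ", collapse = ", "),
        "  (", length(free_nodes(x)), " free nodes)\n", sep = "")
  if (x$strict_threshold) cat("  strict threshold convention (H(u)=1 iff u>0)\n")
  invisible(x)
}

#' @rdname tban
#' @param x Object to test.
#' @export
is_tban <- function(x) inherits(x, "tban")

#' Free (unclamped) node indices
#'
#' @param net A [tban()] network.
#' @return Integer vector of indices of nodes not held fixed by a clamp.
#' @export
free_nodes <- function(net) {
  which(!(net$nodes %in% names(net$clamps)))
}

#' Clamp or release a boundary node
#'
#' Clamping fixes a node's state, shrinking the free configuration space
#' from \eqn{2^n} to \eqn{2^{n-1}}.  All dynamics, metrics and
#' perturbations afterwards treat the coordinate as frozen; in particular
#' stochastic perturbations never flip it.  Re-clamping a node to the value
#' it already holds is a no-op; re-clamping to the opposite value is an
#' error (release it first).
#'
#' @param net A [tban()] network.
#' @param node Node name.
#' @param value Fixed state, 0 or 1.
#' @return The modified network.
#' @examples
#' ga_present <- clamp(toy_model(), "rga", 0)
#' length(free_nodes(ga_present))
#' @export
clamp <- function(net, node, value) {
  stopifnot(is_tban(net))
  if (!node %in% net$nodes) stop("unknown node `", node, "`", call. = FALSE)
  if (!value %in% c(0, 1)) stop("clamp value must be 0 or 1", call. = FALSE)
  if (node %in% names(net$clamps) && net$clamps[[node]] != value)
    stop("node `", node, "` is already clamped to ", net$clamps[[node]],
         "; unclamp() it first", call. = FALSE)
  net$clamps[node] <- as.integer(value)
  net
}

#' @rdname clamp
#' @export
unclamp <- function(net, node) {
  stopifnot(is_tban(net))
  net$clamps <- net$clamps[setdiff(names(net$clamps), node)]
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

heaviside <- function(u, strict) if (strict) (u > 0) * 1L else (u >= 0) * 1L

#' Coerce to a configuration vector
#'
#' A configuration assigns a state in `{0, 1}` to every node, ordered by
#' the network's node names (leftmost character = first node).  Accepted
#' inputs: a 0/1 vector of length `n`, a bit string such as `"0101"`, or a
#' single non-negative integer code in `[0, 2^n)` under the convention that
#' the first node is the most significant bit.  Clamped coordinates are
#' forced to their clamp values.
#'
#' @param x Configuration in any accepted form.
#' @param net A [tban()] network.
#' @return Named integer 0/1 vector of length `n`.
#' @export
as_config <- function(x, net) {
  n <- length(net$nodes)
  if (is.character(x) && length(x) == 1) {
    if (nchar(x) != n) stop("bit string must have ", n, " characters", call. = FALSE)
    x <- as.integer(strsplit(x, "")[[1]])
  } else if (is.numeric(x) && length(x) == 1 && n > 1) {
    if (x < 0 || x >= 2^n) stop("configuration code out of range", call. = FALSE)
    x <- config_states(x, n)
  }
  x <- as.integer(x)
  if (length(x) != n || !all(x %in% c(0, 1)))
    stop("configuration must be a 0/1 vector of length ", n, call. = FALSE)
  names(x) <- net$nodes
  if (length(net$clamps)) x[names(net$clamps)] <- net$clamps
  x
}

#' @rdname as_config
#' @param states Integer 0/1 vector.
#' @return `config_code()`: the integer code; `config_states()`: the 0/1
#'   vector; `config_string()`: the bit string.
#' @export
config_code <- function(states) {
  n <- length(states)
  sum(as.numeric(states) * 2^((n - 1):0))
}

#' @rdname as_config
#' @param code Integer configuration code.
#' @param n Number of nodes.
#' @export
config_states <- function(code, n) {
  vapply(seq_len(n), function(i) bitwAnd(code %/% 2^(n - i), 1L), integer(1))
}

#' @rdname as_config
#' @export
config_string <- function(states) paste(states, collapse = "")

#' Interaction potential of a node
#'
#' The interaction potential of node `i` in configuration `x` is
#' \eqn{\sum_j w_{ji} x_j}; the node's next state is the Heaviside step of
#' the potential minus the activation threshold.
#'
#' @inheritParams as_config
#' @param i Node index or name.
#' @return Integer potential.
#' @export
interaction_potential <- function(net, x, i) {
  x <- as_config(x, net)
  i <- node_index(net, i)
  sum(net$W[, i] * x)
}

node_index <- function(net, i) {
  if (is.character(i)) i <- match(i, net$nodes)
  if (is.na(i) || i < 1 || i > length(net$nodes))
    stop("node index out of range", call. = FALSE)
  as.integer(i)
}

#' Local transition of a single node
#'
#' Applies the threshold rule to one node.  Clamped nodes have no local
#' transition: callers must skip them, and asking for one is an error.
#'
#' @inheritParams interaction_potential
#' @return 0 or 1.
#' @export
local_transition <- function(net, x, i) {
  i <- node_index(net, i)
  if (net$nodes[i] %in% names(net$clamps))
    stop("node `", net$nodes[i], "` is clamped; it has no local transition",
         call. = FALSE)
  unname(heaviside(interaction_potential(net, x, i) - net$theta[[i]],
                   net$strict_threshold))
}

#' Update a block of nodes in parallel
#'
#' All nodes of `block` receive their local transition evaluated on the
#' *input* configuration; all other coordinates are copied unchanged.  An
#' empty block is the identity.
#'
#' @inheritParams interaction_potential
#' @param block Integer vector of node indices (or character names) within
#'   the free node set.
#' @return The successor configuration (named 0/1 vector).
#' @export
step_block <- function(net, x, block) {
  x <- as_config(x, net)
  if (length(block) == 0) return(x)
  if (is.character(block)) block <- match(block, net$nodes)
  block <- as.integer(block)
  if (any(is.na(block)) || any(block < 1) || any(block > length(net$nodes)))
    stop("block contains an unknown node", call. = FALSE)
  if (any(net$nodes[block] %in% names(net$clamps)))
    stop("block contains a clamped node", call. = FALSE)
  pot <- as.vector(x %*% net$W[, block, drop = FALSE])
  x[block] <- heaviside(pot - net$theta[block], net$strict_threshold)
  x
}

#' Block-sequential iteration modes
#'
#' An iteration mode is an ordered partition of the free node set into
#' disjoint, non-empty blocks.  Nodes within a block are updated in
#' parallel; blocks are applied in sequence, each reading the configuration
#' produced by the previous one.  The parallel mode is the single-block
#' partition; a sequential mode has one singleton block per node.
#'
#' @param net A [tban()] network.
#' @param blocks List of node-name (or index) vectors.
#' @return An object of class `"iteration_mode"`: a list of integer index
#'   blocks with the network's node names attached.
#' @examples
#' net <- toy_model()
#' mode_sequential(net)        # 13 singleton blocks
#' mode_parallel(clamp(net, "rga", 0))
#' @export
iteration_mode <- function(net, blocks) {
  stopifnot(is_tban(net))
  idx <- lapply(blocks, function(b) {
    if (is.character(b)) b <- match(b, net$nodes)
    as.integer(b)
  })
  flat <- unlist(idx)
  free <- free_nodes(net)
  if (length(idx) == 0 || any(lengths(idx) == 0))
    stop("iteration mode blocks must be non-empty", call. = FALSE)
  if (any(is.na(flat))) stop("unknown node in iteration mode", call. = FALSE)
  if (anyDuplicated(flat))
    stop("iteration mode blocks must be disjoint", call. = FALSE)
  if (!setequal(flat, free))
    stop("iteration mode must cover exactly the free (unclamped) nodes",
         call. = FALSE)
  structure(idx, class = "iteration_mode", nodes = net$nodes)
}

#' @rdname iteration_mode
#' @export
mode_parallel <- function(net) iteration_mode(net, list(free_nodes(net)))

#' @rdname iteration_mode
#' @param order Optional permutation of the free nodes (names or indices)
#'   giving the update order; defaults to node order.
#' @export
mode_sequential <- function(net, order = NULL) {
  free <- free_nodes(net)
  if (!is.null(order)) {
    if (is.character(order)) order <- match(order, net$nodes)
    free <- as.integer(order)
  }
  iteration_mode(net, as.list(free))
}

#' @export
print.iteration_mode <- function(x, ...) {
  nodes <- attr(x, "nodes")
  cat("Iteration mode (", length(x), " blocks): ",
      paste(vapply(x, function(b) paste0("{", paste(nodes[b], collapse = ","), "}"),
                   character(1)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' One macro time step of the deterministic flow
#'
#' Applies [step_block()] for each block of `mode` in order; the result is
#' one application of the global transition function `F`.
#'
#' @inheritParams interaction_potential
#' @param mode An [iteration_mode()] (or a plain list of blocks).
#' @return The successor configuration.
#' @export
step_mode <- function(net, x, mode) {
  if (!inherits(mode, "iteration_mode")) mode <- iteration_mode(net, mode)
  x <- as_config(x, net)
  for (b in mode) x <- step_block(net, x, b)
  x
}

## Vectorised macro step over a matrix of configurations (rows), used by the
## exhaustive sweeps.  Clamp columns are held fixed by construction of the
## input matrix and never belong to a block.
step_all <- function(net, S, mode) {
  strict <- net$strict_threshold
  for (b in mode) {
    pot <- S %*% net$W[, b, drop = FALSE]
    S[, b] <- heaviside(sweep(pot, 2, net$theta[b], `-`), strict)
  }
  S
}

## Matrix of all free-space configurations (full n columns, clamped columns
## filled with clamp values), plus their integer codes.
free_space <- function(net) {
  n <- length(net$nodes)
  free <- free_nodes(net)
  nf <- length(free)
  if (nf > 24)
    stop("free configuration space has 2^", nf,
         " states; exhaustive enumeration is refused above 2^24", call. = FALSE)
  S <- matrix(0L, 2^nf, n, dimnames = list(NULL, net$nodes))
  if (length(net$clamps)) S[, names(net$clamps)] <- rep(net$clamps, each = 2^nf)
  idx <- 0:(2^nf - 1)
  for (k in seq_len(nf))
    S[, free[k]] <- bitwAnd(idx %/% 2^(nf - k), 1L)
  codes <- as.vector(S %*% 2^((n - 1):0))
  list(S = S, codes = codes)
}

#' Read or write a network in JSON form
#'
#' The JSON format is
#' `{"nodes": [...], "weights": [[...]], "thresholds": [...], "clamps": {...}}`,
#' where `weights[j][i]` is the weight of the action of node `j` on node
#' `i`.  `write_network()` then `read_network()` round-trips bit-exactly.
#'
#' @param path File path.
#' @return `read_network()`: a validated [tban()] network.
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("nodes", "weights", "thresholds"))
    if (is.null(obj[[f]]))
      stop("network file is missing field `", f, "`", call. = FALSE)
  W <- obj$weights
  if (is.list(W)) {
    if (length(unique(lengths(W))) != 1)
      stop("field `weights` is not a rectangular matrix", call. = FALSE)
    W <- do.call(rbind, W)
  }
  if (!is.numeric(W))
    stop("field `weights` must be numeric", call. = FALSE)
  if (any(W != round(W)) || any(obj$thresholds != round(obj$thresholds)))
    stop("fields `weights` and `thresholds` must be integer-valued",
         call. = FALSE)
  tban(W, obj$thresholds, nodes = obj$nodes, clamps = obj$clamps,
       strict_threshold = isTRUE(obj$strict_threshold))
}

#' @rdname read_network
#' @param net A [tban()] network.
#' @export
write_network <- function(net, path) {
  stopifnot(is_tban(net))
  obj <- list(
    nodes = net$nodes,
    weights = unname(net$W),
    thresholds = unname(net$theta)
  )
  if (length(net$clamps)) obj$clamps <- as.list(net$clamps)
  if (net$strict_threshold) obj$strict_threshold <- TRUE
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
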