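#' Characteristic polynomial of a basin-to-basin passage probability
#'
#' Under an i.i.d. stochastic state perturbation each free node flips with
#' probability `p`.  The probability that a configuration drawn uniformly
#' from basin `B_i` is carried into basin `B_j` is
#' \deqn{P(B_i \to B_j)(p) = \frac{1}{|B_i|} \sum_{x \in B_i} \sum_{d=0}^{n}
#'   N_d(x, B_j)\, p^d (1-p)^{n-d},}
#' where \eqn{N_d(x, B_j)} counts the configurations of `B_j` at Hamming
#' distance `d` from `x` and `n` is the number of free nodes.  The
#' polynomial is stored in the Bernstein-like basis as the exact integer
#' coefficient vector \eqn{c_d = \sum_{x \in B_i} N_d(x, B_j)}: counts are
#' exact, the row-sum identity \eqn{\sum_j c^{(ij)}_d = |B_i| \binom{n}{d}}
#' is checkable coefficient-wise, and evaluation is numerically stable.
#'
#' The `restricted` variant runs the outer sum only over the
#' configurations belonging to the attractor cycles of `B_i` (perturbation
#' applied at the attractor rather than anywhere in the basin), leaving
#' the attractors themselves unchanged in nature, number and location.
#'
#' Clamped coordinates are never flipped: distances are computed in the
#' free coordinates only (clamped coordinates agree within a partition).
#' The exhaustive double sweep is refused above 14 free nodes; use
#' [monte_carlo_passage()] for larger systems.
#'
#' @param partition A [enumerate_basins()] partition (possibly merged).
#' @param origin,target Basin labels or indices.
#' @param restricted Restrict the origin sum to attractor configurations.
#' @return An object of class `"passage_polynomial"`: list with `origin`,
#'   `target`, `n` (free-node count), `origin_size` and `raw_counts`
#'   (length `n + 1`, exact integers).
#' @examples
#' net <- tban(matrix(1), 1, nodes = "m")   # bistable memory node
#' part <- enumerate_basins(net, mode_parallel(net))
#' evaluate_passage(passage_polynomial(part, 1, 2), 0.3)  # = p
#' @export
passage_polynomial <- function(partition, origin, target, restricted = FALSE) {
  i <- basin_id(partition, origin)
  j <- basin_id(partition, target)
  nf <- length(free_nodes(partition$net))
  guard_passage(nf)
  A <- if (restricted) attractor_configs(partition, i)
       else basin_configs(partition, i)
  B <- basin_configs(partition, j)
  n_all <- length(partition$net$nodes)
  pc <- popcount_table(n_all)
  new_passage_polynomial(
    partition$labels[i], partition$labels[j], nf, length(A),
    raw_distance_counts(A, B, nf, pc)
  )
}

basin_id <- function(partition, b) {
  i <- if (is.character(b)) match(b, partition$labels) else as.integer(b)
  if (is.na(i) || i < 1 || i > length(partition$attractors))
    stop("unknown basin `", b, "`", call. = FALSE)
  i
}

guard_passage <- function(nf) {
  if (nf > 14)
    stop("exact passage polynomials are refused above 14 free nodes; ",
         "use monte_carlo_passage()", call. = FALSE)
}

## exact histogram of pairwise Hamming distances between code sets,
## chunked to bound memory; clamped coordinates agree so the full-word
## distance equals the free-coordinate distance
raw_distance_counts <- function(A, B, nf, pc) {
  counts <- numeric(nf + 1)
  chunk <- max(1L, floor(4e6 / max(length(B), 1)))
  for (k in seq(1, length(A), by = chunk)) {
    a <- A[k:min(k + chunk - 1, length(A))]
    d <- pc[bitwXor(rep(a, each = length(B)), rep.int(B, length(a))) + 1L]
    counts <- counts + tabulate(d + 1L, nf + 1L)
  }
  counts
}

new_passage_polynomial <- function(origin, target, n, origin_size, raw_counts) {
  structure(
    list(origin = origin, target = target, n = n,
         origin_size = origin_size, raw_counts = raw_counts),
    class = "passage_polynomial"
  )
}

#' @export
print.passage_polynomial <- function(x, ...) {
  cat("Passage polynomial P(", x$origin, " -> ", x$target, ")(p), n = ",
      x$n, ", |origin| = ", x$origin_size, "\n", sep = "")
  cat("  counts per distance d = 0..", x$n, ": ",
      paste(format(x$raw_counts, scientific = FALSE), collapse = " "),
      "\n", sep = "")
  cat("  P(0) = ", evaluate_passage(x, 0), ", P(1) = ",
      format(evaluate_passage(x, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Evaluate a passage polynomial
#'
#' Evaluates \eqn{P(p) = \frac{1}{|B_i|}\sum_d c_d\, p^d (1-p)^{n-d}} in
#' the Bernstein basis.  `P(0)` is 1 for the diagonal polynomial and 0 off
#' the diagonal; `P(1)` is the fraction of origin configurations whose
#' coordinate-wise complement (on the free nodes) lies in the target
#' basin.
#'
#' @param poly A [passage_polynomial()].
#' @param p Perturbation rate(s) in `[0, 1]`; vectorised.
#' @return Numeric vector of probabilities.
#' @export
evaluate_passage <- function(poly, p) {
  if (any(p < 0 | p > 1))
    stop("perturbation rate must lie in [0, 1]", call. = FALSE)
  d <- 0:poly$n
  vapply(p, function(pp)
    sum(poly$raw_counts * pp^d * (1 - pp)^(poly$n - d)) / poly$origin_size,
    numeric(1))
}

#' @rdname evaluate_passage
#' @param num,den Numerator and denominator of a rational rate `p = num/den`.
#' @return `evaluate_passage_exact()`: list `num`, `den`, `value` with the
#'   probability as an exact reduced rational.
#' @export
evaluate_passage_exact <- function(poly, num, den) {
  if (num < 0 || num > den || den <= 0)
    stop("need 0 <= num/den <= 1", call. = FALSE)
  d <- 0:poly$n
  ## common denominator den^n * origin_size; exact while below 2^53
  terms <- poly$raw_counts * num^d * (den - num)^(poly$n - d)
  N <- sum(terms)
  D <- den^poly$n * poly$origin_size
  if (!is.finite(N) || !is.finite(D) || D > 2^53 || max(terms) > 2^53)
    stop("exact evaluation overflows double precision for this rate",
         call. = FALSE)
  g <- gcd(N, D); if (g == 0) g <- 1
  list(num = N / g, den = D / g, value = N / D)
}

#' Full passage-probability matrix of a partition
#'
#' Computes the characteristic polynomials of the passage probabilities
#' from every basin to every other.  The matrix satisfies the coefficient
#' row-sum identity \eqn{\sum_j c^{(ij)}_d = |B_i| \binom{n}{d}} for every
#' `d`, hence \eqn{\sum_j P(B_i \to B_j)(p) = 1} for all `p` (the
#' perturbed configuration always lands in exactly one basin).
#'
#' @inheritParams passage_polynomial
#' @return An object of class `"passage_matrix"`: a tibble with columns
#'   `origin`, `target` and a list-column `poly` of
#'   [passage_polynomial()]s, with the partition's free-node count in
#'   attribute `"n"`.
#' @export
passage_matrix <- function(partition, restricted = FALSE) {
  nf <- length(free_nodes(partition$net))
  guard_passage(nf)
  labs <- partition$labels
  n_all <- length(partition$net$nodes)
  pc <- popcount_table(n_all)
  origins <- lapply(seq_along(labs), function(i)
    if (restricted) attractor_configs(partition, i)
    else basin_configs(partition, i))
  targets <- lapply(seq_along(labs), function(j) basin_configs(partition, j))
  out <- tidyr::expand_grid(origin = labs, target = labs)
  out$poly <- purrr::pmap(out, function(origin, target) {
    i <- match(origin, labs); j <- match(target, labs)
    new_passage_polynomial(
      origin, target, nf, length(origins[[i]]),
      raw_distance_counts(origins[[i]], targets[[j]], nf, pc)
    )
  })
  class(out) <- c("passage_matrix", class(out))
  attr(out, "n") <- nf
  attr(out, "restricted") <- restricted
  out
}

#' @rdname passage_matrix
#' @export
attractor_restricted_passage <- function(partition) {
  passage_matrix(partition, restricted = TRUE)
}

#' Tidy a passage matrix into per-rate probabilities
#'
#' @param x A [passage_matrix()].
#' @param p Rates at which to evaluate each polynomial.
#' @param ... Unused.
#' @return A tibble with columns `origin`, `target`, `p`, `probability`.
#' @export
tidy.passage_matrix <- function(x, p = seq(0, 1, by = 0.05), ...) {
  purrr::pmap_dfr(x, function(origin, target, poly)
    tibble::tibble(origin = origin, target = target, p = p,
                   probability = evaluate_passage(poly, p)))
}

#' Monte-Carlo estimate of passage frequencies
#'
#' Samples configurations uniformly from the origin basin, flips each free
#' coordinate independently with probability `p` (clamped coordinates are
#' never flipped), assigns each perturbed configuration to its basin, and
#' returns empirical frequencies.  Used as an independent check of the
#' exact polynomials, and as the estimator of choice for systems too large
#' for the exhaustive sweep.
#'
#' @inheritParams passage_polynomial
#' @param p Perturbation rate in `[0, 1]`.
#' @param n_samples Number of samples (positive).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `target` and `frequency`, one row per
#'   basin of the partition.
#' @export
monte_carlo_passage <- function(partition, origin, p, n_samples = 1e4,
                                seed = NULL) {
  if (n_samples <= 0) stop("`n_samples` must be positive", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  i <- basin_id(partition, origin)
  A <- basin_configs(partition, i)
  net <- partition$net
  n <- length(net$nodes)
  free <- free_nodes(net)
  x <- A[sample.int(length(A), n_samples, replace = TRUE)]
  flips <- matrix(stats::runif(n_samples * length(free)) < p,
                  n_samples, length(free))
  delta <- as.vector(flips %*% 2^(n - free))
  y <- bitwXor(as.integer(x), as.integer(delta))
  pos <- code_lookup(partition$codes)
  hit <- partition$basin[pos(y)]
  tibble::tibble(
    target = partition$labels,
    frequency = tabulate(hit, length(partition$labels)) / n_samples
  )
}
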