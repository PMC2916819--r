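#' Hamming distance between configurations
#'
#' Number of coordinates at which two equal-length binary words differ.
#'
#' @param x,y Configurations: 0/1 vectors or bit strings of equal length.
#' @return Non-negative integer.
#' @examples
#' hamming_distance("0101", "1010")  # 4
#' @export
hamming_distance <- function(x, y) {
  x <- as_bits(x); y <- as_bits(y)
  if (length(x) != length(y))
    stop("configurations have different lengths", call. = FALSE)
  sum(x != y)
}

as_bits <- function(x) {
  if (is.character(x) && length(x) == 1) x <- strsplit(x, "")[[1]]
  x <- as.integer(x)
  if (!all(x %in% c(0, 1))) stop("not a binary word", call. = FALSE)
  x
}

## popcount lookup table for codes 0 .. 2^n - 1, built by doubling
popcount_table <- function(n) {
  pc <- 0L
  for (i in seq_len(n)) pc <- c(pc, pc + 1L)
  pc
}

## convert bit strings to integer codes (and back) outside a network context
strings_to_codes <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(s) strtoi(s, base = 2L), numeric(1), USE.NAMES = FALSE)
}

## minimal Hamming distance from each code in A to the set B (codes), n bits
min_dist_to_set <- function(A, B, n, pc = popcount_table(n)) {
  vapply(A, function(a) min(pc[bitwXor(a, B) + 1L]), numeric(1))
}

#' Absolute and relative basin sizes
#'
#' The absolute size of an attraction basin is its cardinality; its
#' relative size is the absolute size divided by the number of free
#' configurations, i.e. the probability that a uniformly random initial
#' configuration lands in it.  Relative sizes are returned as exact
#' rationals (numerator/denominator columns) alongside their decimal
#' value; they sum to exactly 1.
#'
#' @param partition A [enumerate_basins()] partition (possibly merged).
#' @return A tibble with columns `basin`, `period`, `size`,
#'   `relative_num`, `relative_den`, `relative_size`, `percent`.
#' @export
basin_sizes <- function(partition) {
  sizes <- tabulate(partition$basin, length(partition$attractors))
  den <- length(partition$codes)
  g <- vapply(sizes, function(s) gcd(s, den), numeric(1))
  g[sizes == 0] <- 1
  tibble::tibble(
    basin = partition$labels,
    period = vapply(partition$attractors, function(a) a$period, integer(1)),
    size = sizes,
    relative_num = sizes / g,
    relative_den = den / g,
    relative_size = sizes / den,
    percent = 100 * sizes / den
  )
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Modified-Hausdorff relative distance between configuration sets
#'
#' The relative distance from set `A` to set `B` is the arithmetic mean,
#' over the words of `A`, of the minimal Hamming distance to a word of
#' `B`.  It is not symmetric: \eqn{\delta(A, B) \ne \delta(B, A)} in
#' general, which is why it is called *relative* rather than a distance.
#' The result is an exact rational (the numerator is an integer sum of
#' minimal distances, the denominator is `|A|`).
#'
#' @param A,B Non-empty sets of equal-length binary words: character
#'   vectors of bit strings, or integer codes with `n_bits` supplied.
#' @param n_bits Word length; required when `A`, `B` are integer codes.
#' @return An object of class `"relative_distance"`: list with `num`,
#'   `den` (reduced), `value`, and the sizes of both sets.
#' @examples
#' relative_distance(c("00", "11"), "00")  # 1
#' relative_distance("00", c("00", "11"))  # 0 (asymmetry witness)
#' @export
relative_distance <- function(A, B, n_bits = NULL) {
  if (length(A) == 0 || length(B) == 0)
    stop("relative distance is undefined for empty sets", call. = FALSE)
  if (is.character(A)) {
    n_bits <- nchar(A[1])
    if (any(nchar(A) != n_bits) || any(nchar(B) != n_bits))
      stop("all words must have equal length", call. = FALSE)
  }
  if (is.null(n_bits)) stop("`n_bits` is required for integer codes", call. = FALSE)
  a <- strings_to_codes(A); b <- strings_to_codes(B)
  num <- sum(min_dist_to_set(a, b, n_bits))
  den <- length(a)
  g <- gcd(num, den); if (g == 0) g <- 1
  structure(
    list(num = num / g, den = den / g, value = num / den,
         size_origin = length(a), size_target = length(b), n_bits = n_bits),
    class = "relative_distance"
  )
}

#' @export
print.relative_distance <- function(x, ...) {
  cat("relative distance = ", x$num, "/", x$den,
      " = ", format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Distribution of minimal distances between two basins
#'
#' For each word of the origin set, the minimal Hamming distance to the
#' target set is computed; the result is the histogram of these minima
#' over `d = 0 .. n`.  Its mean equals [relative_distance()] exactly
#' (integer arithmetic).  For distinct basins of one partition the count
#' at `d = 0` is zero, since basins are disjoint.
#'
#' @inheritParams relative_distance
#' @return A tibble with columns `d`, `count`, `percent`; the origin size
#'   and the exact mean (num/den) are attached as attributes `"total"`,
#'   `"mean_num"`, `"mean_den"`.
#' @export
distance_distribution <- function(A, B, n_bits = NULL) {
  if (length(A) == 0 || length(B) == 0)
    stop("distance distribution is undefined for empty sets", call. = FALSE)
  if (is.character(A)) n_bits <- nchar(A[1])
  if (is.null(n_bits)) stop("`n_bits` is required for integer codes", call. = FALSE)
  a <- strings_to_codes(A); b <- strings_to_codes(B)
  md <- min_dist_to_set(a, b, n_bits)
  counts <- tabulate(md + 1L, n_bits + 1L)
  out <- tibble::tibble(
    d = 0:n_bits,
    count = counts,
    percent = 100 * counts / length(a)
  )
  attr(out, "total") <- length(a)
  attr(out, "mean_num") <- sum(md)
  attr(out, "mean_den") <- length(a)
  out
}

#' All pairwise relative distances between the basins of a partition
#'
#' Cross-regime comparisons (a clamped partition against a free one) are
#' supported by passing two partitions over the same node set: basin
#' configuration sets are compared as full-length words, clamped
#' coordinates filled with their clamp values.
#'
#' @param partition A basin partition supplying the origin basins.
#' @param target_partition Optional partition supplying the target basins;
#'   defaults to `partition`.
#' @return A tibble with columns `origin`, `target`, `num`, `den`,
#'   `distance`.
#' @export
relative_distance_matrix <- function(partition, target_partition = partition) {
  n <- length(partition$net$nodes)
  if (length(target_partition$net$nodes) != n)
    stop("partitions are over different node sets", call. = FALSE)
  pc <- popcount_table(n)
  tidyr::expand_grid(origin = partition$labels,
                     target = target_partition$labels) |>
    dplyr::mutate(purrr::map2_dfr(.data$origin, .data$target, function(o, t) {
      A <- basin_configs(partition, o)
      B <- basin_configs(target_partition, t)
      num <- sum(min_dist_to_set(A, B, n, pc))
      den <- length(A)
      g <- gcd(num, den); if (g == 0) g <- 1
      tibble::tibble(num = num / g, den = den / g, distance = num / den)
    }))
}
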