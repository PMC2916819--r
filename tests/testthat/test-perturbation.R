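test_that("degenerate passage polynomials behave as probability dictates", {
  ## single-basin system: every perturbation stays inside
  always_on <- tban(matrix(0L, 1, 1), -1, nodes = "u")
  part <- enumerate_basins(always_on, mode_parallel(always_on))
  poly <- passage_polynomial(part, 1, 1)
  expect_equal(evaluate_passage(poly, c(0, 0.3, 0.7, 1)), rep(1, 4))

  ## bistable memory node: two one-configuration basins
  mem <- tban(matrix(1L, 1, 1), 1, nodes = "m")
  pm <- enumerate_basins(mem, mode_parallel(mem))
  p01 <- passage_polynomial(pm, 1, 2)
  p00 <- passage_polynomial(pm, 1, 1)
  for (p in c(0, 0.25, 0.8, 1)) {
    expect_equal(evaluate_passage(p01, p), p)
    expect_equal(evaluate_passage(p00, p), 1 - p)
  }
  expect_error(evaluate_passage(p01, 1.5), "\\[0, 1\\]")
  expect_error(passage_polynomial(pm, 1, 9), "unknown basin")
})

test_that("two independent bistable nodes give the product-form polynomials", {
  W <- matrix(0L, 2, 2); diag(W) <- 1L
  net <- tban(W, c(1, 1), nodes = c("a", "b"))
  part <- enumerate_basins(net, mode_parallel(net))
  expect_identical(length(part$attractors), 4L)
  pm <- passage_matrix(part)
  for (i in 1:4) for (j in 1:4) {
    d <- hamming_distance(config_states(part$attractors[[i]]$cycle[1], 2),
                          config_states(part$attractors[[j]]$cycle[1], 2))
    poly <- get_poly(pm, part$labels[i], part$labels[j])
    for (p in c(0.1, 0.5, 0.9))
      expect_equal(evaluate_passage(poly, p), p^d * (1 - p)^(2 - d))
  }
})

test_that("passage counts match the naive double loop on small systems", {
  set.seed(17)
  for (rep in 1:3) {
    net <- random_network(4, 0.5, seed = 300 + rep)
    part <- enumerate_basins(net, random_mode(net))
    for (i in seq_along(part$attractors)) for (j in seq_along(part$attractors)) {
      poly <- passage_polynomial(part, i, j)
      expect_identical(
        poly$raw_counts,
        naive_passage_counts(basin_configs(part, i), basin_configs(part, j), 4))
    }
  }
})

test_that("the passage matrix satisfies the exact row-sum identity", {
  net <- random_network(5, 0.5, seed = 77)
  part <- enumerate_basins(net, mode_sequential(net))
  pm <- passage_matrix(part)
  sizes <- tidy(part)$size
  nf <- attr(pm, "n")
  for (i in seq_along(part$labels)) {
    rows <- pm$poly[pm$origin == part$labels[i]]
    coef_sum <- Reduce(`+`, lapply(rows, function(pp) pp$raw_counts))
    expect_identical(coef_sum, sizes[i] * choose(nf, 0:nf))
  }
  ## P(0) is the identity row; probabilities stay within [0, 1]
  for (pp in pm$poly) {
    expect_identical(evaluate_passage(pp, 0),
                     as.numeric(pp$origin == pp$target))
    expect_true(all(evaluate_passage(pp, seq(0, 1, 0.1)) >= 0))
    expect_true(all(evaluate_passage(pp, seq(0, 1, 0.1)) <= 1 + 1e-12))
  }
  ## evaluation at p = 1 equals the complement-scan fraction
  n_all <- length(net$nodes)
  for (i in seq_along(part$labels)) {
    A <- basin_configs(part, i)
    comp <- bitwXor(A, 2^n_all - 1L)
    for (j in seq_along(part$labels)) {
      frac <- mean(comp %in% basin_configs(part, j))
      expect_equal(evaluate_passage(get_poly(pm, part$labels[i],
                                             part$labels[j]), 1), frac)
    }
  }
})

test_that("exact rational evaluation agrees with the numeric one", {
  mem <- tban(matrix(1L, 1, 1), 1, nodes = "m")
  pm <- enumerate_basins(mem, mode_parallel(mem))
  poly <- passage_polynomial(pm, 1, 2)
  ex <- evaluate_passage_exact(poly, 1, 4)
  expect_identical(c(ex$num, ex$den), c(1, 4))
  expect_error(evaluate_passage_exact(poly, 3, 2), "num/den")

  sep <- get_poly(passage_free(), "Sep", "Sep")
  ex <- evaluate_passage_exact(sep, 1, 2)
  expect_equal(ex$value, evaluate_passage(sep, 0.5))
})

test_that("restricted passage sums over attractor configurations only", {
  ## when every basin equals its attractor the two variants coincide
  W <- matrix(0L, 2, 2); diag(W) <- 1L
  net <- tban(W, c(1, 1), nodes = c("a", "b"))
  part <- enumerate_basins(net, mode_parallel(net))
  pm <- passage_matrix(part)
  pr <- attractor_restricted_passage(part)
  for (k in seq_len(nrow(pm)))
    expect_identical(pm$poly[[k]]$raw_counts, pr$poly[[k]]$raw_counts)

  ## on the merged toy partition the restricted origin is the fixed points
  pr_toy <- attractor_restricted_passage(toy_free_merged())
  sep <- get_poly(pr_toy, "Sep", "Sep")
  expect_identical(sep$origin_size, 2L)   # two sepal fixed points
  ## row sums still form a probability distribution
  for (p in c(0, 0.2, 1)) {
    row <- vapply(toy_free_merged()$labels, function(t)
      evaluate_passage(get_poly(pr_toy, "Sep", t), p), numeric(1))
    expect_equal(sum(row), 1)
  }
})

test_that("Monte-Carlo frequencies agree with the exact polynomials", {
  m <- toy_free_merged()
  pmat <- passage_free()
  for (p in c(0.1, 0.3)) {
    mc <- monte_carlo_passage(m, "Sep", p, n_samples = 2e4, seed = 91)
    for (t in m$labels) {
      exact <- evaluate_passage(get_poly(pmat, "Sep", t), p)
      se <- sqrt(exact * (1 - exact) / 2e4)
      expect_lt(abs(mc$frequency[mc$target == t] - exact), 3 * se + 1e-9)
    }
  }
  expect_error(monte_carlo_passage(m, "Sep", 0.1, n_samples = 0), "positive")
  expect_error(monte_carlo_passage(m, "Sep", 2), "\\[0, 1\\]")
  ## p = 0 leaves every sample in its origin basin
  mc0 <- monte_carlo_passage(m, "Car", 0, n_samples = 500, seed = 1)
  expect_identical(mc0$frequency[mc0$target == "Car"], 1)
})

test_that("perturbation never flips a clamped coordinate", {
  ## two independent memory nodes, second clamped to 0: at p = 1 the free
  ## node flips deterministically and the clamped one must not
  W <- matrix(0L, 2, 2); diag(W) <- 1L
  net <- clamp(tban(W, c(1, 1), nodes = c("a", "b")), "b", 0)
  part <- enumerate_basins(net, mode_sequential(net))
  expect_identical(length(part$attractors), 2L)   # basins {00} and {10}
  mc <- monte_carlo_passage(part, 1, 1, n_samples = 1000, seed = 5)
  expect_identical(mc$frequency[2], 1)            # always lands on the flip
  ## the exact sweep agrees: distances are over the free coordinate only
  poly <- passage_polynomial(part, 1, 2)
  expect_identical(poly$n, 1L)
  expect_equal(evaluate_passage(poly, 1), 1)
  ## and on the clamped floral partition the Monte-Carlo frequencies match
  ## the exact matrix at p = 1 (any rga flip would leave the partition)
  ## (the origin is sampled, so frequencies carry binomial noise even at
  ## p = 1, but an rga flip would push every sample off the partition)
  cl <- toy_clamped_merged()
  mc1 <- monte_carlo_passage(cl, "Sep", 1, n_samples = 2000, seed = 6)
  for (t in cl$labels) {
    exact <- evaluate_passage(get_poly(passage_clamped(), "Sep", t), 1)
    se <- sqrt(exact * (1 - exact) / 2000)
    expect_lt(abs(mc1$frequency[mc1$target == t] - exact), 3 * se + 1e-9)
  }
})

test_that("the exhaustive sweep refuses oversized systems", {
  big <- random_network(15, 0.1, seed = 4)
  fake_part <- structure(list(net = big), class = "basin_partition")
  expect_error(passage_matrix(fake_part), "monte_carlo_passage")
})
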