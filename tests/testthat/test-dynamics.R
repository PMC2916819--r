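test_that("trajectories run to the first repeated configuration", {
  ## a fixed point yields a length-2 trajectory with identical entries
  mem <- tban(matrix(1L, 1, 1), 1, nodes = "m")
  tr <- trajectory(mem, 1, mode_parallel(mem))
  expect_identical(tr$configuration, c("1", "1"))
  ## one-node negation: 0 -> 1 -> 0
  neg <- tban(matrix(-1L, 1, 1), 0, nodes = "a")
  tr <- trajectory(neg, 0, mode_parallel(neg))
  expect_identical(tr$configuration, c("0", "1", "0"))
  expect_error(trajectory(neg, 0, mode_parallel(neg), max_steps = 0),
               "max_steps")
})

test_that("find_attractor extracts the cycle and the transient length", {
  mem <- tban(matrix(1L, 1, 1), 1, nodes = "m")
  fa <- find_attractor(mem, 1, mode_parallel(mem))
  expect_identical(fa$attractor$period, 1L)
  expect_identical(fa$transient, 0L)

  ## 2-node symmetric network: period at most 2 from every start
  W <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  net <- tban(W, c(1, 1), nodes = c("a", "b"))
  for (code in 0:3)
    expect_lte(find_attractor(net, code, mode_parallel(net))$attractor$period, 2)

  ## toy model, sequential mode: every trajectory ends in a fixed point
  toy <- toy_model()
  set.seed(3)
  for (code in sample(0:8191, 12)) {
    fa <- find_attractor(toy, code, floral_modes(toy)$mu1)
    expect_identical(fa$attractor$period, 1L)
  }
})

test_that("release-mechanism genes are frozen after two sequential macro steps", {
  orig <- mendoza_original()
  fs <- basingauge:::free_space(orig)
  mu1 <- floral_modes(orig)$mu1
  S1 <- basingauge:::step_all(orig, fs$S, mu1)
  S2 <- basingauge:::step_all(orig, S1, mu1)
  S3 <- basingauge:::step_all(orig, S2, mu1)
  release <- c("lug", "ufo", "sup", "emf1", "lfy", "cal", "tfl1")
  expect_identical(S3[, release], S2[, release])
})

test_that("basin enumeration matches the printed floral facts", {
  g1 <- glance(orig_mu1())
  expect_identical(g1$n_attractors, 6L)
  expect_identical(g1$n_fixed_points, 6L)

  g2 <- glance(orig_mu2())
  expect_identical(g2$n_fixed_points, 6L)
  expect_identical(g2$n_limit_cycles, 0L)

  gp <- glance(orig_par())
  expect_identical(gp$n_fixed_points, 6L)
  expect_identical(gp$n_limit_cycles, 7L)

  ## the fixed points are the same under every schedule
  fp_keys <- function(part) sort(vapply(
    Filter(function(a) a$period == 1, part$attractors),
    basingauge:::attractor_key, character(1)))
  expect_identical(fp_keys(orig_mu1()), fp_keys(orig_par()))
  expect_identical(fp_keys(orig_mu1()), fp_keys(orig_mu2()))

  gt <- glance(toy_free())
  expect_identical(gt$n_attractors, 8L)
  expect_identical(gt$n_fixed_points, 8L)
})

test_that("basins partition the free space and contain their attractors", {
  for (part in list(orig_mu1(), orig_par(), toy_free(), toy_clamped())) {
    sizes <- tidy(part)$size
    expect_identical(sum(sizes), length(part$codes))
    for (i in seq_along(part$attractors)) {
      members <- basin_configs(part, i)
      expect_true(all(part$attractors[[i]]$cycle %in% members))
    }
  }
  expect_error(enumerate_basins(random_network(25, 0.1, seed = 1),
                                list(1:25)), "2\\^24")
})

test_that("memoised sweep agrees with the naive per-configuration walk", {
  set.seed(21)
  for (rep in 1:4) {
    net <- random_network(sample(3:6, 1), stats::runif(1, 0.2, 0.7),
                          seed = 100 + rep)
    mode <- random_mode(net)
    fast <- enumerate_basins(net, mode)
    slow <- naive_basins(net, mode)
    fast_keys <- vapply(fast$attractors, basingauge:::attractor_key,
                        character(1))
    expect_setequal(fast_keys, names(slow$attractors))
    ## per-configuration assignment must agree
    expect_identical(fast_keys[fast$basin], unname(slow$assignment))
  }
})

test_that("attractor periods obey the symmetric-network theorems", {
  ## symmetric interaction matrix: parallel attractors have period <= 2;
  ## with a non-negative diagonal the bound extends to every
  ## block-sequential mode, and sequential modes give fixed points only
  set.seed(5)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    net <- random_network(n, stats::runif(1, 0.2, 0.8), symmetric = TRUE,
                          seed = 1000 + rep)
    expect_lte(max(tidy(enumerate_basins(net, mode_parallel(net)))$period), 2)

    net2 <- random_network(n, stats::runif(1, 0.2, 0.8), symmetric = TRUE,
                           nonneg_diagonal = TRUE, seed = 2000 + rep)
    expect_lte(max(tidy(enumerate_basins(net2, random_mode(net2)))$period), 2)
    part2 <- enumerate_basins(net2, mode_sequential(net2, sample(n)))
    expect_identical(max(tidy(part2)$period), 1L)
  }
})

test_that("lineage labelling projects toy fixed points onto the original's", {
  labs <- label_lineages(toy_free(), orig_mu1())
  expect_identical(sort(labs),
                   sort(c("Sep", "Sep", "Pet", "Car", "Sta", "Inf", "Inf",
                          "Mut")))
  ## the Pet toy fixed point projects exactly onto the original Pet fixed point
  ref_labs <- lineage_labels(orig_mu1())
  pet_ref <- orig_mu1()$attractors[[which(ref_labs == "Pet")]]$cycle[1]
  pet_toy <- toy_free()$attractors[[which(labs == "Pet")]]$cycle[1]
  expect_identical(config_states(pet_toy, 13)[1:12], config_states(pet_ref, 12))
  ## labelling is invariant to clamping rga
  labs0 <- label_lineages(toy_clamped(), orig_mu1())
  expect_identical(sort(labs0), sort(c("Sep", "Pet", "Car", "Sta", "Inf", "Mut")))
  ## a partition of an unrelated network cannot be labelled
  other <- random_network(3, 0.5, seed = 2)
  expect_error(label_lineages(enumerate_basins(other, mode_parallel(other)),
                              orig_mu1()), "subset")
})

test_that("merging basins by label unions members and adds sizes", {
  part <- toy_free()
  ## all-distinct labels: identity on sizes
  ident <- merge_basins(part, paste0("L", seq_along(part$attractors)))
  expect_identical(sort(tidy(ident)$size), sort(tidy(part)$size))
  ## lineage merge: 6 basins, sizes conserved
  labs <- label_lineages(part, orig_mu1())
  m <- toy_free_merged()
  expect_identical(length(m$attractors), 6L)
  expect_identical(sum(tidy(m)$size), 8192L)
  for (lab in unique(labs)) {
    expect_identical(
      sum(tidy(part)$size[labs == lab]),
      tidy(m)$size[m$labels == lab])
  }
  expect_error(merge_basins(part, labs[-1]), "label")
})

test_that("general iteration graph has out-multiplicity 2^n - 1 everywhere", {
  W <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  net <- tban(W, c(1, 1), nodes = c("a", "b"))
  gig <- general_iteration_graph(net)
  out_mult <- tapply(gig$multiplicity, gig$from, sum)
  expect_true(all(out_mult == 3))
  expect_error(general_iteration_graph(random_network(13, 0.2, seed = 3)),
               "refused")
})

test_that("the component iteration graphs show the parallel cycles are fragile", {
  ## {ap3, pi, bfu} component of the reduced network, context lfy = 0,
  ## ufo = 1, sup = 1 folded into the thresholds
  W <- matrix(0L, 3, 3, dimnames = rep(list(c("ap3", "pi", "bfu")), 2))
  W["bfu", "ap3"] <- 4L; W["bfu", "pi"] <- 4L
  W["ap3", "bfu"] <- 4L; W["pi", "bfu"] <- 4L
  triple <- tban(W, c(ap3 = 4, pi = 4, bfu = 8))
  gig <- general_iteration_graph(triple)
  expect_identical(length(unique(gig$from)), 8L)
  expect_true(all(tapply(gig$multiplicity, gig$from, sum) == 7))
  ## the parallel limit cycle is (1,1,0) <-> (0,0,1)
  part <- enumerate_basins(triple, mode_parallel(triple))
  cyc <- part$attractors[[which(tidy(part)$period == 2)]]$cycle
  expect_setequal(cyc, c(6, 1))     # codes of 110 and 001
  into <- sum(gig$multiplicity[!(gig$from %in% cyc) & gig$to %in% cyc])
  out_of <- sum(gig$multiplicity[gig$from %in% cyc & !(gig$to %in% cyc)])
  expect_lt(into, out_of)   # few arcs enter the cycle, most leave it

  ## {ap1, ag} component, context emf1 = tfl1 = 0, lfy = 0, lug = 1
  Wp <- matrix(c(0L, -2L, -2L, 0L), 2, 2,
               dimnames = rep(list(c("ap1", "ag")), 2))
  pair <- tban(Wp, c(ap1 = 0, ag = 0))
  gigp <- general_iteration_graph(pair)
  expect_identical(length(unique(gigp$from)), 4L)
  pairpart <- enumerate_basins(pair, mode_parallel(pair))
  expect_identical(sort(tidy(pairpart)$period), c(1L, 1L, 2L))
})

test_that("networks are classified by their behaviour across modes", {
  selfact <- tban(matrix(1L, 1, 1), 1, nodes = "a")
  all_modes <- list(mode_parallel(selfact))
  expect_identical(classify_network(selfact, all_modes)$class, "F")

  selfneg <- tban(matrix(-1L, 1, 1), 0, nodes = "a")
  expect_identical(classify_network(selfneg, list(mode_parallel(selfneg)))$class,
                   "C")

  orig <- mendoza_original()
  cl <- classify_network(orig, list(floral_modes(orig)$mu1, mode_parallel(orig)))
  expect_identical(cl$class, "E")
  expect_identical(cl$evidence$n_limit_cycles, c(0L, 7L))
  expect_error(classify_network(orig, list()), "non-empty")
})
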