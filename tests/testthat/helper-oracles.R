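## Independent brute-force oracles, kept deliberately naive: they never
## share code paths with the implementations they check.

## per-configuration trajectory walk (no memoisation, no vectorisation)
naive_basins <- function(net, mode) {
  n <- length(net$nodes)
  fs_codes <- basingauge:::free_space(net)$codes
  key <- function(x) paste(x, collapse = "")
  attractors <- list()
  assignment <- character(length(fs_codes))
  for (k in seq_along(fs_codes)) {
    x <- as_config(fs_codes[k], net)
    seen <- list()
    repeat {
      kk <- key(x)
      if (!is.null(seen[[kk]])) break
      seen[[kk]] <- length(seen)
      x <- step_mode(net, x, mode)
    }
    ## x is on the cycle; walk once around it to collect it
    cyc <- numeric(0)
    y <- x
    repeat {
      cyc <- c(cyc, config_code(y))
      y <- step_mode(net, y, mode)
      if (identical(unname(y), unname(x))) break
    }
    id <- paste(sort(cyc), collapse = "/")
    attractors[[id]] <- sort(cyc)
    assignment[k] <- id
  }
  list(attractors = attractors, assignment = assignment, codes = fs_codes)
}

## doubly-nested exhaustive modified-Hausdorff distance on bit strings
naive_relative_distance <- function(A, B) {
  total <- 0
  for (a in A) {
    best <- Inf
    for (b in B) {
      d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / length(A)
}

## explicit double loop over origin x target for passage counts
naive_passage_counts <- function(origin_codes, target_codes, n) {
  counts <- numeric(n + 1)
  for (x in origin_codes) for (y in target_codes) {
    d <- sum(config_states(bitwXor(x, y), n))
    counts[d + 1] <- counts[d + 1] + 1
  }
  counts
}

## shortest-path lengths by boolean adjacency powers (BFS oracle)
naive_eccentricity <- function(net) {
  A <- net$W != 0
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  for (k in seq_len(n)) {
    reach_next <- reach %*% A > 0
    newly <- reach_next & !reach & (D == Inf)
    D[newly] <- k
    reach <- reach | reach_next
  }
  apply(D, 1, max)
}

## random block-sequential mode over the free nodes
random_mode <- function(net) {
  free <- sample(free_nodes(net))
  cuts <- sort(unique(c(0, which(stats::runif(length(free) - 1) < 0.5),
                        length(free))))
  blocks <- lapply(seq_len(length(cuts) - 1), function(i)
    free[(cuts[i] + 1):cuts[i + 1]])
  iteration_mode(net, blocks)
}
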