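#' Trajectory of a configuration
#'
#' Iterates the deterministic flow from `x0` until a configuration repeats
#' (the trajectory has entered its attractor) or `max_steps` macro steps
#' have been taken.  A macro step is one full pass over all blocks of the
#' iteration mode.  Because the configuration space is finite the
#' trajectory provably repeats within `2^n_free` steps.
#'
#' @param net A [tban()] network.
#' @param x0 Initial configuration (see [as_config()]).
#' @param mode An [iteration_mode()].
#' @param max_steps Maximum number of macro steps; defaults to the provable
#'   bound `2^n_free`.
#' @return A tibble with columns `step`, `configuration` (bit string) and
#'   `code`.
#' @examples
#' net <- toy_model()
#' trajectory(net, "1111111111111", mode_sequential(net))
#' @export
trajectory <- function(net, x0, mode, max_steps = NULL) {
  stopifnot(is_tban(net))
  if (!inherits(mode, "iteration_mode")) mode <- iteration_mode(net, mode)
  nf <- length(free_nodes(net))
  if (is.null(max_steps)) max_steps <- 2^nf
  if (max_steps < 1) stop("`max_steps` must be at least 1", call. = FALSE)
  x <- as_config(x0, net)
  seen <- new.env(hash = TRUE)
  out_codes <- numeric(0)
  step <- 0L
  repeat {
    code <- config_code(x)
    out_codes <- c(out_codes, code)
    key <- format(code, scientific = FALSE)
    if (!is.null(seen[[key]]) || step >= max_steps) break
    seen[[key]] <- step
    x <- step_mode(net, x, mode)
    step <- step + 1L
  }
  n <- length(net$nodes)
  tibble::tibble(
    step = seq_along(out_codes) - 1L,
    configuration = vapply(out_codes, function(cc)
      config_string(config_states(cc, n)), character(1)),
    code = out_codes
  )
}

#' Attractor reached from a configuration
#'
#' Follows the trajectory of `x0` to its first repeated configuration and
#' extracts the cycle.  The transient length is the number of macro steps
#' taken before entering the cycle.
#'
#' @inheritParams trajectory
#' @return A list with components `attractor` (an object of class
#'   `"tban_attractor"`: canonical cycle of configuration codes and its
#'   period) and `transient` (integer).
#' @export
find_attractor <- function(net, x0, mode) {
  tr <- trajectory(net, x0, mode)
  codes <- tr$code
  last <- codes[length(codes)]
  first_hit <- match(last, codes)
  cyc <- codes[first_hit:(length(codes) - 1L)]
  list(
    attractor = new_attractor(cyc, length(net$nodes)),
    transient = first_hit - 1L
  )
}

## canonical rotation: lexicographically smallest code first
new_attractor <- function(cycle_codes, n) {
  k <- which.min(cycle_codes)
  cyc <- c(cycle_codes[k:length(cycle_codes)],
           cycle_codes[seq_len(k - 1L)])
  structure(list(cycle = cyc, period = length(cyc), n = n),
            class = "tban_attractor")
}

#' @export
print.tban_attractor <- function(x, ...) {
  strs <- vapply(x$cycle, function(cc) config_string(config_states(cc, x$n)),
                 character(1))
  if (x$period == 1)
    cat("Fixed point: ", strs, "\n", sep = "")
  else
    cat("Limit cycle (period ", x$period, "): ",
        paste(strs, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

attractor_key <- function(a) paste(a$cycle, collapse = "/")

#' Exhaustive attraction-basin partition
#'
#' Runs every configuration of the free space (all `2^n_free` of them) to
#' its attractor and returns the complete partition of the space into
#' attraction basins.  The sweep computes the successor of every
#' configuration once (a vectorised macro step over the whole space) and
#' then resolves the functional graph, so it is linear in the number of
#' configurations.  Enumeration is refused above `2^24` states.
#'
#' @inheritParams trajectory
#' @return An object of class `"basin_partition"`: a list with elements
#'   `net`, `mode`, `attractors` (list of attractors, canonical order),
#'   `labels` (character, one per attractor; defaults to `A1, A2, ...`),
#'   `codes` (configuration codes of the free space) and `basin` (integer
#'   attractor index per code).  Use [tidy()][tidy.basin_partition()] for a
#'   per-basin summary and [basin_configs()] for the members of one basin.
#' @examples
#' part <- enumerate_basins(mendoza_original(), mode_sequential(mendoza_original()))
#' glance(part)
#' @export
enumerate_basins <- function(net, mode) {
  stopifnot(is_tban(net))
  if (!inherits(mode, "iteration_mode")) mode <- iteration_mode(net, mode)
  fs <- free_space(net)
  succ_codes <- as.vector(step_all(net, fs$S, mode) %*%
                            2^((length(net$nodes) - 1):0))
  ## map full codes -> position in the free-space enumeration
  pos <- code_lookup(fs$codes)
  succ <- pos(succ_codes)
  N <- length(fs$codes)
  colour <- integer(N)        # 0 unvisited, 1 on current path, 2 resolved
  basin <- integer(N)
  attractors <- list()
  for (s0 in seq_len(N)) {
    if (colour[s0] == 2L) next
    path <- integer(0)
    v <- s0
    while (colour[v] == 0L) {
      colour[v] <- 1L
      path <- c(path, v)
      v <- succ[v]
    }
    if (colour[v] == 1L) {
      ## fresh cycle discovered on this path
      k <- match(v, path)
      cyc <- path[k:length(path)]
      attractors[[length(attractors) + 1L]] <-
        new_attractor(fs$codes[cyc], length(net$nodes))
      aid <- length(attractors)
    } else {
      aid <- basin[v]
    }
    basin[path] <- aid
    colour[path] <- 2L
  }
  ## canonical attractor order: by smallest cycle code
  ord <- order(vapply(attractors, function(a) a$cycle[1], numeric(1)))
  relabel <- integer(length(attractors))
  relabel[ord] <- seq_along(ord)
  structure(
    list(net = net, mode = mode,
         attractors = attractors[ord],
         labels = paste0("A", seq_along(ord)),
         codes = fs$codes,
         basin = relabel[basin],
         attractor_members = NULL),
    class = "basin_partition"
  )
}

## closure mapping full configuration codes to positions in `codes`
code_lookup <- function(codes) {
  o <- order(codes)
  sorted <- codes[o]
  function(x) o[findInterval(x, sorted)]
}

#' @export
print.basin_partition <- function(x, ...) {
  k <- length(x$attractors)
  periods <- vapply(x$attractors, function(a) a$period, integer(1))
  cat("Basin partition: ", length(x$codes), " configurations, ",
      k, " attractors (", sum(periods == 1), " fixed points, ",
      sum(periods > 1), " limit cycles)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a basin partition
#'
#' @param x A [enumerate_basins()] partition.
#' @param ... Unused.
#' @return One row per basin: `basin` (label), `period`, `size`,
#'   `relative_size` (exact, `size / 2^n_free`) and `attractor` (bit string
#'   of the cycle's first configuration).
#' @importFrom generics tidy
#' @export
tidy.basin_partition <- function(x, ...) {
  n <- length(x$net$nodes)
  sizes <- tabulate(x$basin, length(x$attractors))
  tibble::tibble(
    basin = x$labels,
    period = vapply(x$attractors, function(a) a$period, integer(1)),
    size = sizes,
    relative_size = sizes / length(x$codes),
    attractor = vapply(x$attractors, function(a)
      config_string(config_states(a$cycle[1], n)), character(1))
  )
}

#' @rdname tidy.basin_partition
#' @importFrom generics glance
#' @export
glance.basin_partition <- function(x, ...) {
  periods <- vapply(x$attractors, function(a) a$period, integer(1))
  tibble::tibble(
    n_configurations = length(x$codes),
    n_free_nodes = length(free_nodes(x$net)),
    n_attractors = length(x$attractors),
    n_fixed_points = sum(periods == 1),
    n_limit_cycles = sum(periods > 1),
    max_period = max(periods)
  )
}

#' Members of one basin
#'
#' @param partition A basin partition.
#' @param basin Basin label (or index).
#' @param as What to return: configuration codes or bit strings.
#' @return Vector of configurations in the basin.
#' @export
basin_configs <- function(partition, basin, as = c("code", "string")) {
  as <- match.arg(as)
  i <- if (is.character(basin)) match(basin, partition$labels) else basin
  if (is.na(i)) stop("unknown basin `", basin, "`", call. = FALSE)
  codes <- partition$codes[partition$basin == i]
  if (as == "code") return(codes)
  n <- length(partition$net$nodes)
  vapply(codes, function(cc) config_string(config_states(cc, n)), character(1))
}

## configuration codes belonging to the attractor cycles of one basin
attractor_configs <- function(partition, i) {
  if (!is.null(partition$attractor_members)) return(partition$attractor_members[[i]])
  partition$attractors[[i]]$cycle
}

#' Merge basins that share a label
#'
#' Basins whose attractors carry equal tags are unioned; sizes add.  The
#' merged partition keeps, for each merged basin, the set of configurations
#' belonging to any member attractor (used by the attractor-restricted
#' passage variant).
#'
#' @param partition A basin partition.
#' @param labels Character vector, one tag per attractor (in partition
#'   order), or a named vector keyed by current basin labels.
#' @return A new `basin_partition` whose basins are the label groups.
#' @export
merge_basins <- function(partition, labels) {
  if (!is.null(names(labels))) labels <- labels[partition$labels]
  labels <- as.character(labels)
  if (length(labels) != length(partition$attractors) || anyNA(labels))
    stop("every attractor needs a label", call. = FALSE)
  groups <- unique(labels)
  map <- match(labels, groups)
  members <- lapply(seq_along(groups), function(g) {
    unlist(lapply(which(map == g), function(i) attractor_configs(partition, i)))
  })
  ## representative attractor per group: the one with the smallest cycle code
  rep_attr <- lapply(seq_along(groups), function(g) {
    cand <- partition$attractors[map == g]
    cand[[which.min(vapply(cand, function(a) a$cycle[1], numeric(1)))]]
  })
  structure(
    list(net = partition$net, mode = partition$mode,
         attractors = rep_attr,
         labels = groups,
         codes = partition$codes,
         basin = map[partition$basin],
         attractor_members = members),
    class = "basin_partition"
  )
}

#' General iteration graph
#'
#' The general iteration graph of a network has one vertex per
#' configuration and, for every configuration `x` and every non-empty
#' subset `S` of the free nodes, an arc from `x` to the configuration
#' obtained by updating all nodes of `S` synchronously.  Arcs with equal
#' endpoints are collapsed and labelled with their multiplicity, so the
#' total out-multiplicity of every vertex is `2^n_free - 1`.  It
#' generalises the iteration graphs of all block-sequential modes and is
#' used to argue that some parallel-mode limit cycles are dynamically
#' unlikely: few arcs enter them and most arcs leave them.
#'
#' @param net A [tban()] network (at most 12 free nodes).
#' @return A tibble with columns `from`, `to` (configuration codes) and
#'   `multiplicity`, with the configuration codes of the space in attribute
#'   `"codes"`.
#' @export
general_iteration_graph <- function(net) {
  stopifnot(is_tban(net))
  free <- free_nodes(net)
  nf <- length(free)
  if (nf > 12)
    stop("general iteration graph is refused above 12 free nodes ",
         "(2^n * (2^n - 1) arc slots)", call. = FALSE)
  fs <- free_space(net)
  pow <- 2^((length(net$nodes) - 1):0)
  acc <- vector("list", 2^nf - 1)
  for (s in seq_len(2^nf - 1)) {
    block <- free[bitwAnd(s %/% 2^(seq_len(nf) - 1), 1L) == 1L]
    to <- as.vector(step_all(net, fs$S, list(block)) %*% pow)
    acc[[s]] <- tibble::tibble(from = fs$codes, to = to)
  }
  edges <- dplyr::count(dplyr::bind_rows(acc), .data$from, .data$to,
                        name = "multiplicity")
  attr(edges, "codes") <- fs$codes
  edges
}

#' Classify a network by its asymptotic behaviour across iteration modes
#'
#' Networks are grouped by how their attractor types react to a change of
#' iteration mode: class `F` if every tested mode yields only fixed points,
#' `C` if every mode yields only limit cycles, `B` if every mode yields
#' both at least one fixed point and at least one limit cycle, and `E` if
#' some modes yield only fixed points while others yield a mixture (the
#' most mode-sensitive networks).  A combination matching none of the four
#' definitions is reported as `"unclassified"` rather than silently
#' guessed.  The full set of block-sequential modes grows as the ordered
#' Bell numbers, so the classification is always relative to the explicit
#' mode collection supplied.
#'
#' @param net A [tban()] network.
#' @param modes Non-empty list of [iteration_mode()]s (or block lists).
#' @return A list with `class` (one of `"F"`, `"C"`, `"B"`, `"E"`,
#'   `"unclassified"`) and `evidence`, a tibble with one row per mode
#'   giving its fixed-point and limit-cycle counts.
#' @export
classify_network <- function(net, modes) {
  if (length(modes) == 0) stop("`modes` must be non-empty", call. = FALSE)
  ev <- purrr::map_dfr(seq_along(modes), function(k) {
    g <- glance(enumerate_basins(net, modes[[k]]))
    tibble::tibble(mode = k, n_fixed_points = g$n_fixed_points,
                   n_limit_cycles = g$n_limit_cycles)
  })
  status <- dplyr::case_when(
    ev$n_fixed_points > 0 & ev$n_limit_cycles == 0 ~ "fp",
    ev$n_fixed_points == 0 & ev$n_limit_cycles > 0 ~ "cyc",
    TRUE ~ "mixed"
  )
  cls <- if (all(status == "fp")) "F"
  else if (all(status == "cyc")) "C"
  else if (all(status == "mixed")) "B"
  else if (all(status %in% c("fp", "mixed"))) "E"
  else "unclassified"
  list(class = cls, evidence = ev)
}
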