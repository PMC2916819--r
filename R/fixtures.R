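## Built-in floral-morphogenesis networks.
##
## The weight matrices below are the package's transcription of the
## Mendoza & Alvarez-Buylla threshold Boolean model of Arabidopsis
## thaliana flower morphogenesis (Mendoza & Alvarez-Buylla, J. Theor.
## Biol. 193:307-319, 1998), its reduced (two-symmetric-component) form,
## and a gibberellin-sensitive extension carrying the boundary gene rga.
## The transcription is validated dynamically by the test suite: six fixed
## points under sequential and block-sequential schedules, the same six
## plus seven period-2 limit cycles under the parallel schedule, eight
## fixed points for the rga extension, and the exact 3/4 : 1/4 split of
## rga-active configurations between the sepal and inflorescence basins.
## Any edit here must keep those facts intact.

floral_genes <- c("emf1", "tfl1", "lfy", "ap1", "cal", "lug", "ufo",
                  "bfu", "ag", "ap3", "pi", "sup")

floral_arcs <- function() {
  ## from, to, weight; one row per arc of the original network
  list(
    ## emf1: self-sustaining master repressor of flowering
    c("emf1", "emf1", 1),
    ## tfl1: maintained by emf1, shut down by lfy
    c("emf1", "tfl1", 1), c("lfy", "tfl1", -1),
    ## lfy: repressed by emf1/tfl1, promoted by ap1/cal; its potential
    ## never reaches the threshold, so lfy switches off at its first
    ## update and stays off (the release mechanism)
    c("emf1", "lfy", -2), c("tfl1", "lfy", -1),
    c("ap1", "lfy", 1), c("cal", "lfy", 1),
    ## ap1: A-function gene, mutually exclusive with ag
    c("emf1", "ap1", -1), c("lfy", "ap1", 2), c("ag", "ap1", -1),
    ## cal: driven by lfy alone
    c("lfy", "cal", 1),
    ## bfu: the AP3/PI heterodimer, present when both subunits are
    c("ap3", "bfu", 1), c("pi", "bfu", 1),
    ## ag: C-function gene, opposed by ap1/tfl1/lug
    c("tfl1", "ag", -2), c("lfy", "ag", 1),
    c("ap1", "ag", -2), c("lug", "ag", -2),
    ## ap3 and pi: B-function genes sustained by the dimer, helped by
    ## ufo and lfy, opposed by sup; the active state sits exactly at
    ## threshold, so one extra unit of repression extinguishes it
    c("lfy", "ap3", 3), c("ufo", "ap3", 2),
    c("bfu", "ap3", 4), c("sup", "ap3", -2),
    c("lfy", "pi", 4), c("ufo", "pi", 1),
    c("bfu", "pi", 4), c("sup", "pi", -1)
  )
}

floral_thresholds <- c(emf1 = 1, tfl1 = 1, lfy = 3, ap1 = 0, cal = 1,
                       lug = -1, ufo = -1, bfu = 2, ag = -2, ap3 = 4,
                       pi = 4, sup = -1)

arcs_to_matrix <- function(arcs, nodes) {
  W <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (a in arcs) W[a[1], a[2]] <- as.integer(a[3])
  W
}

#' Built-in floral-morphogenesis networks
#'
#' `mendoza_original()` returns the 12-gene threshold Boolean network of
#' Arabidopsis thaliana flower morphogenesis (genes emf1, tfl1, lfy, ap1,
#' cal, lug, ufo, bfu, ag, ap3, pi, sup, in that fixed order).  Its six
#' fixed points correspond to the sepal, petal, carpel, stamen,
#' inflorescence and "mutant" cell types.
#'
#' `mendoza_reduced()` returns an arc-reduced network with the same
#' attractor sets whose dynamics is governed by two non-trivial strongly
#' connected *symmetric* components, `{ap1, ag}` and `{ap3, pi, bfu}` --
#' the structure that bounds attractor periods by 2 under any
#' block-sequential mode and by 1 under sequential modes.
#'
#' `toy_model()` returns the 13-node gibberellin-sensitive extension: the
#' original network plus three minimal inhibitions (lfy -| emf1,
#' ap1 -| tfl1, tfl1 -| ap1) and the boundary gene rga with arcs
#' rga -| ag, rga -| ap3, rga -| pi and a self-activation rga -> rga, all
#' of absolute weight 1.  Gibberellin represses rga, so the presence of
#' the hormone is modelled by `clamp(toy_model(), "rga", 0)`; in its
#' absence rga is bistable through its self-loop and the free space
#' doubles.
#'
#' @return A [tban()] network.
#' @examples
#' glance(enumerate_basins(mendoza_original(), mode_sequential(mendoza_original())))
#' @export
mendoza_original <- function() {
  tban(arcs_to_matrix(floral_arcs(), floral_genes),
       floral_thresholds[floral_genes], nodes = floral_genes)
}

#' @rdname mendoza_original
#' @export
mendoza_reduced <- function() {
  arcs <- floral_arcs()
  keep <- vapply(arcs, function(a)
    !(a[1] == "lfy" && a[2] == "tfl1") &&   # cut the lfy/tfl1 feedback
    !(a[1] == "ap1" && a[2] == "lfy") &&    # cut the pair's back-arcs into lfy
    !(a[1] == "cal" && a[2] == "lfy"),
    logical(1))
  arcs <- arcs[keep]
  ## rescale the ap1 row (x2) and the bfu row (x4) so the two governing
  ## components become weight-symmetric without changing any local rule
  rescale <- list(c("emf1", "ap1", -2), c("lfy", "ap1", 4), c("ag", "ap1", -2),
                  c("ap3", "bfu", 4), c("pi", "bfu", 4))
  arcs <- Filter(function(a) !(a[2] %in% c("ap1", "bfu")), arcs)
  th <- floral_thresholds
  th["ap1"] <- 2L * th["ap1"]
  th["bfu"] <- 4L * th["bfu"]
  tban(arcs_to_matrix(c(arcs, rescale), floral_genes),
       th[floral_genes], nodes = floral_genes)
}

#' @rdname mendoza_original
#' @export
toy_model <- function() {
  genes <- c(floral_genes, "rga")
  extra <- list(
    c("lfy", "emf1", -1), c("ap1", "tfl1", -1), c("tfl1", "ap1", -1),
    c("rga", "ag", -1), c("rga", "ap3", -1), c("rga", "pi", -1),
    c("rga", "rga", 1)
  )
  th <- c(floral_thresholds, rga = 1)
  tban(arcs_to_matrix(c(floral_arcs(), extra), genes),
       th[genes], nodes = genes)
}

#' The two update schedules of the floral case study
#'
#' Returns the sequential mode `mu1` (one singleton block per gene, in the
#' canonical gene order, rga last for the 13-node network) and the
#' block-sequential mode `mu2` historically used for the original network:
#' `({emf1, tfl1}, {lfy, ap1, cal}, {lug, ufo, bfu}, {ag, ap3, pi},
#' {sup})`, with `{rga}` appended as a final block when the network
#' carries rga.
#'
#' @param net One of the floral fixture networks (any clamp state).
#' @return Named list of two [iteration_mode()]s, `mu1` and `mu2`.
#' @export
floral_modes <- function(net) {
  stopifnot(is_tban(net))
  free <- net$nodes[free_nodes(net)]
  blocks2 <- list(c("emf1", "tfl1"), c("lfy", "ap1", "cal"),
                  c("lug", "ufo", "bfu"), c("ag", "ap3", "pi"), "sup")
  if ("rga" %in% free) blocks2 <- c(blocks2, list("rga"))
  blocks2 <- lapply(blocks2, intersect, free)
  blocks2 <- blocks2[lengths(blocks2) > 0]
  list(
    mu1 = mode_sequential(net),
    mu2 = iteration_mode(net, blocks2)
  )
}

#' Cell-lineage labels for floral fixed points
#'
#' Assigns each fixed point of a floral-network partition to one of the
#' six cell lineages by its gene states, following the A/B/C reading of
#' the model: `Inf`/`Mut` when emf1 is active (inflorescence meristem,
#' with `Mut` when the B-dimer is also on), `Sep`/`Pet` when ap1 (A
#' function) is active, `Car`/`Sta` when ag (C function) is active -- the
#' B genes (ap3/pi) separating Sep from Pet and Car from Sta.
#'
#' @param partition A basin partition of one of the floral networks whose
#'   attractors are all fixed points.
#' @return Character vector of labels (`Sep`, `Pet`, `Car`, `Sta`, `Inf`,
#'   `Mut`), one per attractor.
#' @export
lineage_labels <- function(partition) {
  net <- partition$net
  need <- c("emf1", "ap1", "ag", "ap3", "pi")
  if (!all(need %in% net$nodes))
    stop("not a floral network partition", call. = FALSE)
  vapply(partition$attractors, function(a) {
    if (a$period != 1)
      stop("lineage labels are defined for fixed points only", call. = FALSE)
    s <- stats::setNames(config_states(a$cycle[1], length(net$nodes)),
                         net$nodes)
    b_on <- s["ap3"] == 1 && s["pi"] == 1
    if (s["emf1"] == 1) { if (b_on) "Mut" else "Inf" }
    else if (s["ap1"] == 1) { if (b_on) "Pet" else "Sep" }
    else if (s["ag"] == 1) { if (b_on) "Sta" else "Car" }
    else stop("fixed point matches no lineage pattern", call. = FALSE)
  }, character(1))
}

#' Label toy-model fixed points by their 12-gene lineage
#'
#' Each fixed point of the 13-node gibberellin network is labelled by the
#' lineage of the original-network fixed point equal to its 12-gene
#' projection (dropping rga).  The labelling is well defined because the
#' six cell lineages are independent of the rga state; a projection that
#' matches no original fixed point signals a fixture transcription bug and
#' raises an error.
#'
#' @param partition A basin partition of [toy_model()] (any clamp state)
#'   whose attractors are fixed points.
#' @param reference A basin partition of [mendoza_original()] supplying
#'   the reference fixed points.
#' @return Character vector of lineage labels, one per attractor of
#'   `partition`, suitable for [merge_basins()].
#' @export
label_lineages <- function(partition, reference) {
  toy_nodes <- partition$net$nodes
  ref_nodes <- reference$net$nodes
  keep <- match(ref_nodes, toy_nodes)
  if (anyNA(keep))
    stop("reference nodes are not a subset of the partition's nodes",
         call. = FALSE)
  ref_labels <- lineage_labels(reference)
  ref_strings <- vapply(reference$attractors, function(a)
    config_string(config_states(a$cycle[1], length(ref_nodes))), character(1))
  vapply(partition$attractors, function(a) {
    if (a$period != 1)
      stop("lineage labelling needs fixed points", call. = FALSE)
    s <- config_states(a$cycle[1], length(toy_nodes))[keep]
    hit <- match(config_string(s), ref_strings)
    if (is.na(hit))
      stop("projected fixed point ", config_string(s),
           " matches no reference fixed point (fixture transcription bug?)",
           call. = FALSE)
    ref_labels[hit]
  }, character(1))
}

#' Random threshold Boolean automata networks
#'
#' Generates reproducible random networks for property testing: each
#' ordered node pair receives an arc with probability `arc_density`, with
#' a non-zero integer weight drawn uniformly from `weight_range`;
#' thresholds are drawn uniformly from `threshold_range`.  The `symmetric`
#' flag forces `w[i, j] == w[j, i]` (arcs are drawn on unordered pairs);
#' `nonneg_diagonal` forces `w[i, i] >= 0` -- together these are the
#' hypotheses under which attractor periods are bounded by 2 (any
#' block-sequential mode) and equal 1 (sequential modes).
#'
#' @param n Number of nodes.
#' @param arc_density Probability of an arc, in `[0, 1]`.
#' @param weight_range,threshold_range Integer ranges `c(lo, hi)`.
#' @param symmetric,nonneg_diagonal Structural flags (see above).
#' @param seed Optional integer seed.
#' @return A [tban()] network.
#' @export
random_network <- function(n, arc_density = 0.4, weight_range = c(-2, 2),
                           threshold_range = c(-1, 2), symmetric = FALSE,
                           nonneg_diagonal = FALSE, seed = NULL) {
  if (arc_density < 0 || arc_density > 1)
    stop("`arc_density` must lie in [0, 1]", call. = FALSE)
  if (weight_range[1] > weight_range[2] ||
      threshold_range[1] > threshold_range[2])
    stop("invalid range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  weights <- setdiff(seq(weight_range[1], weight_range[2]), 0)
  if (length(weights) == 0) stop("weight range contains no non-zero integer",
                                 call. = FALSE)
  W <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    jmax <- if (symmetric) i else n
    for (j in seq_len(jmax)) {
      if (stats::runif(1) < arc_density) {
        w <- sample(weights, 1)
        W[i, j] <- w
        if (symmetric) W[j, i] <- w
      }
    }
  }
  if (nonneg_diagonal) diag(W) <- abs(diag(W))
  theta <- sample(seq(threshold_range[1], threshold_range[2]), n,
                  replace = TRUE)
  tban(W, theta, nodes = paste0("v", seq_len(n)))
}

#' The gibberellin experiment
#'
#' Runs the full boundary-condition comparison on the 13-node floral
#' network under the sequential schedule: basins are enumerated with rga
#' free (no gibberellin) and with rga clamped to 0 (hormone present),
#' fixed points are merged by cell lineage (six basins in both regimes),
#' and the three gauges are computed for both regimes -- merged basin
#' sizes, the 6 x 6 relative-distance matrices, the distance
#' distributions from the sepal and inflorescence basins to every other
#' basin, and the 6 x 6 passage-polynomial matrices.
#'
#' @param passage Also compute the (more expensive) passage matrices.
#' @param dir Optional directory; when given, the tables are written there
#'   as CSV files and the passage polynomials as JSON.
#' @return A list with elements `partitions` (free/clamped merged
#'   partitions), `sizes`, `distances`, `distributions`, and (when
#'   `passage = TRUE`) `passage_free`, `passage_clamped`.
#' @export
run_gibberellin_experiment <- function(passage = TRUE, dir = NULL) {
  toy <- toy_model()
  free_part <- enumerate_basins(toy, floral_modes(toy)$mu1)
  clamped_net <- clamp(toy_model(), "rga", 0)
  clamped_part <- enumerate_basins(clamped_net, floral_modes(clamped_net)$mu1)
  orig_part <- enumerate_basins(mendoza_original(),
                                floral_modes(mendoza_original())$mu1)
  free_m <- merge_basins(free_part, label_lineages(free_part, orig_part))
  clamped_m <- merge_basins(clamped_part,
                            label_lineages(clamped_part, orig_part))

  sizes <- dplyr::bind_rows(
    dplyr::mutate(basin_sizes(free_m), regime = "rga free", .before = 1),
    dplyr::mutate(basin_sizes(clamped_m), regime = "rga = 0", .before = 1)
  )
  distances <- dplyr::bind_rows(
    dplyr::mutate(relative_distance_matrix(free_m), regime = "rga free",
                  .before = 1),
    dplyr::mutate(relative_distance_matrix(clamped_m), regime = "rga = 0",
                  .before = 1)
  )
  distributions <- purrr::map_dfr(c("Sep", "Inf"), function(o) {
    purrr::map_dfr(list(free = free_m, clamped = clamped_m), function(pt) {
      targets <- setdiff(pt$labels, o)
      purrr::map_dfr(targets, function(t)
        dplyr::mutate(
          distance_distribution(basin_configs(pt, o), basin_configs(pt, t),
                                n_bits = length(pt$net$nodes)),
          origin = o, target = t, .before = 1))
    }, .id = "regime")
  })
  out <- list(partitions = list(free = free_m, clamped = clamped_m),
              sizes = sizes, distances = distances,
              distributions = distributions)
  if (passage) {
    out$passage_free <- passage_matrix(free_m)
    out$passage_clamped <- passage_matrix(clamped_m)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sizes, file.path(dir, "basin_sizes.csv"),
                     row.names = FALSE)
    utils::write.csv(distances, file.path(dir, "relative_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(distributions,
                     file.path(dir, "distance_distributions.csv"),
                     row.names = FALSE)
    if (passage) {
      for (nm in c("passage_free", "passage_clamped")) {
        polys <- purrr::pmap(out[[nm]], function(origin, target, poly)
          list(origin = origin, target = target, n = poly$n,
               origin_size = poly$origin_size, raw_counts = poly$raw_counts))
        jsonlite::write_json(polys, file.path(dir, paste0(nm, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  out
}
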