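## Shared, lazily computed fixture partitions (the exhaustive sweeps and
## passage matrices are the expensive part of the suite; compute each once).
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- expr
  .cache[[name]]
}

orig_mu1 <- function() cached("orig_mu1", {
  net <- mendoza_original()
  enumerate_basins(net, floral_modes(net)$mu1)
})
orig_mu2 <- function() cached("orig_mu2", {
  net <- mendoza_original()
  enumerate_basins(net, floral_modes(net)$mu2)
})
orig_par <- function() cached("orig_par", {
  net <- mendoza_original()
  enumerate_basins(net, mode_parallel(net))
})
toy_free <- function() cached("toy_free", {
  net <- toy_model()
  enumerate_basins(net, floral_modes(net)$mu1)
})
toy_clamped <- function() cached("toy_clamped", {
  net <- clamp(toy_model(), "rga", 0)
  enumerate_basins(net, floral_modes(net)$mu1)
})
toy_free_merged <- function() cached("toy_free_merged",
  merge_basins(toy_free(), label_lineages(toy_free(), orig_mu1())))
toy_clamped_merged <- function() cached("toy_clamped_merged",
  merge_basins(toy_clamped(), label_lineages(toy_clamped(), orig_mu1())))
passage_free <- function() cached("passage_free",
  passage_matrix(toy_free_merged()))
passage_clamped <- function() cached("passage_clamped",
  passage_matrix(toy_clamped_merged()))

get_poly <- function(pm, origin, target)
  pm$poly[[which(pm$origin == origin & pm$target == target)]]

merged_sizes <- function(pm) {
  s <- basin_sizes(pm)
  stats::setNames(s$size, s$basin)
}

## basin sizes of an original-network partition, keyed by cell lineage
merged_sizes_of <- function(part) {
  labs <- lineage_labels(part)
  vapply(split(tidy(part)$size, labs), sum, numeric(1))
}
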