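# Simulation runs are expensive; cache them per session so several test
# files can assert on the same run.

.run_cache <- new.env(parent = emptyenv())

mini_run <- function(mode, seed, max_cells = 130, shape = "depression") {
  key <- paste(mode, seed, max_cells, shape, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_simulation(
      run_config(mode = mode, seed = seed, max_cells = max_cells,
                 shape = shape))
  }
  .run_cache[[key]]
}

# phenotype-scale runs (the two preset experiments)
pheno_run <- function(mode, seed, shape = "depression") {
  mini_run(mode, seed, max_cells = 400, shape = shape)
}

# central hexagon surrounded by a full ring of six hexagons; returns the
# tissue plus the id of the central cell
hex_with_ring <- function() {
  r <- sqrt(2 / (3 * sqrt(3)))
  h <- pitchersim:::hex_lattice(3 * r, r)
  keep <- sqrt(h$cx^2 + h$cy^2) < 1.9 * r
  tis <- pitchersim:::hexes_to_tissue(h, keep, r)
  cen <- t(vapply(tis$cells, function(cyc) {
    colMeans(tis$vertices[cyc, , drop = FALSE])
  }, numeric(2)))
  classify_layers(tis)
  list(tissue = classify_layers(tis),
       centre = which.min(rowSums(cen^2)))
}
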