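test_that("cell geometry matches closed forms", {
  sq <- unit_square()
  g <- cell_geometry(sq, 1)
  expect_equal(g$area, 1)
  expect_equal(g$centre, c(0.5, 0.5))
  expect_equal(g$edge_lengths, rep(1, 4))

  hexa <- ngon_tissue(6, rad = 1)
  expect_equal(cell_geometry(hexa, 1)$area, 3 * sqrt(3) / 2, tolerance = 1e-12)

  tri <- leaf_tissue(rbind(c(0, 0), c(2, 0), c(0, 2)), list(1:3))
  g <- cell_geometry(tri, 1)
  expect_equal(g$area, 2)
  expect_equal(g$centre, c(2 / 3, 2 / 3))
})

test_that("clockwise input cycles are normalized to counter-clockwise", {
  tis <- leaf_tissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(4:1))
  expect_gt(pitchersim:::polygon_area(tis$vertices[tis$cells[[1]], ]), 0)
})

test_that("degenerate polygons are rejected", {
  expect_error(leaf_tissue(rbind(c(0, 0), c(1, 0)), list(1:2)), "3 vertices")
  bowtie <- leaf_tissue(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), list(1:4))
  expect_error(cell_geometry(bowtie, 1), "degenerate")
})

test_that("layer classification works on simple fixtures", {
  # every cell of a thin strip touches the boundary
  st <- classify_layers(strip_tissue(3))
  expect_true(all(st$states$layer == "L1"))

  # five-layer onion (12 core wedges + 4 rings of 12): L1, L2, L3, inner,
  # inner from outside in
  on <- onion_tissue(5, 12)
  expect_true(all(on$states$layer[49:60] == "L1"))   # outermost ring
  expect_true(all(on$states$layer[37:48] == "L2"))
  expect_true(all(on$states$layer[25:36] == "L3"))
  expect_true(all(on$states$layer[1:24] == "inner")) # core + ring 2
})

test_that("classification is idempotent and permutation invariant", {
  tis <- default_mesh()
  tis2 <- classify_layers(tis)
  expect_identical(tis$states$layer, tis2$states$layer)
  expect_identical(tis$states$side, tis2$states$side)

  # permute vertex indices; labels must not change
  nv <- nrow(tis$vertices)
  set.seed(7)
  perm <- sample(nv)
  inv <- order(perm)
  tis3 <- leaf_tissue(tis$vertices[perm, , drop = FALSE],
                      lapply(tis$cells, function(cyc) inv[cyc]),
                      tis$states)
  tis3 <- classify_layers(tis3)
  expect_identical(tis3$states$layer, tis$states$layer)
  expect_identical(tis3$states$side, tis$states$side)
})

test_that("boundary source cells flank the identity junctions", {
  # ring of 10 epidermal cells, cells 1-3 adaxial: both junction-flanking
  # cells on each side are sources
  ids <- c(rep("adaxial", 3), rep("abaxial", 7))
  tis <- wedge_disc(10, ids)
  expect_equal(boundary_source_cells(tis), c(1, 3, 4, 10))

  # single adaxial cell: itself plus both neighbours
  ids <- c(rep("abaxial", 4), "adaxial", rep("abaxial", 5))
  tis <- wedge_disc(10, ids)
  expect_equal(boundary_source_cells(tis), c(4, 5, 6))

  # all-abaxial epidermis has no boundary
  tis <- wedge_disc(10, rep("abaxial", 10))
  expect_error(boundary_source_cells(tis), "boundary")
})

test_that("topology audit checks area tiling and passes on fixtures", {
  expect_true(audit_tissue(default_mesh()))
  expect_true(audit_tissue(onion_tissue(4, 8)))

  tis <- default_mesh()
  S <- pitchersim:::cell_areas(tis)
  topo <- tissue_topology(tis)
  outer_area <- pitchersim:::polygon_area(
    tis$vertices[topo$boundary_cycle, , drop = FALSE])
  expect_equal(sum(S), outer_area, tolerance = 1e-9)
})

test_that("tissue serialization round-trips bit-exactly", {
  tis <- default_mesh()
  dir <- withr::local_tempdir()
  write_tissue(tis, file.path(dir, "a"))
  tis2 <- read_tissue(file.path(dir, "a"))
  expect_identical(unname(tis2$vertices), unname(tis$vertices))
  expect_identical(tis2$cells, tis$cells)
  expect_equal(as.data.frame(tis2$states), as.data.frame(tis$states))
  # writing the round-tripped tissue reproduces the same bytes
  write_tissue(tis2, file.path(dir, "b"))
  for (f in c("vertices.csv", "cells.csv")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  }
})
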