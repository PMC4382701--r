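# Small meshes built in code, used across test files.

# one unit-square cell
unit_square <- function() {
  leaf_tissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
}

# horizontal strip of n unit-square cells
strip_tissue <- function(n = 3) {
  V <- cbind(rep(0:n, 2), rep(c(0, 1), each = n + 1))
  cells <- lapply(seq_len(n), function(i) {
    c(i, i + 1, n + 1 + i + 1, n + 1 + i)
  })
  leaf_tissue(V, cells)
}

# disc of n wedge cells around a shared centre vertex: every cell is L1 and
# the cell-adjacency graph is a ring
wedge_disc <- function(n = 10, identities = NULL) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  V <- rbind(c(0, 0), cbind(cos(th), sin(th)))
  cells <- lapply(seq_len(n), function(i) c(1, i + 1, (i %% n) + 2))
  tis <- leaf_tissue(V, cells)
  if (!is.null(identities)) tis$states$identity <- identities
  classify_layers(tis)
}

# radial "onion": n_rings concentric rings of n_sec quadrilaterals around a
# core of n_sec wedges; layers from the outside are L1, L2, L3, inner, ...
onion_tissue <- function(n_rings = 5, n_sec = 12) {
  th <- 2 * pi * (seq_len(n_sec) - 1) / n_sec
  V <- rbind(c(0, 0))
  for (r in seq_len(n_rings)) V <- rbind(V, cbind(r * cos(th), r * sin(th)))
  vid <- function(r, i) 1 + (r - 1) * n_sec + ((i - 1) %% n_sec) + 1
  cells <- lapply(seq_len(n_sec), function(i) c(1, vid(1, i), vid(1, i + 1)))
  for (r in 2:n_rings) {
    cells <- c(cells, lapply(seq_len(n_sec), function(i) {
      c(vid(r - 1, i), vid(r, i), vid(r, i + 1), vid(r - 1, i + 1))
    }))
  }
  classify_layers(leaf_tissue(V, cells))
}

# a regular n-gon cell, circumradius rad
ngon_tissue <- function(n = 6, rad = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n + pi / 2
  leaf_tissue(cbind(rad * cos(th), rad * sin(th)), list(seq_len(n)))
}

# random simple-ish convex polygon (hexagon) for long-axis oracle tests
random_hexagon <- function() {
  th <- sort(stats::runif(6, 0, 2 * pi))
  r <- stats::runif(6, 0.5, 1.5)
  cbind(r * cos(th), r * sin(th))
}

# brute-force long-axis oracle: minimize the summed squared vertex-to-line
# distance R(theta) over a fine grid of orientations
grid_long_axis <- function(P, step = 1e-4) {
  ctr <- colMeans(P)
  x <- P[, 1] - ctr[1]; y <- P[, 2] - ctr[2]
  th <- seq(0, pi, by = step)
  # distance of point to line through origin at angle th: |-sin th * x + cos th * y|
  R <- vapply(th, function(a) sum((-sin(a) * x + cos(a) * y)^2), numeric(1))
  th[which.min(R)]
}

# axis-aligned unit squares (given centre points) assembled into a tissue
squares_tissue <- function(cx, cy) {
  dx <- c(-0.5, 0.5, 0.5, -0.5)
  dy <- c(-0.5, -0.5, 0.5, 0.5)
  vx <- outer(cx, dx, `+`)
  vy <- outer(cy, dy, `+`)
  key <- paste(round(vx * 2), round(vy * 2))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  V <- cbind(as.vector(vx)[first], as.vector(vy)[first])
  cells <- lapply(split(uid, rep(seq_along(cx), times = 4)), unname)
  leaf_tissue(V, cells)
}

# square body with a one-cell-wide finger of adaxial cells hanging from the
# bottom edge: a hand-constructed "protrusion" phenotype
finger_tissue <- function(len = 7, body = 7) {
  g <- expand.grid(x = seq_len(body) - 0.5, y = seq_len(body) - 0.5)
  fx <- rep(ceiling(body / 2) - 0.5, len)
  fy <- -(seq_len(len) - 0.5)
  tis <- squares_tissue(c(g$x, fx), c(g$y, fy))
  topo <- tissue_topology(tis)
  id <- rep("none", length(tis$cells))
  id[topo$l1] <- "abaxial"
  id[(body^2 + 1):(body^2 + len)] <- "adaxial"
  tis$states$identity <- id
  classify_layers(tis)
}

# default initial mesh, built once per test session
default_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- classify_layers(build_initial_mesh(seed = 42))
    cache
  }
})

fold90 <- function(x) pitchersim:::fold_angle_deg(x)
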