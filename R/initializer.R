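#' Procedurally generate the initial primordium cross-section
#'
#' Builds a roughly round aggregate of about `n_cells` polygonal cells with,
#' by default, a small depression on the adaxial side: jittered hexagonal
#' seeds are tessellated into a centroidal Voronoi diagram (Lloyd
#' relaxation), clipped to the target outline (a disc, notched by a cosine
#' profile for `shape = "depression"`), cleaned of sliver and low-degree
#' cells, and mechanically relaxed to quiescence.  The
#' contiguous string of `n_adaxial` epidermal cells centred on the depression
#' is given adaxial identity, all other epidermal cells abaxial identity.
#' Morphogens and clocks start at 0; division thresholds are drawn uniformly
#' from `[(1-f) C, (1+f) C]`.
#'
#' The y axis points from the adaxial (bottom, negative y) to the abaxial
#' (top, positive y) side; the depression is at the bottom of the outline.
#'
#' @param n_cells target cell count (>= 20); generation fails if the packed
#'   count is off by more than 10%.
#' @param shape `"depression"` (default) or `"round"` (control, no notch).
#' @param n_adaxial number of adaxial-L1 cells (>= 2 and fewer than half the
#'   boundary cells).
#' @param depth_frac,width_frac depression depth and width as fractions of
#'   the disc diameter.
#' @param params a [model_params()] list (relaxation mechanics, thresholds).
#' @param relax_tol,relax_max_steps relaxation stops when the per-step vertex
#'   displacement falls below `relax_tol` (or after `relax_max_steps` steps).
#' @param seed optional integer; when given, seeds the RNG so the mesh is
#'   reproducible byte-for-byte.
#' @return A [leaf_tissue()] with layers classified.
#' @examples
#' \donttest{
#' tis <- build_initial_mesh(n_cells = 40, n_adaxial = 4, seed = 1)
#' }
#' @export
build_initial_mesh <- function(n_cells = 100, shape = c("depression", "round"),
                               n_adaxial = 6, depth_frac = 0.15,
                               width_frac = 0.35, params = model_params(),
                               relax_tol = 1e-7, relax_max_steps = 20000,
                               seed = NULL) {
  shape <- match.arg(shape)
  if (n_cells < 20) stop("target cell count must be >= 20")
  if (n_adaxial < 2) stop("need at least 2 adaxial-L1 cells")
  if (!is.null(seed)) set.seed(seed)

  unit <- params$cell_area_scale  # mean cell area of the packing
  r_hex <- sqrt(2 * unit / (3 * sqrt(3)))  # circumradius at that area
  R <- sqrt(n_cells * unit / pi)
  tissue <- NULL
  for (iter in 1:12) {
    tess <- try({
      out <- voronoi_tissue(R, shape, depth_frac, width_frac, r_hex, unit)
      audit_tissue(out)
      out
    }, silent = TRUE)
    if (inherits(tess, "try-error")) {
      R <- R * 1.02  # nudge the outline and re-jitter
      next
    }
    count <- length(tess$cells)
    if (abs(count - n_cells) <= 0.1 * n_cells) { tissue <- tess; break }
    R <- R * sqrt(n_cells / max(count, 1))
  }
  if (is.null(tissue)) stop("tessellation failed to reach within 10% of ", n_cells, " cells")
  tissue <- relax_tissue(tissue, params, tol = relax_tol,
                         max_steps = relax_max_steps)

  topo <- tissue_topology(tissue)
  bc <- topo$boundary_cells
  if (n_adaxial >= length(bc) / 2) {
    stop("adaxial-L1 count must be below half the boundary cell count")
  }
  cen <- vapply(tissue$cells[bc], function(cyc) {
    colMeans(tissue$vertices[cyc, , drop = FALSE])
  }, numeric(2))
  mid <- colMeans(do.call(rbind, lapply(tissue$cells, function(cyc) {
    colMeans(tissue$vertices[cyc, , drop = FALSE])
  })))
  ang <- atan2(cen[2, ] - mid[2], cen[1, ] - mid[1])
  gap <- abs(((ang - (-pi / 2)) + pi) %% (2 * pi) - pi)  # distance to notch axis
  anchor <- which.min(gap)
  offs <- (anchor - floor((n_adaxial - 1) / 2) - 1 +
           seq_len(n_adaxial) - 1) %% length(bc) + 1
  adax <- bc[offs]
  id <- rep("none", length(tissue$cells))
  id[bc] <- "abaxial"
  id[adax] <- "adaxial"
  tissue$states$identity <- id
  fl <- params$threshold_fluctuation
  tissue$states$threshold <- stats::runif(length(tissue$cells),
                                          (1 - fl) * params$C,
                                          (1 + fl) * params$C)
  tissue$states$u <- 0; tissue$states$v <- 0; tissue$states$w <- 0
  tissue$states$clock <- 0
  classify_layers(tissue, tissue_topology(tissue))
}

# centroidal Voronoi tessellation of the target outline: jittered hexagonal
# seeds, Lloyd relaxation, cells clipped to the outline polygon, assembled
# into a shared-vertex tissue
voronoi_tissue <- function(R, shape, depth_frac, width_frac, r_hex,
                           unit = 1, jitter = 0.25, lloyd = 4) {
  spacing <- sqrt(3) * r_hex
  outline <- outline_polygon(R, shape, depth_frac, width_frac)
  h <- hex_lattice(R * 1.5, r_hex)
  seeds <- cbind(h$cx, h$cy)
  seeds <- seeds + matrix(stats::runif(length(seeds), -jitter * r_hex,
                                       jitter * r_hex), ncol = 2)
  for (round in seq_len(lloyd + 1)) {
    inside <- outline_radius(atan2(seeds[, 2], seeds[, 1]), R, shape,
                             depth_frac, width_frac) >=
      sqrt(rowSums(seeds^2))
    seeds <- seeds[inside, , drop = FALSE]
    polys <- lapply(seq_len(nrow(seeds)), function(i) {
      voronoi_cell(i, seeds, outline, cutoff = 3 * spacing)
    })
    ok <- vapply(polys, function(P) !is.null(P) && nrow(P) >= 3, logical(1))
    polys <- polys[ok]
    seeds <- seeds[ok, , drop = FALSE]
    if (round <= lloyd) {
      seeds <- t(vapply(polys, polygon_centroid, numeric(2)))
    }
  }
  # quality culling: remove seeds whose cells come out as slivers or
  # low-degree polygons (their neighbours absorb the space), so the relaxed
  # aggregate has no near-degenerate cells
  for (pass in 1:6) {
    tis <- polys_to_tissue(polys)
    areas <- vapply(tis$cells, function(cyc) {
      polygon_area(tis$vertices[cyc, , drop = FALSE])
    }, numeric(1))
    bad <- areas < 0.55 * unit | lengths(tis$cells) <= 4
    if (!any(bad)) return(tis)
    seeds <- seeds[!bad, , drop = FALSE]
    polys <- lapply(seq_len(nrow(seeds)), function(i) {
      voronoi_cell(i, seeds, outline, cutoff = 4 * spacing)
    })
    ok <- vapply(polys, function(P) !is.null(P) && nrow(P) >= 3, logical(1))
    polys <- polys[ok]
    seeds <- seeds[ok, , drop = FALSE]
  }
  polys_to_tissue(polys)
}

outline_polygon <- function(R, shape, depth_frac, width_frac, n = 48) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- outline_radius(th, R, shape, depth_frac, width_frac)
  cbind(r * cos(th), r * sin(th))
}

# Sutherland-Hodgman clip of polygon P by the half-plane n . x <= c
clip_halfplane <- function(P, nvec, cval) {
  m <- nrow(P)
  if (m == 0) return(P)
  d <- P %*% nvec - cval
  out <- matrix(0, m * 2, 2)
  k <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (d[i] <= 0) { k <- k + 1; out[k, ] <- P[i, ] }
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1
      out[k, ] <- P[i, ] + t * (P[j, ] - P[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

voronoi_cell <- function(i, seeds, outline, cutoff) {
  si <- seeds[i, ]
  d2 <- (seeds[, 1] - si[1])^2 + (seeds[, 2] - si[2])^2
  nbr <- which(d2 > 0 & d2 < cutoff^2)
  P <- outline
  for (j in nbr[order(d2[nbr])]) {
    nvec <- seeds[j, ] - si
    cval <- (sum(seeds[j, ]^2) - sum(si^2)) / 2
    P <- clip_halfplane(P, nvec, cval)
    if (nrow(P) < 3) return(NULL)
  }
  P
}

polygon_centroid <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

# assemble clipped cell polygons into a shared-vertex tissue; coincident
# vertices computed independently by adjacent cells are merged by snapping
# to a fine grid, and degenerate (snapped-together) cycle entries dropped
polys_to_tissue <- function(polys, snap = 1e-6) {
  allv <- do.call(rbind, polys)
  key <- paste(round(allv[, 1] / snap), round(allv[, 2] / snap))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  V <- allv[first, , drop = FALSE]
  counts <- vapply(polys, nrow, integer(1))
  cells <- split(uid, rep(seq_along(polys), counts))
  cells <- lapply(cells, function(cyc) {
    cyc <- cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]
    if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
    cyc
  })
  if (any(lengths(cells) < 3)) stop("degenerate tessellation cell")
  simplify_boundary(V, unname(cells))
}

# drop outline-sampling vertices owned by a single cell (mid-arc points of a
# boundary cell's outer wall) so each boundary cell keeps one straight outer
# edge per stretch; junction vertices (shared by >= 2 cells) survive
simplify_boundary <- function(V, cells) {
  owners <- tabulate(unlist(cells), nbins = nrow(V))
  drop <- owners == 1L
  cells <- lapply(cells, function(cyc) cyc[!drop[cyc]])
  if (any(lengths(cells) < 3)) stop("boundary simplification degenerated a cell")
  used <- sort(unique(unlist(cells)))
  remap <- match(seq_len(nrow(V)), used)
  leaf_tissue(V[used, , drop = FALSE],
              lapply(cells, function(cyc) remap[cyc]))
}

# pointy-top hexagon lattice covering a disc of radius `extent`
hex_lattice <- function(extent, r) {
  dx <- sqrt(3) * r
  dy <- 1.5 * r
  jr <- ceiling(extent / dy)
  ir <- ceiling(extent / dx)
  grid <- expand.grid(i = -ir:ir, j = -jr:jr)
  cx <- dx * (grid$i + (grid$j %% 2) / 2)
  cy <- dy * grid$j
  list(cx = cx, cy = cy, r = r)
}

# target outline radius as a function of polar angle
outline_radius <- function(theta, R, shape, depth_frac, width_frac) {
  if (shape == "round") return(rep(R, length(theta)))
  depth <- depth_frac * 2 * R
  half <- width_frac  # angular half-width in radians (width_frac * 2R / 2R)
  d <- abs(((theta - (-pi / 2)) + pi) %% (2 * pi) - pi)
  notch <- ifelse(d < half, cos(pi * d / (2 * half))^2, 0)
  R - depth * notch
}

# assemble kept hexagons into a shared-vertex tissue (vertex dedup by
# rounding to a fine grid; exact enough because lattice coordinates of
# coincident vertices differ only by floating noise)
hexes_to_tissue <- function(hexes, keep, r) {
  cx <- hexes$cx[keep]; cy <- hexes$cy[keep]
  ang <- pi / 2 + (0:5) * pi / 3
  vx <- outer(cx, r * cos(ang), `+`)
  vy <- outer(cy, r * sin(ang), `+`)
  key <- paste(round(vx / (r * 1e-6)), round(vy / (r * 1e-6)))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  V <- cbind(as.vector(vx)[first], as.vector(vy)[first])[order(uid[first]), , drop = FALSE]
  cells <- split(uid, rep(seq_along(cx), times = 6))
  cells <- lapply(cells, unname)
  leaf_tissue(V, cells)
}

#' Audit an initial mesh
#'
#' Runs the full topology audit and summarizes the generated aggregate:
#' counts per layer and identity, mean cell area, and outer boundary length.
#'
#' @param tissue a [leaf_tissue()].
#' @return A list with `n_cells`, `per_layer`, `per_identity`, `mean_area`,
#'   `boundary_length`.
#' @export
audit_initial <- function(tissue) {
  if (!inherits(tissue, "leaf_tissue") || length(tissue$cells) == 0) {
    stop("empty or invalid mesh")
  }
  audit_tissue(tissue)
  topo <- tissue_topology(tissue)
  bcyc <- topo$boundary_cycle
  bl <- sum(sqrt(rowSums((tissue$vertices[bcyc, , drop = FALSE] -
                          tissue$vertices[c(bcyc[-1], bcyc[1]), , drop = FALSE])^2)))
  list(n_cells = length(tissue$cells),
       per_layer = table(tissue$states$layer),
       per_identity = table(tissue$states$identity),
       mean_area = mean(cell_areas(tissue)),
       boundary_length = bl)
}
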