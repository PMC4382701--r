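#' Division-clock rate
#'
#' Non-epidermal cells accumulate a division clock at rate
#' `P0 + P * u^n/(u0^n + u^n) * S^m/(S0^m + S^m)`: a baseline `P0` plus a
#' rate `P` gated by two Hill terms, one in the division-promoting morphogen
#' `u` (half-saturation `u0`, exponent `n`) and one in the cell area `S`
#' (half-saturation `S0`, exponent `m`).  A cell divides when its clock
#' exceeds its threshold (strictly), after which daughters restart at 0 with
#' freshly drawn thresholds.
#'
#' @param u,S morphogen concentration and cell area (vectors recycle).
#' @param params a [model_params()] list.
#' @return Numeric vector of clock rates.
#' @examples
#' clock_rate(0, 1)              # baseline P0
#' clock_rate(0.03, 1.2)         # both Hill terms at half saturation
#' @export
clock_rate <- function(u, S, params = model_params()) {
  if (any(u < 0) || any(S < 0)) stop("negative u or S in clock rate")
  hu <- ifelse(u > 0, u^params$n / (params$u0^params$n + u^params$n), 0)
  hs <- ifelse(S > 0, S^params$m / (params$S0^params$m + S^params$m), 0)
  params$P0 + params$P * hu * hs
}

#' Advance the division clock
#'
#' One (or more) Euler steps of the clock ODE for every non-epidermal cell;
#' epidermal cells divide by the neighbour-count rule instead and their
#' clocks are never advanced.
#'
#' @param tissue a [leaf_tissue()] with current layer labels.
#' @inheritParams clock_rate
#' @param n_steps number of Euler steps of size `dt`.
#' @return The tissue with updated `clock` column.
#' @export
clock_step <- function(tissue, params = model_params(), n_steps = 1) {
  st <- tissue$states
  if (any(is.na(st$layer))) stop("layer labels missing: run classify_layers()")
  S <- cell_areas(tissue)
  non_epi <- st$layer != "L1"
  rate <- clock_rate(st$u[non_epi], S[non_epi], params)
  st$clock[non_epi] <- st$clock[non_epi] + n_steps * params$dt * rate
  tissue$states <- st
  tissue
}

cell_areas <- function(tissue) {
  vapply(tissue$cells,
         function(cyc) polygon_area(tissue$vertices[cyc, , drop = FALSE]),
         numeric(1))
}

#' Cells due to divide
#'
#' Queues every non-epidermal cell whose clock strictly exceeds its threshold
#' and every epidermal cell with five or more neighbouring cells (six edges,
#' for a cell with a single outermost edge), in ascending cell-id order.
#'
#' @inheritParams clock_step
#' @param topo optional precomputed [tissue_topology()].
#' @return Integer vector of cell ids (possibly empty).
#' @export
check_divisions <- function(tissue, params = model_params(),
                            topo = tissue_topology(tissue)) {
  st <- tissue$states
  non_epi <- !topo$l1 & st$clock > st$threshold
  epi <- topo$l1 & lengths(topo$neighbors) >= 5L
  sort(st$cell[non_epi | epi])
}

#' Long axis of a point set
#'
#' The line through the centre (unweighted mean of the points) that
#' minimizes the sum of squared point-to-line distances `R(theta)`; in closed
#' form the principal axis of the second-moment sums `Sxx`, `Syy`, `Sxy`
#' about the centre, `theta0 = atan2(2 Sxy, Sxx - Syy) / 2`.  Inner cells
#' divide perpendicular to this axis.
#'
#' @param P numeric matrix of points (rows), e.g. a cell's vertices.
#' @param centre optional centre; defaults to `colMeans(P)`.
#' @return List with `theta` (radians in `[0, pi)`), `degenerate` (`TRUE`
#'   when the moment matrix has no eigenvalue gap, e.g. a square, so the
#'   axis is a tie) and `gap` (the eigenvalue gap).
#' @examples
#' long_axis(cbind(c(-2, 2, 2, -2), c(-1, -1, 1, 1)))$theta  # 0: x axis
#' @export
long_axis <- function(P, centre = NULL) {
  P <- as.matrix(P)
  if (nrow(P) < 3) stop("need at least 3 points")
  if (is.null(centre)) centre <- colMeans(P)
  x <- P[, 1] - centre[1]; y <- P[, 2] - centre[2]
  Sxx <- sum(x * x); Syy <- sum(y * y); Sxy <- sum(x * y)
  gap <- sqrt((Sxx - Syy)^2 + 4 * Sxy^2)
  theta <- 0.5 * atan2(2 * Sxy, Sxx - Syy)
  theta <- theta %% pi
  list(theta = theta, degenerate = gap < 1e-12, gap = gap)
}

#' Morphogen-weighted division axis
#'
#' For a dividing L2/L3 cell, each neighbour `k` contributes a vector `s_k`
#' pointing from the cell centre toward the midpoint of the shared edge,
#' scaled to length `z_k`, the neighbour's concentration of morphogen `z`
#' (`v` or `w`).  The polygon of the `s_k` elongates toward higher
#' concentrations, and its long axis ([long_axis()] of the point set about
#' its mean) defines the axis `L_z`: divisions run parallel to `L_v`
#' (longitudinal) or perpendicular to `L_w` (periclinal).
#'
#' @inheritParams check_divisions
#' @param cell_id persistent cell id.
#' @param species `"v"` or `"w"`.
#' @return List with `theta`, `degenerate`, `available` (`FALSE` when every
#'   neighbour concentration is zero, in which case the caller falls back to
#'   the cell-shape long-axis rule).
#' @export
morphogen_axis <- function(tissue, cell_id, species = c("v", "w"),
                           topo = tissue_topology(tissue)) {
  species <- match.arg(species)
  i <- match(cell_id, tissue$states$cell)
  if (is.na(i)) stop("no cell with id ", cell_id)
  nbs <- topo$neighbors[[i]]
  if (length(nbs) < 2) stop("cell has fewer than 2 neighbours")
  cyc <- tissue$cells[[i]]
  xc <- colMeans(tissue$vertices[cyc, , drop = FALSE])
  inter <- which(!topo$outer & (topo$cell1 == i | topo$cell2 == i))
  other <- ifelse(topo$cell1[inter] == i, topo$cell2[inter], topo$cell1[inter])
  mids <- (tissue$vertices[topo$edge_a[inter], , drop = FALSE] +
           tissue$vertices[topo$edge_b[inter], , drop = FALSE]) / 2
  z <- tissue$states[[species]][other]
  if (all(z <= 0)) {
    return(list(theta = NA_real_, degenerate = FALSE, available = FALSE))
  }
  dir <- mids - matrix(xc, length(other), 2, byrow = TRUE)
  len <- sqrt(rowSums(dir^2))
  sk <- dir / len * z
  ax <- long_axis(sk)
  list(theta = ax$theta, degenerate = ax$degenerate, available = TRUE)
}

# cyclic integer range from..to inclusive over 1..N (empty if wrapping past)
cyc_seq <- function(from, to, N) {
  if (from > to) c(from:N, seq_len(to)) else from:to
}

# intersections of the line through `centre` with direction angle `theta`
# with the edges of polygon cycle; returns the chord straddling the centre
# or NULL when degenerate (grazes a vertex, misses, no straddling pair).
# Cuts closer than `eps` (fractional) or `abs_margin` (model units) to an
# existing vertex are rejected: they would create a near-zero edge whose
# repulsive term destabilizes the mechanics.
find_chord <- function(V, cyc, centre, theta, eps = 0.02, abs_margin = 0.02) {
  N <- length(cyc)
  d <- c(cos(theta), sin(theta))
  hits <- list()
  for (j in seq_len(N)) {
    a <- V[cyc[j], ]; b <- V[cyc[j %% N + 1], ]
    e <- b - a
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-14) next
    # centre + t d = a + s e
    ca <- a - centre
    t <- (ca[1] * e[2] - ca[2] * e[1]) / den
    s <- (ca[1] * d[2] - ca[2] * d[1]) / den
    if (s > 0 && s < 1) {
      L <- sqrt(sum(e^2))
      if (s < eps || s > 1 - eps || s * L < abs_margin ||
          (1 - s) * L < abs_margin) {
        return(NULL)  # grazes a vertex
      }
      hits[[length(hits) + 1]] <- list(j = j, s = s, t = t,
                                       p = a + s * e)
    }
  }
  if (length(hits) < 2) return(NULL)
  tv <- vapply(hits, `[[`, numeric(1), "t")
  neg <- which(tv < 0); pos <- which(tv >= 0)
  if (!length(neg) || !length(pos)) return(NULL)
  h1 <- hits[[neg[which.max(tv[neg])]]]
  h2 <- hits[[pos[which.min(tv[pos])]]]
  if (h1$j == h2$j) return(NULL)
  list(h1 = h1, h2 = h2)
}

#' Split a cell along a division line
#'
#' Executes one division: two new vertices are inserted where the division
#' line meets the cell boundary (and into the vertex cycles of the
#' neighbouring cells sharing the cut edges), and the parent polygon is
#' replaced by two counter-clockwise daughters that exactly partition its
#' area.  Daughters inherit the parent's identity and morphogen
#' concentrations; clocks restart at 0 with freshly drawn thresholds.
#'
#' If the line grazes a vertex (closer than the safety margin that protects
#' the edge-repulsion term), misses the polygon, or would cut off a daughter
#' below 1% of the parent's area, the line is rotated in increasing steps up
#' to +-0.15 rad (under 9 degrees, so the orientation class of the division
#' is preserved); if all attempts fail the division is deferred (returns
#' `NULL`).
#'
#' @inheritParams morphogen_axis
#' @param centre point on the division line (default: cell centre).
#' @param theta direction angle of the division line (radians).
#' @param cuts optional explicit cut specification, a list
#'   `list(j1 =, s1 =, j2 =, s2 =)` of cycle-edge indices and fractions
#'   (used by the epidermal midpoint rule); overrides `centre`/`theta`.
#' @param thresholds length-2 numeric, the daughters' division thresholds;
#'   drawn uniformly from `[0.9 C, 1.1 C]` if missing.
#' @param params a [model_params()] list (threshold draw).
#' @return `list(tissue =, event =)` where `event` is a one-row tibble
#'   (parent, daughter ids, division-line endpoints), or `NULL` if deferred.
#' @export
split_cell <- function(tissue, cell_id, centre = NULL, theta = NULL,
                       cuts = NULL, thresholds = NULL,
                       params = model_params(),
                       topo = tissue_topology(tissue),
                       rotations = c(0, 0.01, -0.01, 0.02, -0.02, 0.05,
                                     -0.05, 0.1, -0.1, 0.15, -0.15)) {
  i <- match(cell_id, tissue$states$cell)
  if (is.na(i)) stop("no cell with id ", cell_id)
  cyc <- tissue$cells[[i]]
  N <- length(cyc)
  V <- tissue$vertices
  parent_area <- polygon_area(V[cyc, , drop = FALSE])
  if (is.null(cuts)) {
    if (is.null(centre)) centre <- colMeans(V[cyc, , drop = FALSE])
    stopifnot(!is.null(theta))
    chord <- NULL
    for (dth in rotations) {
      chord <- find_chord(V, cyc, centre, theta + dth)
      if (!is.null(chord)) {
        aA <- chord_area(V, cyc, chord)
        if (min(aA, parent_area - aA) < 0.01 * parent_area) chord <- NULL
      }
      if (!is.null(chord)) break
    }
    if (is.null(chord)) return(NULL)
    j1 <- chord$h1$j; p1 <- chord$h1$p
    j2 <- chord$h2$j; p2 <- chord$h2$p
  } else {
    j1 <- cuts$j1; j2 <- cuts$j2
    stopifnot(j1 != j2)
    p1 <- V[cyc[j1], ] + cuts$s1 * (V[cyc[j1 %% N + 1], ] - V[cyc[j1], ])
    p2 <- V[cyc[j2], ] + cuts$s2 * (V[cyc[j2 %% N + 1], ] - V[cyc[j2], ])
  }
  # order cuts so jA < jB along the cycle
  if (j1 < j2) { jA <- j1; pA <- p1; jB <- j2; pB <- p2 }
  else         { jA <- j2; pA <- p2; jB <- j1; pB <- p1 }
  nv <- nrow(V)
  tissue$vertices <- rbind(V, pA, pB, deparse.level = 0)
  nA <- nv + 1L; nB <- nv + 2L
  dA <- c(nA, cyc[(jA + 1):jB], nB)
  dB <- c(nB, if (jB < N) cyc[(jB + 1):N], cyc[seq_len(jA)], nA)
  # insert the new vertices into the neighbours across the cut edges
  for (cut in list(list(j = jA, nn = nA), list(j = jB, nn = nB))) {
    a <- cyc[cut$j]; b <- cyc[cut$j %% N + 1]
    key <- format(as.numeric(b) * topo$K + a, trim = TRUE, scientific = FALSE)
    nb <- topo$dir_cell[key]
    if (!is.na(nb)) {
      ncyc <- tissue$cells[[nb]]
      k <- which(ncyc == b)
      k <- k[ncyc[k %% length(ncyc) + 1] == a]
      stopifnot(length(k) == 1)
      tissue$cells[[nb]] <- append(ncyc, cut$nn, after = k)
    }
  }
  aA <- polygon_area(tissue$vertices[dA, , drop = FALSE])
  aB <- polygon_area(tissue$vertices[dB, , drop = FALSE])
  if (abs(aA + aB - parent_area) > 1e-9 * max(1, parent_area)) {
    stop("daughters do not partition the parent area")
  }
  if (is.null(thresholds)) {
    fl <- params$threshold_fluctuation
    thresholds <- stats::runif(2, (1 - fl) * params$C, (1 + fl) * params$C)
  }
  id1 <- tissue$next_id; id2 <- tissue$next_id + 1L
  tissue$next_id <- tissue$next_id + 2L
  st <- tissue$states
  parent_row <- st[i, ]
  d1 <- parent_row; d1$cell <- id1; d1$clock <- 0; d1$threshold <- thresholds[1]
  d2 <- parent_row; d2$cell <- id2; d2$clock <- 0; d2$threshold <- thresholds[2]
  tissue$cells[[i]] <- dA
  tissue$cells[[length(tissue$cells) + 1L]] <- dB
  st[i, ] <- d1
  st <- dplyr::bind_rows(st, d2)
  tissue$states <- st
  event <- tibble::tibble(parent = cell_id, daughter1 = id1, daughter2 = id2,
                          x1 = pA[1], y1 = pA[2], x2 = pB[1], y2 = pB[2])
  list(tissue = tissue, event = event)
}

# area of the daughter cut off between the two chord points (the one
# containing cycle vertices jA+1..jB)
chord_area <- function(V, cyc, chord) {
  if (chord$h1$j < chord$h2$j) { jA <- chord$h1; jB <- chord$h2 }
  else { jA <- chord$h2; jB <- chord$h1 }
  P <- rbind(jA$p, V[cyc[(jA$j + 1):jB$j], , drop = FALSE], jB$p)
  polygon_area(P)
}

#' Choose and execute a division for one cell
#'
#' Applies the position-dependent orientation rules: epidermal (L1) cells are
#' split by the segment joining the midpoints of their outermost and
#' innermost edges; L2/L3 cells divide longitudinally (parallel to the
#' morphogen-`v` axis) except adaxial L2/L3 in `ridge` mode, which divide
#' periclinally (perpendicular to the morphogen-`w` axis); deeper cells
#' divide perpendicular to their long axis.  When a morphogen axis is
#' unavailable or degenerate, the cell falls back to the long-axis rule.
#'
#' @inheritParams split_cell
#' @param mode `"hollow"` (longitudinal throughout L1-L3) or `"ridge"`
#'   (adaxial L2/L3 forced periclinal).
#' @return As [split_cell()]; the event gains `mode` and `layer`/`side`
#'   columns.  `NULL` if the division was deferred.
#' @export
divide_cell <- function(tissue, cell_id, params = model_params(),
                        mode = c("hollow", "ridge"),
                        topo = tissue_topology(tissue)) {
  mode <- match.arg(mode)
  i <- match(cell_id, tissue$states$cell)
  st <- tissue$states[i, ]
  if (is.na(st$layer)) stop("layer labels missing: run classify_layers()")
  cyc <- tissue$cells[[i]]
  N <- length(cyc)
  xc <- colMeans(tissue$vertices[cyc, , drop = FALSE])
  div_mode <- NULL; res <- NULL
  if (st$layer == "L1") {
    # outermost edge: the cell's boundary edge (longest, if several);
    # innermost: the edge whose midpoint is farthest from the boundary
    is_outer <- vapply(seq_len(N), function(j) {
      a <- cyc[j]; b <- cyc[j %% N + 1]
      key <- format(as.numeric(b) * topo$K + a, trim = TRUE, scientific = FALSE)
      is.na(topo$dir_cell[key])
    }, logical(1))
    if (!any(is_outer)) stop("L1 cell without an outermost edge")
    mids <- t(vapply(seq_len(N), function(j) {
      (tissue$vertices[cyc[j], ] + tissue$vertices[cyc[j %% N + 1], ]) / 2
    }, numeric(2)))
    lens <- vapply(seq_len(N), function(j) {
      sqrt(sum((tissue$vertices[cyc[j], ] - tissue$vertices[cyc[j %% N + 1], ])^2))
    }, numeric(1))
    outer_j <- which(is_outer)[which.max(lens[is_outer])]
    # innermost edge: farthest midpoint from the boundary polyline, preferring
    # edges shared with a non-L1 neighbour so the cut never feeds vertices
    # back into the epidermis (keeps the six-edge trigger cascade finite)
    nb_layer <- vapply(seq_len(N), function(j) {
      a <- cyc[j]; b <- cyc[j %% N + 1]
      key <- format(as.numeric(b) * topo$K + a, trim = TRUE, scientific = FALSE)
      nb <- topo$dir_cell[key]
      if (is.na(nb)) NA_character_ else tissue$states$layer[nb]
    }, character(1))
    bpoly <- tissue$vertices[topo$boundary_cycle, , drop = FALSE]
    dists <- vapply(seq_len(N), function(j) {
      if (is_outer[j]) return(-Inf)
      dist_point_polyline(mids[j, ], bpoly, closed = TRUE)
    }, numeric(1))
    cand <- which(!is_outer & !is.na(nb_layer) & nb_layer != "L1")
    if (!length(cand)) cand <- which(!is_outer)
    # of those, take the edge cyclically opposite the outer edge (so the two
    # daughters split the lateral neighbours evenly and return to four
    # neighbours each), breaking ties by distance from the boundary
    d_cyc <- pmin((cand - outer_j) %% N, (outer_j - cand) %% N)
    cand <- cand[d_cyc == max(d_cyc)]
    inner_j <- cand[which.max(dists[cand])]
    res <- split_cell(tissue, cell_id,
                      cuts = list(j1 = outer_j, s1 = 0.5, j2 = inner_j, s2 = 0.5),
                      params = params, topo = topo)
    div_mode <- "epidermal"
  } else {
    if (st$layer %in% c("L2", "L3")) {
      periclinal <- mode == "ridge" && !is.na(st$side) && st$side == "adaxial"
      species <- if (periclinal) "w" else "v"
      ax <- morphogen_axis(tissue, cell_id, species, topo)
      if (!ax$available || ax$degenerate) {
        la <- long_axis(tissue$vertices[cyc, , drop = FALSE])
        theta <- if (la$degenerate) pi / 2 else la$theta + pi / 2
        div_mode <- "long-axis"
      } else {
        theta <- if (periclinal) ax$theta + pi / 2 else ax$theta
        div_mode <- if (periclinal) "periclinal" else "longitudinal"
      }
    } else {
      la <- long_axis(tissue$vertices[cyc, , drop = FALSE])
      theta <- (if (la$degenerate) 0 else la$theta) + pi / 2
      div_mode <- "long-axis"
    }
    res <- split_cell(tissue, cell_id, centre = xc, theta = theta,
                      params = params, topo = topo)
    if (is.null(res)) {
      # rule direction cannot produce a valid chord (strongly non-convex
      # cell); sweep alternative directions so the division is only ever
      # deferred, never stuck
      for (extra in pi * seq_len(11) / 12) {
        res <- split_cell(tissue, cell_id, centre = xc, theta = theta + extra,
                          params = params, topo = topo)
        if (!is.null(res)) { div_mode <- "long-axis"; break }
      }
    }
  }
  if (is.null(res)) return(NULL)
  res$event$mode <- div_mode
  res$event$layer <- st$layer
  res$event$side <- st$side
  res
}

# distance from point p to a (closed) polyline given as a vertex matrix
dist_point_polyline <- function(p, P, closed = TRUE) {
  n <- nrow(P)
  idx <- if (closed) cbind(seq_len(n), c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  dmin <- Inf
  for (r in seq_len(nrow(idx))) {
    a <- P[idx[r, 1], ]; b <- P[idx[r, 2], ]
    e <- b - a
    L2 <- sum(e^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * e) / L2))
    d <- sqrt(sum((a + t * e - p)^2))
    if (d < dmin) dmin <- d
  }
  dmin
}
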