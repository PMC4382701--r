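#' Polygonal tissue objects
#'
#' A `leaf_tissue` represents a transverse section of a primordium as a
#' shared-vertex polygonal cell aggregate: a matrix of vertex positions, one
#' counter-clockwise vertex cycle per cell, and a per-cell state table
#' (epidermal identity, derived layer label, morphogen concentrations,
#' division clock and threshold).  Vertices are never reconnected between
#' cells during a run; topology changes only by cell division.
#'
#' @param vertices numeric matrix with two columns (x, y).
#' @param cells list of integer vectors, each a vertex cycle; clockwise cycles
#'   are reversed to counter-clockwise.
#' @param states optional tibble with one row per cell; missing columns are
#'   filled with defaults (identity `"none"`, morphogens and clocks 0,
#'   threshold `C` from [model_params()]).
#' @return An object of class `leaf_tissue`.
#' @examples
#' sq <- leaf_tissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
#' cell_geometry(sq, 1)
#' @export
leaf_tissue <- function(vertices, cells, states = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2) stop("vertices must be an n x 2 matrix")
  cells <- lapply(cells, as.integer)
  for (i in seq_along(cells)) {
    cyc <- cells[[i]]
    if (length(cyc) < 3) stop("cell ", i, " has fewer than 3 vertices")
    if (anyDuplicated(cyc)) stop("cell ", i, " repeats a vertex")
    if (any(cyc < 1L | cyc > nrow(vertices))) stop("cell ", i, ": vertex index out of range")
    if (polygon_area(vertices[cyc, , drop = FALSE]) < 0) cells[[i]] <- rev(cyc)
  }
  n <- length(cells)
  if (is.null(states)) states <- tibble::tibble(cell = seq_len(n))
  states <- tibble::as_tibble(states)
  if (nrow(states) != n) stop("states must have one row per cell")
  defaults <- list(identity = "none", layer = NA_character_, side = NA_character_,
                   u = 0, v = 0, w = 0, clock = 0,
                   threshold = model_params()$C)
  if (is.null(states$cell)) states$cell <- seq_len(n)
  for (col in names(defaults)) {
    if (is.null(states[[col]])) states[[col]] <- defaults[[col]]
  }
  states <- states[c("cell", "identity", "layer", "side", "u", "v", "w",
                     "clock", "threshold")]
  structure(
    list(vertices = vertices, cells = cells, states = states,
         time = 0, step = 0L, next_id = max(states$cell) + 1L),
    class = "leaf_tissue"
  )
}

#' @export
print.leaf_tissue <- function(x, ...) {
  cat("<leaf_tissue> ", length(x$cells), " cells, ", nrow(x$vertices),
      " vertices, t = ", format(x$time), "\n", sep = "")
  tab <- table(x$states$layer, useNA = "ifany")
  if (!all(is.na(x$states$layer)))
    cat("  layers:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# shoelace area, signed (> 0 for CCW)
polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# simple-polygon check: no two non-adjacent edges intersect
polygon_simple <- function(P) {
  n <- nrow(P)
  if (n < 3) return(FALSE)
  a <- P
  b <- P[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Tissue topology
#'
#' Derives the edge structure of a tissue: every edge with its one or two
#' owning cells, outermost-edge flags, the cell-adjacency list, L1 flags
#' (cells owning at least one outermost edge) and the ordered outer boundary
#' cycle.  Interior edges must be shared by exactly two cells and directed
#' edges must be unique (consistent counter-clockwise orientation).
#'
#' @param tissue a [leaf_tissue()].
#' @return A list with elements `edge_a`, `edge_b`, `cell1`, `cell2`, `outer`,
#'   `neighbors` (list over cells), `l1` (logical), `boundary_cycle` (vertex
#'   indices, counter-clockwise), `boundary_cells` (cell positions in boundary
#'   order) and `dir_cell` (directed-edge lookup).
#' @export
tissue_topology <- function(tissue) {
  nv <- nrow(tissue$vertices)
  K <- nv + 1
  cyc_len <- lengths(tissue$cells)
  owner <- rep.int(seq_along(tissue$cells), cyc_len)
  a <- unlist(tissue$cells, use.names = FALSE)
  b <- unlist(lapply(tissue$cells, function(cyc) c(cyc[-1], cyc[1])), use.names = FALSE)
  dir_key <- as.numeric(a) * K + b
  if (anyDuplicated(dir_key)) stop("inconsistent orientation: duplicated directed edge")
  und_key <- pmin(a, b) * K + pmax(a, b)
  first <- !duplicated(und_key)
  idx2 <- match(und_key[!first], und_key[first])
  counts <- tabulate(match(und_key, und_key[first]), nbins = sum(first))
  if (any(counts > 2)) stop("edge shared by more than 2 cells")
  edge_a <- pmin(a, b)[first]; edge_b <- pmax(a, b)[first]
  cell1 <- owner[first]
  cell2 <- rep(NA_integer_, length(cell1))
  cell2[idx2] <- owner[!first]
  outer <- is.na(cell2)
  nb <- vector("list", length(tissue$cells))
  ii <- c(cell1[!outer], cell2[!outer]); jj <- c(cell2[!outer], cell1[!outer])
  sp <- split(jj, ii)
  nb[as.integer(names(sp))] <- lapply(sp, function(z) sort(unique(z)))
  for (i in seq_along(nb)) if (is.null(nb[[i]])) nb[[i]] <- integer(0)
  l1 <- rep(FALSE, length(tissue$cells))
  l1[unique(cell1[outer])] <- TRUE
  bc <- boundary_walk(edge_a[outer], edge_b[outer], cell1[outer], tissue$vertices)
  dir_cell <- owner
  names(dir_cell) <- format(dir_key, trim = TRUE, scientific = FALSE)
  list(edge_a = edge_a, edge_b = edge_b, cell1 = cell1, cell2 = cell2,
       outer = outer, neighbors = nb, l1 = l1,
       boundary_cycle = bc$cycle, boundary_cells = bc$cells,
       dir_cell = dir_cell, K = K, nv = nv)
}

# order the outer edges into one closed cycle (CCW) and list their owner
# cells in boundary order (consecutive duplicates merged)
boundary_walk <- function(ea, eb, cells, V) {
  if (length(ea) == 0) stop("tissue has no outer boundary")
  vs <- sort(unique(c(ea, eb)))
  adj <- split(c(eb, ea), factor(c(ea, eb), levels = vs))
  deg <- lengths(adj)
  if (any(deg != 2)) stop("boundary is not a single closed curve (tissue not simply connected)")
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  owner <- cells
  names(owner) <- key(ea, eb)
  start <- vs[1]
  cyc <- integer(length(ea))
  cyc[1] <- start
  prev <- -1L
  cur <- start
  for (k in seq_along(ea)) {
    nxt <- adj[[match(cur, vs)]]
    nxt <- nxt[nxt != prev][1]
    if (k < length(ea)) cyc[k + 1] <- nxt
    prev <- cur; cur <- nxt
  }
  if (cur != start) stop("boundary walk did not close (tissue not simply connected)")
  if (length(unique(cyc)) != length(vs)) stop("boundary has more than one component")
  if (polygon_area(V[cyc, , drop = FALSE]) < 0) cyc <- rev(cyc)
  ord_cells <- owner[key(cyc, c(cyc[-1], cyc[1]))]
  ord_cells <- ord_cells[c(TRUE, diff(ord_cells) != 0)]
  if (length(ord_cells) > 1 && ord_cells[1] == ord_cells[length(ord_cells)])
    ord_cells <- ord_cells[-length(ord_cells)]
  list(cycle = cyc, cells = unname(ord_cells))
}

#' Per-cell geometry
#'
#' Area (shoelace, counter-clockwise so positive), cell centre (unweighted
#' mean of the cell's vertex positions) and Euclidean edge lengths of one
#' cell.
#'
#' @param tissue a [leaf_tissue()].
#' @param cell_id persistent cell id (column `cell` of the state table).
#' @return A list with `area`, `centre` (length-2), `edge_lengths`.
#' @export
cell_geometry <- function(tissue, cell_id) {
  i <- match(cell_id, tissue$states$cell)
  if (is.na(i)) stop("no cell with id ", cell_id)
  P <- tissue$vertices[tissue$cells[[i]], , drop = FALSE]
  if (nrow(P) < 3) stop("degenerate polygon: fewer than 3 vertices")
  S <- polygon_area(P)
  if (S <= 0) stop("degenerate polygon: area <= 0")
  if (!polygon_simple(P)) stop("degenerate polygon: self-intersecting")
  nxt <- P[c(2:nrow(P), 1), , drop = FALSE]
  list(area = S, centre = colMeans(P),
       edge_lengths = sqrt(rowSums((nxt - P)^2)))
}

#' Layer classification
#'
#' Labels every cell by depth from the tissue surface: `L1` are the cells
#' owning at least one outermost edge, `L2` the remaining cells sharing an
#' edge with L1, `L3` those sharing an edge with L2, and everything deeper is
#' `inner`.  L2/L3 cells additionally get an adaxial/abaxial side label from
#' the layer above (adaxial L2 touches adaxial L1, adaxial L3 touches adaxial
#' L2; a cell touching both sides of the layer above is labelled adaxial).
#'
#' @param tissue a [leaf_tissue()] whose L1 cells carry adaxial/abaxial
#'   identities.
#' @param topo optional precomputed [tissue_topology()].
#' @return The tissue with updated `layer` and `side` state columns.
#' @export
classify_layers <- function(tissue, topo = tissue_topology(tissue)) {
  n <- length(tissue$cells)
  layer <- rep("inner", n)
  layer[topo$l1] <- "L1"
  touches <- function(set) {
    vapply(topo$neighbors, function(nbs) any(set[nbs]), logical(1))
  }
  is_l2 <- layer == "inner" & touches(topo$l1)
  layer[is_l2] <- "L2"
  is_l3 <- layer == "inner" & touches(is_l2)
  layer[is_l3] <- "L3"
  side <- rep(NA_character_, n)
  side[topo$l1] <- tissue$states$identity[topo$l1]
  ad1 <- topo$l1 & tissue$states$identity == "adaxial"
  ab1 <- topo$l1 & tissue$states$identity == "abaxial"
  side[is_l2 & touches(ad1)] <- "adaxial"
  side[is_l2 & !touches(ad1) & touches(ab1)] <- "abaxial"
  ad2 <- is_l2 & !is.na(side) & side == "adaxial"
  ab2 <- is_l2 & !is.na(side) & side == "abaxial"
  side[is_l3 & touches(ad2)] <- "adaxial"
  side[is_l3 & !touches(ad2) & touches(ab2)] <- "abaxial"
  tissue$states$layer <- layer
  tissue$states$side <- side
  if (any(tissue$states$identity != "none" & layer != "L1")) {
    stop("epidermal identity on a non-L1 cell")
  }
  tissue
}

#' Morphogen source cells at the adaxial-abaxial boundary
#'
#' The division-promoting morphogen is synthesized in the L1 cells flanking
#' the junctions between the adaxial and abaxial epidermal domains: every L1
#' cell that shares an edge with an L1 cell of the opposite identity (both
#' cells at each junction; two junctions give up to four source cells).
#'
#' @inheritParams classify_layers
#' @return Integer vector of cell ids.
#' @export
boundary_source_cells <- function(tissue, topo = tissue_topology(tissue)) {
  id <- tissue$states$identity
  if (!any(id == "adaxial") || !any(id == "abaxial")) {
    stop("no adaxial-abaxial boundary: need both identities on the epidermis")
  }
  src <- vapply(seq_along(topo$neighbors), function(i) {
    if (!topo$l1[i] || id[i] == "none") return(FALSE)
    nbs <- topo$neighbors[[i]]
    nbs <- nbs[topo$l1[nbs]]
    any(id[nbs] != "none" & id[nbs] != id[i])
  }, logical(1))
  sort(tissue$states$cell[src])
}

#' Topology audit
#'
#' Verifies the structural invariants of a tissue: every polygon is simple,
#' counter-clockwise and has at least 3 vertices; every interior edge is
#' shared by exactly two cells and outermost edges by one; directed edges are
#' unique; the outer boundary is a single closed curve; and the summed cell
#' areas equal the shoelace area of the outer boundary polygon (no overlaps
#' or gaps) to within `tol`.
#'
#' @inheritParams classify_layers
#' @param tol absolute tolerance on the area identity.
#' @return Invisibly `TRUE`; stops with a diagnostic on any violation.
#' @export
audit_tissue <- function(tissue, tol = 1e-9) {
  topo <- tissue_topology(tissue)  # errors on edge-sharing/orientation issues
  areas <- vapply(tissue$cells, function(cyc) {
    P <- tissue$vertices[cyc, , drop = FALSE]
    if (nrow(P) < 3) stop("cell with fewer than 3 vertices")
    if (!polygon_simple(P)) stop("self-intersecting cell polygon")
    a <- polygon_area(P)
    if (a <= 0) stop("non-positive (clockwise or degenerate) cell area")
    a
  }, numeric(1))
  outer_area <- polygon_area(tissue$vertices[topo$boundary_cycle, , drop = FALSE])
  if (abs(sum(areas) - outer_area) > tol * max(1, outer_area)) {
    stop("cell areas do not tile the boundary polygon: sum = ", sum(areas),
         ", boundary = ", outer_area)
  }
  id <- tissue$states$identity
  if (any((id != "none") != topo$l1)) {
    if (any(id != "none" & !topo$l1)) stop("identity assigned to a non-L1 cell")
  }
  invisible(TRUE)
}

# flat 0-based topology bundle for the compiled engine
engine_topo <- function(tissue, topo = tissue_topology(tissue),
                        params = model_params(),
                        src_u = NULL, src_v = NULL, src_w = NULL) {
  st <- tissue$states
  if (is.null(src_v)) src_v <- topo$l1
  if (is.null(src_w)) src_w <- topo$l1 & st$identity == "adaxial"
  if (is.null(src_u)) {
    src_u <- rep(FALSE, length(tissue$cells))
    if (any(st$identity == "adaxial") && any(st$identity == "abaxial")) {
      src_u[match(boundary_source_cells(tissue, topo), st$cell)] <- TRUE
    }
  }
  inter <- !topo$outer
  list(
    nv = nrow(tissue$vertices),
    cell_ptr = c(0L, cumsum(lengths(tissue$cells))),
    cell_vert = unlist(tissue$cells, use.names = FALSE) - 1L,
    edge_a = topo$edge_a - 1L, edge_b = topo$edge_b - 1L,
    edge_outer = as.integer(topo$outer),
    adj_i = topo$cell1[inter] - 1L, adj_j = topo$cell2[inter] - 1L,
    epidermal = as.integer(topo$l1),
    src_u = as.integer(src_u), src_v = as.integer(src_v),
    src_w = as.integer(src_w),
    s_target = params$cell_area_scale * target_area(lengths(tissue$cells))
  )
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.leaf_tissue <- function(x, ...) {
  topo <- tissue_topology(x)
  geo <- lapply(seq_along(x$cells), function(i) {
    P <- x$vertices[x$cells[[i]], , drop = FALSE]
    c(area = polygon_area(P), x = mean(P[, 1]), y = mean(P[, 2]))
  })
  geo <- do.call(rbind, geo)
  dplyr::bind_cols(
    x$states,
    tibble::tibble(n_edges = lengths(x$cells), area = geo[, "area"],
                   x = geo[, "x"], y = geo[, "y"],
                   n_neighbors = lengths(topo$neighbors))
  )
}

#' Read and write tissues as a CSV pair
#'
#' `write_tissue()` serializes a tissue to `vertices.csv` (id, x, y) and
#' `cells.csv` (id, vertex cycle as a space-separated index list, identity,
#' layer, side, morphogens, clock, threshold) inside `dir`; `read_tissue()`
#' round-trips it.  Coordinates are written with full precision so that a
#' round trip is bit-exact.
#'
#' @param tissue a [leaf_tissue()].
#' @param dir directory (created if needed).
#' @return `write_tissue()` the directory path invisibly; `read_tissue()` a
#'   [leaf_tissue()].
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vt <- tibble::tibble(id = seq_len(nrow(tissue$vertices)),
                       x = sprintf("%.17g", tissue$vertices[, 1]),
                       y = sprintf("%.17g", tissue$vertices[, 2]))
  readr::write_csv(vt, file.path(dir, "vertices.csv"), progress = FALSE)
  st <- tissue$states
  ct <- tibble::tibble(
    id = st$cell,
    vertex_cycle = vapply(tissue$cells, paste, character(1), collapse = " "),
    identity = st$identity, layer = st$layer, side = st$side,
    u = sprintf("%.17g", st$u), v = sprintf("%.17g", st$v),
    w = sprintf("%.17g", st$w), clock = sprintf("%.17g", st$clock),
    threshold = sprintf("%.17g", st$threshold))
  readr::write_csv(ct, file.path(dir, "cells.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(dir) {
  # base read.csv: correctly rounded strtod so 17-digit round trips are exact
  vt <- utils::read.csv(file.path(dir, "vertices.csv"))
  ct <- utils::read.csv(file.path(dir, "cells.csv"),
                        colClasses = c(vertex_cycle = "character",
                                       identity = "character",
                                       layer = "character",
                                       side = "character"))
  cells <- lapply(strsplit(ct$vertex_cycle, " "), as.integer)
  states <- tibble::tibble(cell = ct$id, identity = ct$identity,
                           layer = ct$layer, side = ct$side,
                           u = ct$u, v = ct$v, w = ct$w,
                           clock = ct$clock, threshold = ct$threshold)
  leaf_tissue(as.matrix(vt[, c("x", "y")]), cells, states)
}
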