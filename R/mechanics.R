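#' Target area of an N-sided cell
#'
#' Cells relax toward an edge-count-dependent target area: the area of a
#' regular N-gon relative to a regular hexagon of the same edge length,
#' `s = N tan(pi/6) / (6 tan(pi/N))`.  A hexagon therefore has target area 1
#' and the target grows strictly with the number of edges, which is what lets
#' the tissue expand as divisions redistribute edge counts.
#'
#' @param n_edges integer vector of polygon edge counts (>= 3).
#' @return Numeric vector of target areas.
#' @examples
#' target_area(c(4, 6, 8))
#' @export
target_area <- function(n_edges) {
  if (any(n_edges < 3)) stop("a polygon needs at least 3 edges")
  n_edges * tan(pi / 6) / (6 * tan(pi / n_edges))
}

#' Potential energy of a tissue
#'
#' The mechanical potential has three terms: area elasticity
#' `(K_S/2) sum_i (S_i - s_i)^2` about the edge-count-dependent target area
#' `cell_area_scale * target_area(N)` (the relative N-gon factor expressed in
#' the model's area unit); an edge term `sum_j (K_B L_j + K_R / L_j)` whose tension
#' plus short-range repulsion give every edge the finite target length
#' `sqrt(K_R / K_B)` and diverge as an edge shrinks to zero (vertices can
#' never cross); and outer-wall elasticity `(K_E/2) sum_k (L_k - L_E)^2` over
#' the outermost edges, representing the stiff cuticle.
#'
#' This is a plain-R reference implementation; the compiled engine evaluates
#' the identical expression and [vertex_forces()] returns its exact analytic
#' gradient.
#'
#' @param tissue a [leaf_tissue()].
#' @param params a [model_params()] list.
#' @param topo optional precomputed [tissue_topology()].
#' @return Scalar energy.
#' @export
potential_energy <- function(tissue, params = model_params(),
                             topo = tissue_topology(tissue)) {
  V <- tissue$vertices
  S <- vapply(tissue$cells, function(cyc) polygon_area(V[cyc, , drop = FALSE]),
              numeric(1))
  s_t <- params$cell_area_scale * target_area(lengths(tissue$cells))
  L <- sqrt(rowSums((V[topo$edge_a, , drop = FALSE] -
                     V[topo$edge_b, , drop = FALSE])^2))
  if (any(L <= 0)) stop("zero-length edge: repulsive term undefined")
  params$K_S / 2 * sum((S - s_t)^2) +
    sum(params$K_B * L + params$K_R / L) +
    params$K_E / 2 * sum((L[topo$outer] - params$L_E)^2)
}

#' Forces on vertices
#'
#' Analytic gradient `F_j = -dU/dx_j` of [potential_energy()], assembled
#' term by term in compiled code.
#'
#' @inheritParams potential_energy
#' @return Numeric matrix (vertices x 2).
#' @export
vertex_forces <- function(tissue, params = model_params(),
                          topo = tissue_topology(tissue)) {
  cpp_forces(tissue$vertices, engine_topo(tissue, topo, params), params)
}

#' Advance the mechanics
#'
#' Integrates the overdamped equation of motion `eta dx_j/dt = F_j` with the
#' fourth-order Runge-Kutta method, time step `dt`.  If a step collapses a
#' cell (non-positive area), it is retried with a halved step up to five
#' times before failing.
#'
#' @inheritParams potential_energy
#' @param n_steps number of RK4 steps.
#' @param record_energy if `TRUE`, attach the per-step energy trace as
#'   attribute `"energy"` of the result.
#' @return The tissue with updated vertex positions (time advanced by
#'   `n_steps * dt`).
#' @export
integrate_step <- function(tissue, params = model_params(), n_steps = 1,
                           record_energy = FALSE) {
  res <- cpp_mech_steps(tissue$vertices, engine_topo(tissue, params = params), params,
                        as.integer(n_steps), record_energy)
  tissue$vertices <- res$V
  tissue$time <- tissue$time + res$steps * params$dt
  tissue$step <- tissue$step + res$steps
  if (record_energy) attr(tissue, "energy") <- res$energy
  tissue
}

# relax until the per-step displacement drops below tol (or max_steps)
relax_tissue <- function(tissue, params = model_params(), tol = 1e-7,
                         max_steps = 20000) {
  res <- cpp_mech_steps(tissue$vertices, engine_topo(tissue, params = params), params,
                        as.integer(max_steps), FALSE, tol)
  tissue$vertices <- res$V
  tissue
}
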