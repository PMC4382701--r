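#' Morphogen dynamics on the cell-adjacency graph
#'
#' Three diffusible species live on the cells: `u`, the division-promoting
#' morphogen synthesized in the L1 cells flanking the adaxial-abaxial
#' boundary ([boundary_source_cells()]); `v`, synthesized in all L1 cells,
#' which orients longitudinal divisions in L2/L3; and `w`, synthesized in
#' adaxial L1 cells, which orients periclinal divisions.  Each species `z`
#' obeys, per cell `i` with neighbour set `nbr(i)`,
#' `dz_i/dt = A_z [i in sources] - B_z z_i + D_z sum_{j in nbr(i)} (z_j - z_i)`
#' (unweighted graph-Laplacian coupling), integrated with Euler's method at
#' step `dt`.
#'
#' @param tissue a [leaf_tissue()] with current layer labels (see
#'   [classify_layers()]).
#' @param params a [model_params()] list.
#' @param n_steps number of Euler steps.
#' @param sources optional named list (`u`, `v`, `w`) of cell-id vectors
#'   overriding the default source sets (useful on synthetic fixtures).
#' @return The tissue with updated `u`, `v`, `w` state columns.
#' @export
morphogen_step <- function(tissue, params = model_params(), n_steps = 1,
                           sources = NULL) {
  topo <- tissue_topology(tissue)
  st <- tissue$states
  inter <- !topo$outer
  i <- topo$cell1[inter]; j <- topo$cell2[inter]
  lap <- function(z) {
    d <- z[j] - z[i]
    out <- numeric(length(z))
    acc <- rowsum(c(d, -d), c(i, j))     # accumulate both directions
    out[as.integer(rownames(acc))] <- acc
    out
  }
  src <- morphogen_sources(tissue, topo, sources)
  for (s in seq_len(n_steps)) {
    for (z in c("u", "v", "w")) {
      A <- params[[paste0("A_", z)]]; B <- params[[paste0("B_", z)]]
      D <- params[[paste0("D_", z)]]
      zi <- st[[z]]
      zi <- zi + params$dt * (A * src[[z]] - B * zi + D * lap(zi))
      if (any(zi < 0 | !is.finite(zi))) {
        deg <- max(lengths(topo$neighbors))
        stop("Euler instability: dt * (B + D * max degree) = ",
             params$dt * (B + D * deg), " for species ", z)
      }
      st[[z]] <- zi
    }
  }
  tissue$states <- st
  tissue
}

# source indicator vectors for the three species; `override` is a named list
# of cell-id vectors replacing the model's default source sets
morphogen_sources <- function(tissue, topo = tissue_topology(tissue),
                              override = NULL) {
  st <- tissue$states
  out <- list()
  for (z in c("u", "v", "w")) {
    if (!is.null(override[[z]])) {
      ind <- rep(0, length(tissue$cells))
      ind[match(override[[z]], st$cell)] <- 1
      out[[z]] <- ind
    } else {
      out[[z]] <- switch(z,
        u = {
          ind <- rep(0, length(tissue$cells))
          ind[match(boundary_source_cells(tissue, topo), st$cell)] <- 1
          ind
        },
        v = as.numeric(topo$l1),
        w = as.numeric(topo$l1 & st$identity == "adaxial"))
    }
  }
  out
}

#' Steady state of one morphogen species
#'
#' Direct linear solve of the fixed point of the morphogen ODE system,
#' `(B I + D Lap) z = A s`, where `Lap` is the unweighted graph Laplacian of
#' the cell adjacency and `s` the source indicator.  Used as the exact
#' reference the Euler trajectory of [morphogen_step()] must converge to.
#'
#' @inheritParams morphogen_step
#' @param species one of `"u"`, `"v"`, `"w"`.
#' @return Numeric vector of steady-state concentrations (one per cell).
#' @export
steady_state <- function(tissue, params = model_params(), species = "u",
                         sources = NULL) {
  species <- match.arg(species, c("u", "v", "w"))
  topo <- tissue_topology(tissue)
  n <- length(tissue$cells)
  A <- params[[paste0("A_", species)]]
  B <- params[[paste0("B_", species)]]
  D <- params[[paste0("D_", species)]]
  inter <- !topo$outer
  i <- topo$cell1[inter]; j <- topo$cell2[inter]
  L <- matrix(0, n, n)
  for (k in seq_along(i)) {
    L[i[k], i[k]] <- L[i[k], i[k]] + 1
    L[j[k], j[k]] <- L[j[k], j[k]] + 1
    L[i[k], j[k]] <- L[i[k], j[k]] - 1
    L[j[k], i[k]] <- L[j[k], i[k]] - 1
  }
  M <- B * diag(n) + D * L
  src <- morphogen_sources(tissue, topo, sources)[[species]]
  z <- try(solve(M, A * src), silent = TRUE)
  if (inherits(z, "try-error")) stop("singular steady-state system (B = 0 on a disconnected graph?)")
  as.numeric(z)
}
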