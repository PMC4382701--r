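#' Model parameters
#'
#' Returns the full parameter set of the vertex-dynamics model with the
#' default values used for the preset in-silico experiments: mechanical
#' constants (viscosity `eta`, area elasticity `K_S`, edge tension `K_B` and
#' short-range repulsion `K_R`, outer-wall elasticity `K_E` with target length
#' `L_E`), the area unit `cell_area_scale` (the energy's target area is
#' `cell_area_scale * target_area(N)`; the default, the area of a regular
#' hexagon with unit edge, puts mature cells at edge lengths near 1 so that
#' the outer-wall target `L_E = 1.3` and the division half-saturation area
#' `S0 = 1.2` sit on the scales the model's constants imply), the
#' synthesis/degradation/diffusion constants of the three
#' morphogens (`u` division-promoting, `v` epidermal, `w` adaxial-epidermal),
#' and the division-clock constants (`P0` baseline rate, `P` promoted rate,
#' half-saturations `u0` and `S0`, Hill exponents `n` and `m`, threshold mean
#' `C`). `dt` is the shared Euler/Runge-Kutta time step.
#'
#' @param ... name-value overrides of any default, e.g. `D_u = 0.5`.
#' @return A named list of class `leaf_params`.
#' @examples
#' p <- model_params(D_u = 2)
#' p$D_u
#' @export
model_params <- function(...) {
  p <- list(
    eta = 1.0, K_S = 1.0, K_B = 0.1, K_R = 0.001, K_E = 0.005, L_E = 1.3,
    cell_area_scale = 6 / (4 * tan(pi / 6)),  # area of the unit-edge hexagon
    dt = 0.005,
    A_u = 2.0, B_u = 1.0, D_u = 1.0,
    A_v = 1.0, B_v = 1.0, D_v = 0.2,
    A_w = 1.0, B_w = 1.0, D_w = 0.2,
    P0 = 1.0, P = 20.0, u0 = 0.03, S0 = 1.2, n = 2, m = 8,
    C = 10000, threshold_fluctuation = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  mech <- c("eta", "K_S", "K_B", "K_R", "K_E", "L_E", "cell_area_scale", "dt")
  if (any(unlist(p[mech]) <= 0)) stop("mechanical parameters must be > 0")
  chem <- c("A_u", "B_u", "D_u", "A_v", "B_v", "D_v", "A_w", "B_w", "D_w")
  if (any(unlist(p[chem]) < 0)) stop("morphogen parameters must be >= 0")
  if (p$C <= 0) stop("division threshold C must be > 0")
  structure(p, class = "leaf_params")
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("<leaf_params>\n")
  cat(paste0("  ", names(x), " = ", unlist(x), collapse = "\n"), "\n")
  invisible(x)
}
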