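#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a division-angle comparison
#'
#' One row per group with the summary statistics, plus the test statistic
#' and p-values repeated alongside.
#'
#' @param x a `leaf_angle_test` from [compare_angle_distributions()].
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.leaf_angle_test <- function(x, ...) {
  dplyr::bind_cols(x$groups,
                   tibble::tibble(U = x$U, p_value = x$p_value,
                                  p_adjusted = x$p_adjusted,
                                  method = x$method))
}

#' @rdname tidy.leaf_angle_test
#' @export
glance.leaf_angle_test <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, p_adjusted = x$p_adjusted,
                 method = x$method)
}

#' Summarize a run in one row
#'
#' Final cell count and per-layer counts, number of divisions, simulated
#' time, and the protrusion morphometrics ([protrusion_index()]).
#'
#' @param x a `leaf_run` from [run_simulation()].
#' @param ... ignored.
#' @return A one-row tibble.
#' @export
glance.leaf_run <- function(x, ...) {
  lay <- table(factor(x$tissue$states$layer,
                      levels = c("L1", "L2", "L3", "inner")))
  pr <- protrusion_index(x$tissue)
  tibble::tibble(
    n_cells = length(x$tissue$cells), n_divisions = nrow(x$events),
    time = x$tissue$time,
    n_L1 = as.integer(lay["L1"]), n_L2 = as.integer(lay["L2"]),
    n_L3 = as.integer(lay["L3"]), n_inner = as.integer(lay["inner"]),
    protrusion_height = pr$protrusion_height,
    aspect_ratio = pr$aspect_ratio,
    adaxial_share = pr$adaxial_share,
    inner_fraction = pr$inner_fraction,
    classification = pr$classification)
}

#' Tidy a run's division events
#'
#' @param x a `leaf_run`.
#' @param ... ignored.
#' @return The event log as a tibble (one row per division).
#' @export
tidy.leaf_run <- function(x, ...) {
  x$events
}
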