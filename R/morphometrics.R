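#' Division-plane angle relative to the local tissue surface
#'
#' The angle between a division line and the local surface tangent, folded
#' into `[0, 90]` degrees: values close to 0 indicate periclinal division
#' (plane parallel to the surface), values close to 90 longitudinal division
#' (plane perpendicular to the surface).  The local tangent is the
#' least-squares direction of the outer-boundary chain of +-`window` edges
#' around the boundary segment nearest to the division line's midpoint
#' (nearest-by-centroid when distances tie).
#'
#' @param tissue a [leaf_tissue()].
#' @param p1,p2 the division-line endpoints (length-2 numeric).
#' @param window half-width of the boundary chain, in edges.
#' @param topo optional precomputed [tissue_topology()].
#' @return Angle in degrees in `[0, 90]`.
#' @export
division_angle <- function(tissue, p1, p2, window = 2,
                           topo = tissue_topology(tissue)) {
  mid <- (p1 + p2) / 2
  tang <- surface_tangent(tissue, mid, window, topo)
  theta_line <- atan2(p2[2] - p1[2], p2[1] - p1[1])
  fold_angle_deg((theta_line - tang) * 180 / pi)
}

# local surface tangent (radians) near a point: principal direction of the
# boundary vertices spanning +-window edges around the nearest boundary edge
surface_tangent <- function(tissue, point, window = 2,
                            topo = tissue_topology(tissue)) {
  cyc <- topo$boundary_cycle
  n <- length(cyc)
  P <- tissue$vertices[cyc, , drop = FALSE]
  Q <- tissue$vertices[c(cyc[-1], cyc[1]), , drop = FALSE]
  d <- vapply(seq_len(n), function(j) {
    a <- P[j, ]; b <- Q[j, ]
    e <- b - a; L2 <- sum(e^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((point - a) * e) / L2))
    sum((a + t * e - point)^2)
  }, numeric(1))
  j <- which.min(d)
  idx <- ((j - window):(j + window + 1) - 1) %% n + 1
  chain <- tissue$vertices[cyc[idx], , drop = FALSE]
  long_axis(chain)$theta
}

# fold an angle difference (degrees) into [0, 90]
fold_angle_deg <- function(delta) {
  a <- abs(delta) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Compare two division-angle samples
#'
#' Mann-Whitney U comparison of two groups of division angles (or any two
#' samples).  With both groups of size `<= n_exact` the two-sided p-value is
#' computed by full enumeration of all group assignments of the pooled
#' values (ties handled by the 0.5 convention in U); for larger samples the
#' normal approximation with tie correction and continuity correction is
#' used.  The p-value can be Bonferroni-adjusted for a family of
#' `n_comparisons` tests.  Medians and the +-1 and +-1.5 interquartile
#' ranges reported match violin-plot summary conventions.
#'
#' @param a,b numeric vectors (each of length >= 3).
#' @param n_exact exact-enumeration threshold on the per-group size.
#' @param n_comparisons Bonferroni family size.
#' @return An object of class `leaf_angle_test`: list with `U` (statistic of
#'   the first group), `p_value`, `p_adjusted`, `method`, and a `groups`
#'   tibble (n, median, quartiles, iqr bands).
#' @examples
#' compare_angle_distributions(c(10, 20, 30), c(80, 85, 88))
#' @export
compare_angle_distributions <- function(a, b, n_exact = 8, n_comparisons = 1) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 samples")
  U <- u_statistic(a, b)
  if (length(a) <= n_exact && length(b) <= n_exact) {
    p <- u_exact_p(a, b)
    method <- "exact enumeration"
  } else {
    p <- u_normal_p(a, b)
    method <- "normal approximation (tie-corrected)"
  }
  grp <- function(x, label) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    tibble::tibble(group = label, n = length(x), median = q[2],
                   q1 = q[1], q3 = q[3],
                   lo_1iqr = max(min(x), q[1] - 1 * iqr),
                   hi_1iqr = min(max(x), q[3] + 1 * iqr),
                   lo_1.5iqr = max(min(x), q[1] - 1.5 * iqr),
                   hi_1.5iqr = min(max(x), q[3] + 1.5 * iqr))
  }
  structure(list(U = U, p_value = p,
                 p_adjusted = min(1, p * n_comparisons),
                 n_comparisons = n_comparisons, method = method,
                 groups = dplyr::bind_rows(grp(a, "A"), grp(b, "B"))),
            class = "leaf_angle_test")
}

# U statistic of the first group (0.5 per tie)
u_statistic <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# two-sided p by full enumeration of group assignments of the pooled sample
u_exact_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); N <- length(pool)
  mu <- n1 * length(b) / 2
  obs <- abs(u_statistic(a, b) - mu)
  picks <- utils::combn(N, n1)
  us <- apply(picks, 2, function(ix) u_statistic(pool[ix], pool[-ix]))
  mean(abs(us - mu) >= obs - 1e-12)
}

# normal approximation with tie correction and continuity correction
u_normal_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U <- u_statistic(a, b)
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' @export
print.leaf_angle_test <- function(x, ...) {
  cat("Mann-Whitney U comparison (", x$method, ")\n", sep = "")
  cat("  U = ", x$U, ", p = ", format.pval(x$p_value), sep = "")
  if (x$n_comparisons > 1) {
    cat(", Bonferroni-adjusted p = ", format.pval(x$p_adjusted),
        " (m = ", x$n_comparisons, ")", sep = "")
  }
  cat("\n")
  print(x$groups)
  invisible(x)
}

#' Circular summary of angle data
#'
#' Mean direction and mean resultant length of a sample of angles, treated
#' as directions on the circle.
#'
#' @param angles numeric, degrees.
#' @param period circular period in degrees (360 for directions; use 180 for
#'   axial data such as division planes).
#' @return A one-row tibble with `mean_direction` (degrees, in
#'   `[0, period)`) and `resultant_length` (0 = uniform, 1 = concentrated).
#' @export
angle_summary <- function(angles, period = 180) {
  th <- angles * 2 * pi / period
  C <- mean(cos(th)); S <- mean(sin(th))
  tibble::tibble(
    mean_direction = (atan2(S, C) * period / (2 * pi)) %% period,
    resultant_length = sqrt(C^2 + S^2))
}

#' Protrusion and bifacial morphometrics
#'
#' Quantifies the two preset phenotypes through three complementary
#' signatures:
#'
#' * `protrusion_height` — the largest outward excursion of the adaxial-L1
#'   boundary beyond the chord joining the two adaxial-abaxial junctions
#'   (only vertices projecting between the junctions count), in mean cell
#'   diameters (`2 sqrt(S/pi)` averaged over cells).  This captures
#'   finger-like appendages directly.
#' * `adaxial_share` — adaxial-L1 cells as a fraction of all L1 cells.
#'   Bifacial growth expands the adaxial surface (longitudinal divisions in
#'   adaxial L2/L3 keep feeding vertices into the adaxial epidermis, whose
#'   cells then divide by the neighbour rule); the share rises from about
#'   0.17 in the initial section to 0.35-0.4.  Periclinal stacking leaves
#'   the adaxial epidermis almost unchanged.
#' * `inner_fraction` — cells deeper than L3 as a fraction of all cells.
#'   Periclinal division increases the number of cell layers by definition,
#'   driving this fraction from about 0.19 (compact initial disc) above
#'   0.3; surface-expanding growth thins the tissue and drives it below
#'   0.1.
#'
#' A tissue classifies as `"protrusion"` when `inner_fraction > 0.25`
#' (layer accumulation) or when a literal outgrowth is present
#' (`protrusion_height > cutoff` with a non-expanded adaxial surface,
#' `adaxial_share <= 0.25`); otherwise `"bifacial"`.  The fraction cutoffs
#' were calibrated once on pilot runs of the two presets at the default
#' problem size and then frozen; see the methods vignette.  The bifacial
#' aspect ratio (extent along the adaxial growth axis over extent along the
#' junction chord) is reported for shape comparisons.
#'
#' @param tissue a [leaf_tissue()] with identities assigned.
#' @param cutoff geometric classification cutoff in cell diameters.
#' @return One-row tibble: `protrusion_height`, `aspect_ratio`,
#'   `adaxial_share`, `inner_fraction`, `classification`.
#' @export
protrusion_index <- function(tissue, cutoff = 2) {
  st <- tissue$states
  if (!any(st$identity == "adaxial") || !any(st$identity == "abaxial")) {
    stop("identities missing: need adaxial and abaxial L1 cells")
  }
  topo <- tissue_topology(tissue)
  centroid <- function(i) colMeans(tissue$vertices[tissue$cells[[i]], , drop = FALSE])
  cen <- t(vapply(seq_along(tissue$cells), centroid, numeric(2)))
  cen_all <- colMeans(cen)
  adax <- st$identity == "adaxial"
  cen_ad <- colMeans(cen[adax, , drop = FALSE])
  nhat <- cen_ad - cen_all
  nhat <- nhat / sqrt(sum(nhat^2))

  # junction anchor points: midpoints between the flanking cells of the two
  # identity transitions along the boundary cell order
  bc <- topo$boundary_cells
  idb <- st$identity[bc]
  nb <- length(bc)
  flips <- which(idb != idb[c(2:nb, 1)])
  if (length(flips) != 2) {
    stop("expected exactly 2 adaxial-abaxial junctions, found ", length(flips))
  }
  anchors <- t(vapply(flips, function(f) {
    (cen[bc[f], ] + cen[bc[f %% nb + 1], ]) / 2
  }, numeric(2)))
  that <- anchors[2, ] - anchors[1, ]
  that <- that / sqrt(sum(that^2))
  # outward signed distance from the junction chord
  sgn <- sign(sum(c(-that[2], that[1]) * nhat))
  if (sgn == 0) sgn <- 1
  perp <- sgn * c(-that[2], that[1])

  ad_edges <- which(topo$outer & adax[topo$cell1])
  ad_v <- unique(c(topo$edge_a[ad_edges], topo$edge_b[ad_edges]))
  rel <- tissue$vertices[ad_v, , drop = FALSE] -
    matrix(anchors[1, ], length(ad_v), 2, byrow = TRUE)
  mean_diam <- mean(2 * sqrt(cell_areas(tissue) / pi))
  # only vertices projecting between the junction anchors count: an outgrowth
  # rises from the chord, whereas bifacial wings carry the junctions with
  # them and their flanks project outside the segment
  chord_len <- sqrt(sum((anchors[2, ] - anchors[1, ])^2))
  along_chord <- as.numeric(rel %*% that)
  inside <- along_chord >= 0 & along_chord <= chord_len
  if (!any(inside)) inside <- rep(TRUE, length(along_chord))
  height <- max(rel[inside, , drop = FALSE] %*% perp) / mean_diam

  B <- tissue$vertices[topo$boundary_cycle, , drop = FALSE]
  chordwise <- diff(range(B %*% that))
  axial <- diff(range(B %*% perp))

  tissue <- classify_layers(tissue, topo)
  lay <- tissue$states$layer
  adax_share <- sum(adax) / sum(topo$l1)
  inner_frac <- mean(lay == "inner")
  protruding <- inner_frac > 0.25 ||
    (height > cutoff && adax_share <= 0.25)
  tibble::tibble(protrusion_height = height,
                 aspect_ratio = axial / chordwise,
                 adaxial_share = adax_share,
                 inner_fraction = inner_frac,
                 classification = ifelse(protruding, "protrusion",
                                         "bifacial"))
}

#' Expression-boundary detection on an intensity profile
#'
#' Reproduces the signal-quantification procedure for in-situ expression
#' domains: a cubic smoothing spline (generalized cross-validation by
#' default) is fitted to ordered (position, grey value) points along an
#' epidermal path, the backward differences of the fitted values are
#' computed, and boundaries between signal-positive and -negative stretches
#' are reported at the local maxima (steepest rise) and minima (steepest
#' fall) of the backward difference whose magnitude exceeds the noise floor.
#' A flat or monotone-trend profile yields no boundary (empty result).
#'
#' @param position strictly increasing positions (cell index or arc length);
#'   at least 5 points.
#' @param value grey values at those positions.
#' @param noise_floor minimum |backward difference| for a boundary; default
#'   `3 * mad(diff(fitted))`.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()] (default: GCV).
#' @return A tibble with one row per boundary, ordered by position:
#'   `position`, `index`, `sign` (`"rise"`/`"fall"`), `magnitude`.
#' @examples
#' prof <- c(rep(100, 10), rep(10, 10)) + rnorm(20, 0, 3)
#' expression_boundary(1:20, prof)
#' @export
expression_boundary <- function(position, value, noise_floor = NULL,
                                spar = NULL) {
  if (length(position) < 5) stop("profile needs at least 5 points")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (length(value) != length(position)) stop("position/value length mismatch")
  fit <- if (is.null(spar)) {
    stats::smooth.spline(position, value, cv = FALSE)
  } else {
    stats::smooth.spline(position, value, spar = spar)
  }
  f <- stats::predict(fit, position)$y
  d <- diff(f)  # d[i] = f[i+1] - f[i], the backward difference at i+1
  if (is.null(noise_floor)) {
    # robust baseline wiggle (mad), guarded against fitter ripple on flat
    # profiles and against minor inflections far below the dominant step
    noise_floor <- max(3 * stats::mad(d), 0.25 * max(abs(d)),
                       1e-6 * max(abs(value), 1))
  }
  n <- length(d)
  out <- list()
  for (i in 2:(n - 1)) {
    if (abs(d[i]) <= noise_floor) next
    if (d[i] > d[i - 1] && d[i] > d[i + 1] && d[i] > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        position = position[i + 1], index = i + 1L, sign = "rise",
        magnitude = d[i])
    } else if (d[i] < d[i - 1] && d[i] < d[i + 1] && d[i] < 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        position = position[i + 1], index = i + 1L, sign = "fall",
        magnitude = d[i])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(position = numeric(), index = integer(),
                          sign = character(), magnitude = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), position)
}
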