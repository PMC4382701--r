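test_that("edge-count-dependent target area follows the printed formula", {
  expect_equal(target_area(6), 1)
  expect_equal(target_area(4), 4 * tan(pi / 6) / (6 * tan(pi / 4)),
               tolerance = 1e-12)
  expect_equal(target_area(4), 0.3849, tolerance = 1e-4)
  expect_equal(target_area(3), 1 / 6, tolerance = 1e-12)
  expect_true(all(diff(target_area(3:20)) > 0))  # strictly increasing
  expect_error(target_area(2), "at least 3")
})

test_that("potential energy matches term-by-term closed forms", {
  p <- model_params()
  # unit-edge regular hexagon: area equals the target exactly, so the area
  # term vanishes and only the edge and outer-wall terms remain
  hexa <- ngon_tissue(6, rad = 1)
  L <- cell_geometry(hexa, 1)$edge_lengths[1]
  expect_equal(L, 1, tolerance = 1e-12)
  expect_equal(cell_geometry(hexa, 1)$area, p$cell_area_scale,
               tolerance = 1e-12)
  U <- potential_energy(hexa, p)
  expect_equal(U, 6 * (p$K_B * L + p$K_R / L) +
                  6 * p$K_E / 2 * (L - p$L_E)^2, tolerance = 1e-12)

  # the edge term K_B L + K_R / L is minimized at L* = sqrt(K_R / K_B) = 0.1
  Lstar <- sqrt(p$K_R / p$K_B)
  expect_equal(Lstar, 0.1)
  dterm <- function(L) p$K_B - p$K_R / L^2
  expect_equal(dterm(0.1), 0)
  # shrinking an edge raises the energy without bound
  edge_term <- function(L) p$K_B * L + p$K_R / L
  expect_true(all(diff(edge_term(c(0.1, 0.01, 0.001, 1e-5))) > 0))
  expect_gt(edge_term(1e-8), 1e4)
})

test_that("R and compiled energies agree", {
  p <- model_params()
  for (tis in list(unit_square(), onion_tissue(4, 9), default_mesh())) {
    expect_equal(potential_energy(tis, p),
                 pitchersim:::cpp_energy(tis$vertices,
                                         pitchersim:::engine_topo(tis), p),
                 tolerance = 1e-12)
  }
})

test_that("analytic forces match central finite differences of the energy", {
  p <- model_params()
  # unrelaxed fixtures so force components are O(1)
  set.seed(3)
  for (tis in list(onion_tissue(4, 9), strip_tissue(4))) {
    tis$vertices <- tis$vertices + matrix(stats::runif(length(tis$vertices),
                                                       -0.05, 0.05),
                                          ncol = 2)
    F <- vertex_forces(tis, p)
    scale <- max(abs(F))
    h <- 1e-6
    for (j in sample(nrow(tis$vertices), min(15, nrow(tis$vertices)))) {
      for (d in 1:2) {
        tp <- tis; tp$vertices[j, d] <- tp$vertices[j, d] + h
        tm <- tis; tm$vertices[j, d] <- tm$vertices[j, d] - h
        fd <- -(potential_energy(tp, p) - potential_energy(tm, p)) / (2 * h)
        expect_equal(F[j, d], fd, tolerance = 1e-4 * max(scale, abs(fd)))
      }
    }
  }
})

test_that("forces vanish at a minimum and are translation invariant", {
  p <- model_params()
  tis <- pitchersim:::relax_tissue(ngon_tissue(6, 0.7), p,
                                   tol = 1e-14, max_steps = 400000)
  F <- vertex_forces(tis, p)
  expect_lt(max(abs(F)), 1e-8)

  tis2 <- default_mesh()
  F1 <- vertex_forces(tis2, p)
  tis3 <- tis2
  tis3$vertices <- tis3$vertices + matrix(c(3.7, -1.2), nrow(tis3$vertices),
                                          2, byrow = TRUE)
  expect_equal(vertex_forces(tis3, p), F1, tolerance = 1e-9)
})

test_that("RK4 integration is a fixed point at equilibrium and 4th order", {
  p <- model_params()
  # fixed point: equilibrated mesh does not move
  tis <- pitchersim:::relax_tissue(onion_tissue(3, 8), p, tol = 1e-12,
                                   max_steps = 400000)
  tis2 <- integrate_step(tis, p, n_steps = 1)
  expect_equal(tis2$vertices, tis$vertices, tolerance = 1e-9)

  # order: the defect between one dt step and two dt/2 steps scales ~dt^5,
  # so halving dt shrinks it ~32x
  tis <- onion_tissue(3, 8)
  defect <- function(dt) {
    p1 <- model_params(dt = dt); p2 <- model_params(dt = dt / 2)
    a <- integrate_step(tis, p1, 1)$vertices
    b <- integrate_step(integrate_step(tis, p2, 1), p2, 1)$vertices
    max(abs(a - b))
  }
  r <- defect(0.08) / defect(0.04)
  expect_gt(r, 12); expect_lt(r, 80)
})

test_that("energy is non-increasing along the gradient flow", {
  p <- model_params()
  for (tis in list(default_mesh(), onion_tissue(4, 10))) {
    tis <- integrate_step(tis, p, n_steps = 1000, record_energy = TRUE)
    en <- attr(tis, "energy")
    expect_length(en, 1001)
    expect_true(all(diff(en) <= 1e-12))
  }
})

test_that("a relaxed isolated N-gon attains its target area", {
  # with weak edge terms the area term dominates and S -> s(N) within 2%
  # (area unit set to 1 so the relative target is read off directly)
  p <- model_params(K_B = 1e-4, K_R = 1e-8, K_E = 1e-6, cell_area_scale = 1)
  for (n in c(4, 6, 8)) {
    tis <- pitchersim:::relax_tissue(ngon_tissue(n, rad = 0.8), p,
                                     tol = 1e-10, max_steps = 100000)
    S <- pitchersim:::cell_areas(tis)
    expect_equal(S, target_area(n), tolerance = 0.02)
  }
})
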