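test_that("an isolated source cell reaches the A/B fixed point", {
  tis <- unit_square()
  p <- model_params()
  src <- list(u = 1, v = 1, w = 1)
  tis <- morphogen_step(tis, p, n_steps = 20000, sources = src)
  expect_equal(tis$states$u, p$A_u / p$B_u, tolerance = 1e-6)  # u* = 2
  expect_equal(tis$states$v, p$A_v / p$B_v, tolerance = 1e-6)
  expect_equal(steady_state(tis, p, "u", sources = src), 2)
})

test_that("two-cell chain steady state solves to (2/3, 1/3)", {
  tis <- strip_tissue(2)
  p <- model_params(A_u = 1, B_u = 1, D_u = 1)
  z <- steady_state(tis, p, "u", sources = list(u = 1))
  expect_equal(z, c(2 / 3, 1 / 3), tolerance = 1e-12)
  tis <- morphogen_step(tis, p, n_steps = 20000, sources = list(u = 1))
  expect_equal(tis$states$u, c(2 / 3, 1 / 3), tolerance = 1e-6)
})

test_that("Euler trajectories converge to the direct linear solve", {
  p <- model_params()
  # ring of cells (wedge disc adjacency), one source
  tis <- wedge_disc(4, rep("abaxial", 4))
  src <- list(u = 1, v = 1, w = 1)
  tis2 <- morphogen_step(tis, p, n_steps = 30000, sources = src)
  for (sp in c("u", "v", "w")) {
    z <- steady_state(tis, p, sp, sources = src)
    expect_equal(tis2$states[[sp]], z, tolerance = 1e-6)
  }
  # full default mesh with the model's own source sets
  tis <- default_mesh()
  zu <- steady_state(tis, p, "u")
  tis2 <- morphogen_step(tis, p, n_steps = 30000)
  expect_equal(tis2$states$u, zu, tolerance = 1e-6)
})

test_that("steady state balances synthesis against degradation", {
  p <- model_params()
  tis <- default_mesh()
  for (sp in c("u", "v", "w")) {
    z <- steady_state(tis, p, sp)
    n_src <- sum(pitchersim:::morphogen_sources(tis)[[sp]])
    A <- p[[paste0("A_", sp)]]; B <- p[[paste0("B_", sp)]]
    expect_equal(A * n_src, B * sum(z), tolerance = 1e-6)
  }
})

test_that("steady state obeys the maximum principle and distance decay", {
  p <- model_params()
  tis <- default_mesh()
  z <- steady_state(tis, p, "u")
  src <- pitchersim:::morphogen_sources(tis)$u == 1
  expect_gte(min(z[src]), max(z[!src]))  # maximal at the sources

  # on a path graph the concentration strictly decreases with distance
  chain <- strip_tissue(8)
  z <- steady_state(chain, p, "u", sources = list(u = 1))
  expect_true(all(diff(z) < 0))
})

test_that("the steady state is linear in the synthesis rate", {
  tis <- wedge_disc(6, rep("abaxial", 6))
  src <- list(u = 1, w = 2)
  z1 <- steady_state(tis, model_params(A_w = 1), "w", sources = src)
  z2 <- steady_state(tis, model_params(A_w = 2), "w", sources = src)
  expect_equal(z2, 2 * z1, tolerance = 1e-12)
})

test_that("decoupled cells (D = 0) hold A/B on sources and 0 elsewhere", {
  tis <- strip_tissue(3)
  p <- model_params(D_u = 0)
  z <- steady_state(tis, p, "u", sources = list(u = 2))
  expect_equal(z, c(0, p$A_u / p$B_u, 0))
})

test_that("R and compiled morphogen steps agree", {
  p <- model_params()
  tis <- default_mesh()
  tis$states$u <- stats::runif(length(tis$cells))
  tis$states$v <- stats::runif(length(tis$cells))
  tis$states$w <- stats::runif(length(tis$cells))
  r1 <- morphogen_step(tis, p, n_steps = 3)
  r2 <- pitchersim:::engine_chunk(tis, p, 3, check_divisions = FALSE,
                                  clocks_on = FALSE, quiesce = FALSE)
  expect_equal(r1$states$u, r2$u, tolerance = 1e-12)
  expect_equal(r1$states$v, r2$v, tolerance = 1e-12)
  expect_equal(r1$states$w, r2$w, tolerance = 1e-12)
})
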