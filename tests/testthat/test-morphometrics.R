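test_that("division angles fold correctly against a flat surface", {
  # strip tissue: straight boundary along x
  tis <- strip_tissue(5)
  ctr <- c(2.5, 0.5)
  horiz <- division_angle(tis, ctr - c(0.3, 0), ctr + c(0.3, 0))
  vert <- division_angle(tis, ctr - c(0, 0.3), ctr + c(0, 0.3))
  expect_equal(horiz, 0, tolerance = 1e-6)   # periclinal
  expect_equal(vert, 90, tolerance = 1e-6)   # longitudinal

  # boundary rotated by 30 degrees, division line vertical -> 60 degrees
  rot <- pi / 6
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  tis2 <- tis
  tis2$vertices <- tis$vertices %*% t(R)
  c2 <- as.numeric(R %*% ctr)
  expect_equal(division_angle(tis2, c2 - c(0, 0.3), c2 + c(0, 0.3)), 60,
               tolerance = 1e-6)
  # all outputs live in [0, 90]
  set.seed(2)
  for (k in 1:20) {
    th <- stats::runif(1, 0, 2 * pi)
    a <- division_angle(tis, ctr, ctr + 0.3 * c(cos(th), sin(th)))
    expect_gte(a, 0); expect_lte(a, 90)
  }
})

test_that("Mann-Whitney comparison handles identical and separated groups", {
  x <- c(10, 20, 30)
  t1 <- compare_angle_distributions(x, x)
  expect_equal(t1$p_value, 1)

  t2 <- compare_angle_distributions(c(1, 2, 3), c(80, 85, 88))
  expect_equal(t2$U, 0)  # first group uniformly smaller
  # exact two-sided p for complete separation at n1 = n2 = 3: 2/20
  expect_equal(t2$p_value, 0.1)

  expect_error(compare_angle_distributions(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("exact enumeration agrees with wilcox.test and the approximation", {
  x <- c(12, 25, 31, 40, 47, 55, 61, 70)
  y <- c(18, 28, 39, 44, 52, 64, 72, 80)
  ours <- compare_angle_distributions(x, y, n_exact = 8)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # normal approximation: within 1e-3 of the exact tail p for clearly
  # separated groups; within 1e-2 across arbitrary samples at n = 8
  xs <- c(5, 8, 11, 14, 17, 20, 23, 26)
  ys <- c(55, 58, 62, 66, 70, 74, 78, 82)
  exs <- compare_angle_distributions(xs, ys, n_exact = 8)
  aps <- compare_angle_distributions(xs, ys, n_exact = 0)
  expect_equal(aps$p_value, exs$p_value, tolerance = 1e-3)
  set.seed(8)
  for (k in 1:10) {
    x <- stats::runif(8, 0, 90); y <- stats::runif(8, 0, 90)
    d <- abs(compare_angle_distributions(x, y, n_exact = 8)$p_value -
             compare_angle_distributions(x, y, n_exact = 0)$p_value)
    expect_lt(d, 0.02)
  }
  # Bonferroni adjustment multiplies and caps at 1
  fam <- compare_angle_distributions(xs, ys, n_exact = 8, n_comparisons = 3)
  expect_equal(fam$p_adjusted, min(1, 3 * fam$p_value))
})

test_that("tidy and glance methods expose the comparison table", {
  t2 <- compare_angle_distributions(c(1, 2, 3), c(80, 85, 88))
  td <- tidy(t2)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(c("median", "q1", "q3", "U", "p_value") %in% names(td)))
  expect_equal(nrow(glance(t2)), 1)
})

test_that("circular summaries behave at the extremes", {
  s <- angle_summary(rep(30, 10), period = 180)
  expect_equal(s$mean_direction, 30, tolerance = 1e-9)
  expect_equal(s$resultant_length, 1, tolerance = 1e-12)
  u <- angle_summary(seq(0, 179, by = 1), period = 180)
  expect_lt(u$resultant_length, 0.02)
})

test_that("protrusion morphometrics separate a disc from a finger", {
  disc <- wedge_disc(36, c(rep("adaxial", 6), rep("abaxial", 30)))
  pr <- protrusion_index(disc)
  expect_equal(pr$classification, "bifacial")
  expect_lt(pr$protrusion_height, 2)

  finger <- finger_tissue(len = 7)
  pr2 <- protrusion_index(finger)
  expect_equal(pr2$classification, "protrusion")
  expect_gt(pr2$protrusion_height, 2)

  # classification invariant under rigid motion
  rot <- 0.83
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  f2 <- finger
  f2$vertices <- finger$vertices %*% t(R) +
    matrix(c(11, -4), nrow(finger$vertices), 2, byrow = TRUE)
  pr3 <- protrusion_index(f2)
  expect_equal(pr3$classification, "protrusion")
  expect_equal(pr3$protrusion_height, pr2$protrusion_height, tolerance = 1e-9)

  d2 <- wedge_disc(36, rep("none", 36))
  expect_error(protrusion_index(d2), "identities")
})

test_that("expression boundaries are recovered from step profiles", {
  # profiles sampled per pixel along the epidermal path (8 px per cell),
  # positions in cell units
  px <- 8
  pos <- seq(1 / px, 20, by = 1 / px)
  set.seed(21)
  # clean step between cells 10 and 11: one falling boundary within 1 cell
  val <- ifelse(pos <= 10.5, 100, 10) + stats::rnorm(length(pos), 0, 5)
  b <- expression_boundary(pos, val)
  falls <- b[b$sign == "fall", ]
  expect_equal(nrow(falls), 1)
  expect_lte(abs(falls$position - 10.5), 1)

  # constant profile: nothing to find
  expect_equal(nrow(expression_boundary(pos, rep(50, length(pos)))), 0)

  # two-step staircase: two rising boundaries, in order, each within 1 cell
  val <- ifelse(pos <= 8, 10, ifelse(pos <= 16, 60, 120)) +
    stats::rnorm(length(pos), 0, 3)
  b2 <- expression_boundary(pos, val)
  rises <- b2[b2$sign == "rise", ]
  expect_equal(nrow(rises), 2)
  expect_true(all(diff(rises$position) > 0))
  expect_lte(abs(rises$position[1] - 8), 1)
  expect_lte(abs(rises$position[2] - 16), 1)

  expect_error(expression_boundary(1:4, 1:4), "at least 5")
  expect_error(expression_boundary(c(1, 2, 2, 3, 4), 1:5), "increasing")
})

test_that("boundary recovery holds across replicates at SNR 5", {
  px <- 8
  pos <- seq(1 / px, 20, by = 1 / px)
  set.seed(77)
  hits <- 0
  for (k in 1:100) {
    val <- ifelse(pos <= 10.5, 100, 10) +
      stats::rnorm(length(pos), 0, 90 / 5)
    b <- expression_boundary(pos, val)
    falls <- b[b$sign == "fall", ]
    if (nrow(falls) >= 1 && min(abs(falls$position - 10.5)) <= 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 95)
})
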