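long_source <- function(d = 1, R = 2, iso = 1, half = 40) {
  data.frame(
    ax = -half, ay = 0, az = 0, bx = half, by = 0, bz = 0,
    d = d, R = R, lambda = lambda_weight(d, R, iso),
    node_a = 1L, node_b = 2L
  )
}

test_that("quartic kernel matches its closed form and support", {
  expect_equal(quartic_kernel(0, 1), 1)
  expect_equal(quartic_kernel(1, 1), 0)
  expect_equal(quartic_kernel(0.5, 1), 0.5625) # (1 - 0.25)^2
  expect_equal(quartic_kernel(2, 1), 0)
  # continuity at the support boundary
  expect_lt(quartic_kernel(1 - 1e-8, 1), 1e-14)
  expect_error(quartic_kernel(-0.1, 1), "non-negative")
})

test_that("lambda_weight reproduces the analytic values", {
  expect_equal(lambda_weight(1, 2, 1), 15 * 16 / (16 * 3^2.5))
  expect_equal(lambda_weight(1, 2, 1), 0.96225045, tolerance = 1e-7)
  expect_equal(lambda_weight(0, 1, 1), 0.9375) # degenerates to 15T/(16R)
  expect_equal(lambda_weight(1, 2, 0), 0) # linear in the iso-value
  expect_error(lambda_weight(2, 2, 1), "undefined")
})

test_that("infinite-line closed form hits the iso-value at x = d", {
  lam <- lambda_weight(1, 2, 1)
  expect_equal(line_field_closed_form(1, lam, 2), 1, tolerance = 1e-14)
  expect_equal(line_field_closed_form(2, lam, 2), 0)
  expect_equal(line_field_closed_form(0, lam, 2), (4 / 3)^2.5, tolerance = 1e-7)
  # 1000 random (d, R = 2d, T) triples: F(d) = T to machine precision
  set.seed(7)
  d <- runif(1000, 0.1, 10)
  R <- 2 * d
  iso <- runif(1000, 0.5, 2)
  lam <- lambda_weight(d, R, iso)
  expect_equal(line_field_closed_form(d, lam, R), iso, tolerance = 1e-12)
})

test_that("closed form equals numeric line quadrature of the kernel", {
  # independent oracle: integrate the quartic kernel along an infinite line
  # at perpendicular distance x (the integrand vanishes beyond the support)
  lam <- lambda_weight(1, 2, 1)
  for (x in c(0, 0.5, 1, 1.5)) {
    num <- 2 * lam * stats::integrate(
      function(t) quartic_kernel(sqrt(x^2 + t^2), 2),
      0, sqrt(4 - x^2), rel.tol = 1e-12
    )$value
    expect_equal(line_field_closed_form(x, lam, 2), num, tolerance = 1e-9)
  }
})

test_that("finite-segment quadrature approaches the infinite-line limit", {
  src <- long_source(d = 1, R = 2, half = 20) # length 20 * R
  expect_equal(field_value(c(0, 1, 0), src), 1, tolerance = 1e-2)
  src50 <- long_source(d = 1, R = 2, half = 50) # length 50 * R
  expect_equal(field_value(c(0, 1, 0), src50), 1, tolerance = 1e-3)
  # support: zero beyond the capsule
  expect_equal(field_value(c(0, 2.0001, 0), src), 0)
  expect_equal(field_value(c(60, 0, 0), src50), 0)
})

test_that("segment potential is additive over collinear sub-segments", {
  whole <- data.frame(
    ax = 0, ay = 0, az = 0, bx = 10, by = 0, bz = 0,
    d = 1, R = 2, lambda = lambda_weight(1, 2, 1), node_a = 1L, node_b = 2L
  )
  first <- whole; first$bx <- 4
  second <- whole; second$ax <- 4
  p <- rbind(c(3, 0.8, 0), c(5, 1.2, 0.3), c(9, 0.5, -0.5))
  expect_equal(
    segment_potential(p, first) + segment_potential(p, second),
    segment_potential(p, whole),
    tolerance = 1e-10
  )
})

test_that("superposition near a joint exceeds each single-segment field", {
  lam <- lambda_weight(1, 2, 1)
  s1 <- data.frame(ax = 0, ay = 0, az = 0, bx = 10, by = 0, bz = 0,
                   d = 1, R = 2, lambda = lam, node_a = 1L, node_b = 2L)
  s2 <- data.frame(ax = 0, ay = 0, az = 0, bx = 0, by = 10, bz = 0,
                   d = 1, R = 2, lambda = lam, node_a = 1L, node_b = 3L)
  both <- rbind(s1, s2)
  p <- c(0.7, 0.7, 0)
  expect_gt(field_value(p, both), field_value(p, s1))
  expect_gt(field_value(p, both), field_value(p, s2))
  expect_equal(field_value(p, both),
               field_value(p, s1) + field_value(p, s2))
  expect_equal(field_value(matrix(0, 0, 3), both), numeric(0))
})

test_that("grid-culled evaluation equals the brute-force full sum", {
  tree <- synth_morphology("random_binary", nodes = 40, seed = 5, taper = 0.9)
  src <- segment_sources(tree)
  set.seed(21)
  P <- cbind(runif(100, -30, 30), runif(100, -30, 30), runif(100, -30, 30))
  expect_identical(field_value(P, src), field_value(P, src, brute = TRUE))
})

test_that("gradient points toward the axis and vanishes outside support", {
  src <- long_source()
  g <- field_gradient(c(0, 1.5, 0), src)
  gn <- g / sqrt(sum(g^2))
  # antiparallel to the outward radial direction within 1 degree
  expect_gt(sum(gn * c(0, -1, 0)), cos(pi / 180))
  # on-axis symmetry: radial components cancel
  g0 <- field_gradient(c(0, 0, 0), src)
  expect_lt(abs(g0[2]), 1e-6)
  expect_lt(abs(g0[3]), 1e-6)
  # outside all supports: exactly zero
  expect_identical(as.numeric(field_gradient(c(0, 5, 0), src)), c(0, 0, 0))
})

test_that("projection lands on the iso-surface from both sides", {
  src <- long_source()
  out <- project_vertex(c(0, 1.5, 0), src, l_step = 0.2)
  expect_true(out$converged)
  expect_equal(sqrt(sum(out$position[2:3]^2)), 1, tolerance = 1e-3)
  inside <- project_vertex(c(0, 0.5, 0), src, l_step = 0.2)
  expect_true(inside$converged)
  expect_equal(sqrt(sum(inside$position[2:3]^2)), 1, tolerance = 1e-3)
  expect_gt(inside$position[2], 0.5) # moved outward

  # already on the surface: returned unchanged with 0 iterations
  onit <- project_vertex(c(0, 1, 0), src, l_step = 0.2)
  expect_equal(onit$iterations, 0L)
  expect_equal(as.numeric(onit$position), c(0, 1, 0))

  # zero gradient everywhere: flagged non-converged, point returned
  far <- project_vertex(c(0, 10, 0), src, l_step = 0.2)
  expect_false(far$converged)
  expect_equal(as.numeric(far$position), c(0, 10, 0))
})

test_that("each accepted projection step strictly decreases |F - T|", {
  src <- long_source()
  p <- c(0.3, 1.7, 0.2)
  errs <- numeric(0)
  pos <- p
  for (k in 1:20) {
    out <- project_vertex(pos, src, l_step = 0.15, max_iter = 1L, tol = 0)
    e <- abs(field_value(out$position, src) - 1)
    errs <- c(errs, e)
    if (identical(as.numeric(out$position), as.numeric(pos))) break
    pos <- as.numeric(out$position)
  }
  moved <- which(diff(errs) != 0)
  expect_true(all(diff(errs) <= 1e-15))
})

test_that("segment_sources derives offsets, radii and weights from the tree", {
  tr <- parse_swc(paste(
    "1 1 0 0 0 4 -1",
    "2 3 6 0 0 2 1",
    "3 3 12 0 0 1 2",
    sep = "\n"
  ))
  src <- segment_sources(tr, iso = 1, kernel_mult = 2)
  expect_equal(nrow(src), 2L)
  expect_equal(src$d, c(3, 1.5)) # mean of endpoint radii
  expect_equal(src$R, 2 * src$d)
  expect_equal(src$lambda, lambda_weight(src$d, src$R, 1))
  expect_error(segment_sources(tr, kernel_mult = 1), "exceed 1")
})
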