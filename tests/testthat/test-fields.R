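# Structured fields: analytic fixtures, interpolation, gradients, VTK I/O.

test_that("analytic fixtures evaluate their closed forms exactly at nodes", {
  # planar Poiseuille: centerline = 1.5 x mean speed
  f <- poiseuille_field(U = 0.2, H = 2e-3, ny = 41)
  expect_equal(max(f$u), 1.5 * 0.2)
  expect_equal(f$v, matrix(0, 41, 41))

  # tube profile: centerline = 2 x mean speed
  ft <- make_analytic_field(
    analytic_field_spec("poiseuille_tube", speed = 0.1, length = 4e-3,
                        extent = c(0.01, 4e-3)), 11, 41)
  expect_equal(max(ft$u), 2 * 0.1)

  # stagnation flow is divergence-free at every node
  fs <- make_analytic_field(
    analytic_field_spec("stagnation", speed = 0.1, length = 0.01,
                        extent = c(0.01, 0.01)), 21, 21)
  expect_equal(continuity_residual(fs), 0, tolerance = 1e-12)

  # Couette: constant shear-rate magnitude everywhere
  fc <- make_analytic_field(
    analytic_field_spec("couette", speed = 0.1, length = 2e-3,
                        extent = c(0.01, 2e-3)), 11, 21)
  gr <- sapply(seq(2e-4, 9e-4, by = 1e-4), function(y)
    shear_rate_magnitude(velocity_gradient_at(fc, c(5e-3, y))))
  expect_equal(gr, rep(0.1 / 2e-3, length(gr)), tolerance = 1e-10)

  expect_error(analytic_field_spec("vortex", 1, 1, c(1, 1)))
})

test_that("sampling interpolates multilinearly and flags out-of-domain", {
  f <- make_analytic_field(
    analytic_field_spec("uniform", speed = 0.3, length = 1e-2,
                        extent = c(0.04, 0.02)), 9, 5)
  expect_equal(sample_velocity(f, c(0.011, 0.013)),
               matrix(c(0.3, 0), 1, dimnames = list(NULL, c("u", "v"))))
  # exact at a node
  fp <- poiseuille_field()
  expect_equal(unname(sample_velocity(fp, c(fp$x[7], fp$y[13]))[1, 1]),
               fp$u[7, 13])
  # outside the bounding box: NA signal, not an error
  expect_true(all(is.na(sample_velocity(fp, c(-1e-3, 1e-3)))))

  # convexity: interpolated speed never exceeds the enclosing nodes
  set.seed(11)
  for (k in 1:50) {
    pt <- c(runif(1, 0, 0.02), runif(1, 0, 2e-3))
    sp <- sqrt(sum(sample_velocity(fp, pt)^2))
    expect_lte(sp, max(abs(fp$u)) + 1e-12)
  }
})

test_that("solid nodes are forced to zero velocity (no-slip consistent)", {
  msk <- matrix(TRUE, 5, 5); msk[3, 3] <- FALSE
  u <- matrix(1, 5, 5)
  f <- structured_field(seq(0, 1, length.out = 5), seq(0, 1, length.out = 5),
                        u, u * 0, mask = msk)
  expect_equal(f$u[3, 3], 0)
})

test_that("discrete gradients converge at second order on smooth fields", {
  # a non-polynomial profile so central differences are not trivially exact
  build <- function(n) {
    x <- seq(0, 1e-2, length.out = 5)
    y <- seq(0, 2e-3, length.out = n)
    u <- outer(rep(1, 5), sin(2 * pi * y / 2e-3)) * 0.1
    structured_field(x, y, u, u * 0)
  }
  err <- sapply(c(21, 41), function(n) {
    f <- build(n)
    pt <- c(5e-3, 0.67e-3)
    G <- velocity_gradient_at(f, pt)
    # compare at the nearest node to isolate differencing error
    iy <- which.min(abs(f$y - pt[2]))
    Gn <- velocity_gradient_at(f, c(5e-3, f$y[iy]))
    exact <- 0.1 * 2 * pi / 2e-3 * cos(2 * pi * f$y[iy] / 2e-3)
    abs(Gn[1, 2] - exact)
  })
  expect_gt(err[1] / err[2], 3.3)   # ~4x error drop when spacing halves

  # uniform field: zero tensor; Couette: single off-diagonal entry
  fu <- make_analytic_field(
    analytic_field_spec("uniform", speed = 0.3, length = 1, extent = c(1, 1)),
    5, 5)
  expect_equal(velocity_gradient_at(fu, c(0.5, 0.5)), matrix(0, 3, 3))
  fc <- make_analytic_field(
    analytic_field_spec("couette", speed = 0.2, length = 1, extent = c(1, 1)),
    9, 9)
  G <- velocity_gradient_at(fc, c(0.4, 0.6))
  expect_equal(G[1, 2], 0.2, tolerance = 1e-12)
  expect_equal(sum(abs(G)) - abs(G[1, 2]), 0, tolerance = 1e-12)
})

test_that("VTK round-trip preserves the field to formatting precision", {
  set.seed(3)
  nx <- 13; ny <- 7
  msk <- matrix(runif(nx * ny) > 0.2, nx, ny)
  f <- structured_field(sort(runif(nx)), sort(runif(ny)),
                        matrix(rnorm(nx * ny), nx, ny),
                        matrix(rnorm(nx * ny), nx, ny),
                        viscosity = matrix(runif(nx * ny, 0.001, 0.03),
                                           nx, ny),
                        mask = msk)
  p <- withr::local_tempfile(fileext = ".vtk")
  write_field(f, p)
  f2 <- read_field(p)
  scale <- max(abs(f$u))
  expect_lt(max(abs(f2$u - f$u)), 1e-10 * scale)
  expect_lt(max(abs(f2$v - f$v)), 1e-10 * scale)
  expect_equal(f2$viscosity, f$viscosity, tolerance = 1e-12)
  expect_identical(f2$mask, f$mask)
  expect_equal(f2$x, f$x, tolerance = 1e-14)
})

test_that("VTK reader validates structure and names the offending line", {
  fixture <- test_path("fixture-minimal.vtk")
  f <- read_field(fixture)
  expect_equal(dim(f$u), c(3L, 2L))
  expect_equal(f$u[, 1], c(0.1, 0.2, 0.3))

  # a field written without a velocity array is rejected
  p <- withr::local_tempfile(fileext = ".vtk")
  lines <- readLines(fixture)
  bad <- sub("VECTORS velocity double", "VECTORS speed double", lines)
  writeLines(bad, p)
  expect_error(read_field(p), "velocity")

  # malformed dimensions reported with the line content
  bad2 <- sub("DIMENSIONS 3 2 1", "DIMENSIONS 3 x 1", lines)
  writeLines(bad2, p)
  expect_error(read_field(p), "line")
})
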