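# Shear-rate magnitude and the Carreau shear-thinning law.

test_that("shear-rate magnitude reduces to the known closed forms", {
  expect_equal(shear_rate_magnitude(matrix(0, 3, 3)), 0)

  # pure rigid rotation: antisymmetric gradient has no strain
  W <- matrix(c(0, -7, 0, 7, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(shear_rate_magnitude(W), 0)

  # simple shear du/dy = G gives exactly G
  G <- matrix(0, 3, 3); G[1, 2] <- 123.4
  expect_equal(shear_rate_magnitude(G), 123.4)

  # 2x2 input embeds as zero out-of-plane components
  expect_equal(shear_rate_magnitude(matrix(c(0, 0, 50, 0), 2, 2)), 50)

  expect_error(shear_rate_magnitude(matrix(c(1, NA, 0, 0), 2, 2)),
               "non-finite")
})

test_that("shear-rate magnitude is frame-invariant and blind to rotation", {
  set.seed(42)
  for (k in 1:25) {
    A <- matrix(rnorm(9), 3, 3)
    g0 <- shear_rate_magnitude(A)
    # adding any antisymmetric tensor changes nothing
    W <- matrix(rnorm(9), 3, 3); W <- (W - t(W)) / 2
    expect_equal(shear_rate_magnitude(A + W), g0)
    # rotation of the frame: G' = Q G Q^T
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    expect_equal(shear_rate_magnitude(Q %*% A %*% t(Q)), g0,
                 tolerance = 1e-10)
  }
})

test_that("Carreau viscosity matches the printed plateaus and closed form", {
  cp <- carreau_parameters()
  expect_equal(carreau_viscosity(cp, 0), 0.025)
  expect_equal(carreau_viscosity(cp, 1e9), 0.00345, tolerance = 1e-5)
  # lambda * gamma = 1 evaluates the closed form directly
  expect_equal(carreau_viscosity(cp, 1 / cp$lambda_time),
               0.00345 + (0.025 - 0.00345) * 2^(-0.375))
  expect_error(carreau_viscosity(cp, -1), "non-negative")
  expect_error(carreau_parameters(mu_zero = 0.001), "exceed")
  expect_error(carreau_parameters(n_index = 1.5), "n_index")
})

test_that("Carreau viscosity is bounded and monotone for random parameters", {
  set.seed(7)
  for (k in 1:40) {
    mu_inf <- runif(1, 1e-4, 1e-2)
    cp <- carreau_parameters(mu_inf = mu_inf,
                             mu_zero = mu_inf * runif(1, 1.5, 50),
                             lambda_time = runif(1, 0.01, 100),
                             n_index = runif(1, 0.05, 0.95))
    g <- sort(c(0, 10^runif(20, -3, 7)))
    mu <- carreau_viscosity(cp, g)
    expect_true(all(mu <= cp$mu_zero + 1e-15))
    expect_true(all(mu >= cp$mu_inf - 1e-15))
    expect_true(all(diff(mu) <= 1e-15))  # non-increasing in shear rate
  }
})

test_that("scalar shear stress is mu(gamma) * gamma and strictly monotone", {
  cp <- carreau_parameters()
  expect_equal(scalar_shear_stress(cp, 0), 0)
  expect_equal(scalar_shear_stress(cp, 1e6),
               carreau_viscosity(cp, 1e6) * 1e6)
  # near-asymptotic regime: tau ~ mu_inf * gamma
  expect_equal(scalar_shear_stress(cp, 1e6), 0.00345 * 1e6,
               tolerance = 1e-2)
  g <- seq(0, 5000, length.out = 200)
  expect_true(all(diff(scalar_shear_stress(cp, g)) > 0))
})
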