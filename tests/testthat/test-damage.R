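# Platelet lysis index, residence/shear statistics, tip-volume metrics
# and flux integration.

test_that("per-step PLI matches the power law and its identities", {
  pl <- pli_parameters()
  expect_equal(step_pli(pl, 1, 1), 3.31e-6)
  expect_equal(step_pli(pl, 0, 5), 0)
  expect_equal(step_pli(pl, 5, 0), 0)
  # exponent identities checked by direct evaluation
  expect_equal(step_pli(pl, 1, 2) / step_pli(pl, 1, 1), 2^3.075)
  expect_equal(step_pli(pl, 2, 1) / step_pli(pl, 1, 1), 2^0.77)
  expect_error(step_pli(pl, -1, 1), "non-negative")
})

test_that("path-line PLI sums steps and is additive under concatenation", {
  pl <- pli_parameters()
  l1 <- synthetic_pathline(dt = c(0, 1e-3, 2e-3), tau = c(0, 4, 6))
  expect_equal(pathline_pli(pl, l1),
               step_pli(pl, 1e-3, 4) + step_pli(pl, 2e-3, 6))
  # single-step line equals step_pli of that step
  ls <- synthetic_pathline(dt = 5e-4, tau = 12)
  expect_equal(pathline_pli(pl, ls), step_pli(pl, 5e-4, 12))
  # concatenation additivity
  l2 <- synthetic_pathline(dt = c(3e-3, 1e-3), tau = c(2, 9))
  lcat <- synthetic_pathline(dt = c(0, 1e-3, 2e-3, 3e-3, 1e-3),
                             tau = c(0, 4, 6, 2, 9))
  expect_equal(pathline_pli(pl, lcat),
               pathline_pli(pl, l1) + pathline_pli(pl, l2))
  # constant-tau closed form: A * n * (T/n)^0.77 * tau^3.075
  n <- 10; T <- 0.02; tau <- 7
  lc <- synthetic_pathline(dt = rep(T / n, n), tau = rep(tau, n))
  expect_equal(pathline_pli(pl, lc), 3.31e-6 * n * (T / n)^0.77 * tau^3.075)
})

test_that("ensemble PLI averages per line and is monotone", {
  pl <- pli_parameters()
  l1 <- synthetic_pathline(dt = rep(1e-3, 5), tau = rep(5, 5))
  l2 <- synthetic_pathline(dt = rep(1e-3, 5), tau = rep(9, 5))
  expect_equal(ensemble_pli(pl, list(l1)), pathline_pli(pl, l1))
  expect_equal(ensemble_pli(pl, list(l1, l1)), pathline_pli(pl, l1))
  m <- ensemble_pli(pl, list(l1, l2))
  expect_gte(m, pathline_pli(pl, l1))
  expect_lte(m, pathline_pli(pl, l2))
  # raising any step's stress cannot decrease the ensemble value
  l2b <- synthetic_pathline(dt = rep(1e-3, 5), tau = c(9, 9, 11, 9, 9))
  expect_gt(ensemble_pli(pl, list(l1, l2b)), m)
  # per-step reading: grand sum over grand step count
  expect_equal(ensemble_pli(pl, list(l1, l2), mode = "per_step"),
               (pathline_pli(pl, l1) + pathline_pli(pl, l2)) / 10)
  expect_error(ensemble_pli(pl, list()), "empty")
})

test_that("residence time is the sum of step durations", {
  l <- synthetic_pathline(dt = c(0, 1e-3, 4e-3), tau = c(0, 1, 1))
  expect_equal(residence_time(l), 5e-3)
  expect_equal(residence_time(l), unname(l[nrow(l), "t"] - l[1, "t"]))
  l0 <- synthetic_pathline(dt = 0, tau = 0)
  expect_equal(residence_time(l0), 0)
})

test_that("platelet shear statistics are exposure-time weighted", {
  # constant 5 Pa: mean 5, nothing above 10
  lA <- synthetic_pathline(dt = rep(1e-3, 8), tau = rep(5, 8))
  sA <- platelet_shear_stats(list(lA))
  expect_equal(sA$mean_stress, 5)
  expect_equal(sA$pct_above, 0)
  # half the exposure at 20 Pa, half at 0: 50% above 10
  lB <- synthetic_pathline(dt = c(2e-3, 2e-3), tau = c(20, 0))
  sB <- platelet_shear_stats(list(lB))
  expect_equal(sB$pct_above, 50)
  expect_equal(sB$mean_stress, 10)
  # threshold 0: 100% whenever stress is positive
  expect_equal(platelet_shear_stats(list(lA), threshold = 1e-12)$pct_above,
               100)
  # time weighting differs from step weighting when durations vary
  lC <- synthetic_pathline(dt = c(1e-3, 9e-3), tau = c(20, 0))
  expect_equal(platelet_shear_stats(list(lC))$pct_above, 10)
  expect_equal(platelet_shear_stats(list(lC),
                                    weighting = "step")$pct_above, 50)
})

test_that("tip-volume statistics reproduce closed forms on fixtures", {
  mu <- 0.004
  newt <- newtonian_parameters(mu)
  # Couette: uniform stress tau0 everywhere in the region
  U <- 0.2; H <- 2e-3
  fc <- make_analytic_field(
    analytic_field_spec("couette", speed = U, length = H,
                        extent = c(0.01, H)), 21, 41)
  tau0 <- mu * U / H
  spec <- tip_volume_spec(threshold = 10, x_range = c(2e-3, 8e-3),
                          y_range = c(0.5e-3, 1.5e-3))
  tv <- tip_volume_stats(fc, spec, newt)
  expect_equal(tv$mean_stress, tau0, tolerance = 1e-10)
  expect_equal(tv$pct_above, 100 * (tau0 > 10))
  # with a threshold below tau0 the whole region is above
  spec2 <- tip_volume_spec(threshold = tau0 / 2, x_range = c(2e-3, 8e-3),
                           y_range = c(0.5e-3, 1.5e-3))
  expect_equal(tip_volume_stats(fc, spec2, newt)$pct_above, 100)

  # planar Poiseuille: linear stress profile, analytic channel average
  # tau(y) = 3 mu U |y'| / b^2, mean over [-b, b] = 3 mu U / (2 b)
  fp <- poiseuille_field(U = U, H = H, nx = 21, ny = 201)
  spec3 <- tip_volume_spec(threshold = 10, x_range = c(2e-3, 8e-3),
                           y_range = c(0, H))
  tv3 <- tip_volume_stats(fp, spec3, newt)
  b <- H / 2
  expect_equal(tv3$mean_stress, 3 * mu * U / (2 * b), tolerance = 5e-3)
  # max speed in the region is the centerline value
  expect_equal(tv3$max_speed, 1.5 * U)

  # monotone non-increasing in the threshold
  ths <- c(0.1, 0.5, 1, 2, 5)
  pcts <- sapply(ths, function(th)
    tip_volume_stats(fp, tip_volume_spec(threshold = th,
                                         x_range = c(2e-3, 8e-3),
                                         y_range = c(0, H)), newt)$pct_above)
  expect_true(all(diff(pcts) <= 1e-12))

  expect_error(
    tip_volume_stats(fp, tip_volume_spec(threshold = 1,
                                         x_range = c(1, 2),
                                         y_range = c(0, H)), newt),
    "no grid nodes|no fluid")
})

test_that("segment flux integrates uniform normal inflow exactly", {
  # uniform downward flow: v = -w everywhere
  nx <- 21; ny <- 21
  x <- seq(0, 0.01, length.out = nx); y <- seq(0, 0.01, length.out = ny)
  f <- structured_field(x, y, matrix(0, nx, ny), matrix(-0.05, nx, ny))
  q <- segment_flux(f, y = 5e-3, x_range = c(2e-3, 8e-3))
  expect_equal(q, 0.05 * 6e-3, tolerance = 1e-12)
  # closed wall segment (zero velocity) carries nothing
  f0 <- structured_field(x, y, matrix(0, nx, ny), matrix(0, nx, ny))
  expect_equal(segment_flux(f0, 5e-3, c(2e-3, 8e-3)), 0)
})
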