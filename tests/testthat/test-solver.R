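# Finite-volume SIMPLE solver: analytic verification and conservation.

test_that("Newtonian channel flow reproduces planar Poiseuille within 2%", {
  sol <- cached_solve("poiseuille_newt", function() {
    geom <- tip_geometry(vessel_width = 2e-3, vessel_length = 16e-3,
                         insertion_length = 0, tip_opening_length = 0)
    solve_steady(geom, boundary_spec(inlet_speed = 0.05),
                 newtonian_parameters(0.025),
                 solver_settings(spacing = 0.05e-3))   # 40 cells across
  })
  expect_true(sol$converged)
  H <- 2e-3
  ix <- which.min(abs(sol$field$x - 12e-3))
  prof <- sol$field$u[ix, ]
  exact <- 1.5 * 0.05 * (1 - ((sol$field$y - H / 2) / (H / 2))^2)
  expect_lt(max(abs(prof - exact)) / max(exact), 0.02)
})

test_that("converged solves conserve mass globally", {
  sol <- toy_solution("single")
  expect_true(sol$converged)
  bf <- boundary_fluxes(sol)
  expect_lt(abs(bf$net) / bf$inlet, 1e-5)
  # recovered outflow within the +/-0.25% analog of 400 +/- 1 mL/min
  expect_lt(abs(sol$outflow_ml_min - 400), 1)
})

test_that("hole and tip-opening fluxes partition the lumen outflow", {
  sol <- toy_solution("single")
  q_holes <- hole_flow_rate(sol, 1)
  q_tip <- tip_opening_flow_rate(sol)
  expect_equal(q_holes + q_tip, sol$outflow_ml_min, tolerance = 1e-3)
  expect_gt(q_holes, 0)
})

test_that("Carreau viscosity field stays within its plateaus", {
  sol <- toy_solution("single")
  expect_true(all(sol$field$viscosity >= 0.00345 - 1e-12))
  expect_true(all(sol$field$viscosity <= 0.025 + 1e-12))
})

test_that("continuity residual is zero for uniform flow and detects
           perturbations", {
  nx <- 21; ny <- 11
  f <- structured_field(seq(0, 0.02, length.out = nx),
                        seq(0, 0.01, length.out = ny),
                        matrix(0.3, nx, ny), matrix(0, nx, ny))
  expect_equal(continuity_residual(f), 0, tolerance = 1e-14)
  f$u[10, 6] <- 0.35
  expect_gt(continuity_residual(f), 0)
  # solver-grid residual of a converged solve is below tolerance
  sol <- toy_solution("single")
  expect_lt(continuity_residual(sol), 1e-5)
})

test_that("solves are deterministic: identical config, identical fields", {
  g <- tip_geometry(vessel_width = 2e-3, vessel_length = 8e-3,
                    insertion_length = 0, tip_opening_length = 0)
  st <- solver_settings(spacing = 0.1e-3)
  s1 <- solve_steady(g, boundary_spec(inlet_speed = 0.05),
                     newtonian_parameters(0.01), st)
  s2 <- solve_steady(g, boundary_spec(inlet_speed = 0.05),
                     newtonian_parameters(0.01), st)
  expect_identical(s1$field$u, s2$field$u)
  expect_identical(s1$p, s2$p)
})
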