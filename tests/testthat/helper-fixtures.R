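# Shared fixtures. Converged solves are expensive, so they are memoized in
# a session-level cache shared across test files.

.solve_cache <- new.env(parent = emptyenv())

cached_solve <- function(key, fn) {
  if (is.null(.solve_cache[[key]])) .solve_cache[[key]] <- fn()
  .solve_cache[[key]]
}

# Coarse toy solves used by several files (0.5 mm spacing keeps them fast).
toy_solution <- function(design = "single", spacing = 0.5e-3, ...) {
  key <- sprintf("%s_%g", design, spacing)
  cached_solve(key, function() {
    solve_steady(toy_tip_design(design, ...), boundary_spec(),
                 carreau_parameters(), solver_settings(spacing = spacing))
  })
}

# Planar Poiseuille fixture on a modest grid.
poiseuille_field <- function(U = 0.2, H = 2e-3, L = 0.02,
                             nx = 41, ny = 41, rheo = NULL) {
  make_analytic_field(
    analytic_field_spec("poiseuille_planar", speed = U, length = H,
                        extent = c(L, H)), nx, ny, rheo = rheo)
}

# A small pathline built directly from step data (t, tau, dt), for the
# damage metrics that only read the recorded columns.
synthetic_pathline <- function(dt, tau, gamma = tau / 0.00345) {
  n <- length(dt)
  m <- cbind(t = cumsum(dt), x = seq_len(n) * 1e-6, y = 0,
             up = 0.1, vp = 0, uf = 0.1, vf = 0,
             gamma_dot = gamma, tau = tau, dt = dt)
  attr(m, "termination") <- "exited_vessel_outlet"
  class(m) <- c("pathline", class(m))
  m
}
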