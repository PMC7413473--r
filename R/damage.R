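# Design scoring: the power-law platelet lysis index accumulated along
# path lines, platelet residence/shear statistics, Eulerian tip-volume
# statistics and side-hole flow rates. These mirror the standard
# comparison columns for catheter-tip designs: max velocity, average
# shear stress, percentage of volume (or exposure time) above a damage
# threshold, side-hole flow, residence time and overall PLI.

#' Platelet lysis index parameters
#'
#' The power-law blood-damage model \eqn{PLI = A\, t^{0.77} \tau^{3.075}}
#' with the Giersiepen-type constants: prefactor \eqn{A = 3.31\times
#' 10^{-6}}, time exponent 0.77, stress exponent 3.075.
#'
#' @param A Prefactor. @param time_exp Time exponent.
#' @param stress_exp Stress exponent.
#' @return An object of class `pli_parameters`.
#' @export
pli_parameters <- function(A = 3.31e-6, time_exp = 0.77, stress_exp = 3.075) {
  stop_unless(is_pos_scalar(A), "A must be positive")
  stop_unless(is_pos_scalar(time_exp), "time_exp must be positive")
  stop_unless(is_pos_scalar(stress_exp), "stress_exp must be positive")
  structure(list(A = A, time_exp = time_exp, stress_exp = stress_exp),
            class = "pli_parameters")
}

#' Per-step platelet lysis index
#'
#' \eqn{A \, dt^{0.77} \tau^{3.075}} for one exposure step. Vectorized.
#'
#' @param params A [pli_parameters()].
#' @param dt Step duration(s) (s), non-negative.
#' @param tau Scalar shear stress(es) (Pa), non-negative.
#' @return Dimensionless per-step damage contribution(s).
#' @export
step_pli <- function(params, dt, tau) {
  stopifnot(inherits(params, "pli_parameters"))
  stop_unless(all(dt >= 0), "dt must be non-negative")
  stop_unless(all(tau >= 0), "tau must be non-negative")
  params$A * dt^params$time_exp * tau^params$stress_exp
}

#' Path-line PLI
#'
#' Sum of the per-step PLI over all recorded steps of one path line
#' (additive under path concatenation). Note the step-size dependence
#' inherent to the per-step summation: \eqn{\sum dt^{0.77}} is
#' sub-additive in the step refinement, so the standard 0.5 um spatial
#' step is part of the metric's definition.
#'
#' @param params A [pli_parameters()].
#' @param line A [advance_platelet()] path line.
#' @return Dimensionless accumulated PLI.
#' @export
pathline_pli <- function(params, line) {
  stop_unless(nrow(line) >= 1, "path line has no records")
  sum(step_pli(params, line[, "dt"], line[, "tau"]))
}

#' Ensemble PLI
#'
#' Overall per-design magnitude: the PLI summed along each path line and
#' then averaged over lines (`mode = "per_line"`, the default). The
#' alternative per-step reading (grand sum over all steps divided by the
#' grand step count) is available as `mode = "per_step"`.
#'
#' @param params A [pli_parameters()].
#' @param lines A `pathline_set` or list of path lines.
#' @param mode Averaging convention, see Details.
#' @return Dimensionless overall PLI.
#' @export
ensemble_pli <- function(params, lines, mode = c("per_line", "per_step")) {
  mode <- match.arg(mode)
  lines <- as_pathline_list(lines)
  stop_unless(length(lines) >= 1, "empty path-line ensemble")
  per_line <- vapply(lines, function(l) pathline_pli(params, l), 0)
  if (mode == "per_line") return(mean(per_line))
  nsteps <- vapply(lines, function(l) sum(l[, "dt"] > 0), 0)
  sum(per_line) / max(sum(nsteps), 1)
}

as_pathline_list <- function(lines) {
  if (inherits(lines, "pathline_set")) lines$lines
  else if (inherits(lines, "pathline")) list(lines)
  else lines
}

#' Residence time of a path line
#'
#' Sum of the recorded step durations; equals last time minus first time
#' exactly.
#'
#' @param line A path line.
#' @return Residence time (s).
#' @export
residence_time <- function(line) {
  sum(line[, "dt"])
}

#' Platelet-ensemble shear statistics
#'
#' Exposure statistics over all steps of all lines: mean scalar shear
#' stress, percentage of exposure above the stress threshold, and mean
#' shear rate. Time-weighted by default (each step weighted by its
#' duration); `weighting = "step"` weights each recorded step equally.
#'
#' @param lines A `pathline_set` or list of path lines.
#' @param threshold Stress threshold (Pa). Default 10.
#' @param weighting `"time"` or `"step"`.
#' @return Named list: `mean_stress` (Pa), `pct_above` (0-100),
#'   `mean_shear_rate` (1/s).
#' @export
platelet_shear_stats <- function(lines, threshold = 10,
                                 weighting = c("time", "step")) {
  weighting <- match.arg(weighting)
  lines <- as_pathline_list(lines)
  stop_unless(length(lines) >= 1, "empty path-line ensemble")
  tau <- unlist(lapply(lines, function(l) l[, "tau"]))
  gam <- unlist(lapply(lines, function(l) l[, "gamma_dot"]))
  w <- if (weighting == "time")
    unlist(lapply(lines, function(l) l[, "dt"]))
  else unlist(lapply(lines, function(l) as.numeric(l[, "dt"] > 0)))
  W <- sum(w)
  if (W == 0) return(list(mean_stress = 0, pct_above = 0, mean_shear_rate = 0))
  list(mean_stress = sum(w * tau) / W,
       pct_above = 100 * sum(w[tau > threshold]) / W,
       mean_shear_rate = sum(w * gam) / W)
}

# ---- Eulerian tip-volume statistics ----------------------------------------

#' Tip-volume specification
#'
#' The fixed comparison region around the inflow lumen: it extends from
#' the distal tip backwards along the axis by `axial_extent` and spans the
#' lumen interior transversely, so that all compared designs are scored
#' over an identical region. Explicit `x_range` / `y_range` override the
#' geometry-derived placement (used for analytic fixtures).
#'
#' @param axial_extent Axial extent from the tip (m). Default 22 mm
#'   (reaches proximal of the most proximal default side-hole).
#' @param threshold Shear-stress threshold (Pa). Default 10, the usual
#'   platelet-activation level.
#' @param x_range,y_range Optional explicit region bounds (m).
#' @return An object of class `tip_volume_spec`.
#' @export
tip_volume_spec <- function(axial_extent = 22e-3, threshold = 10,
                            x_range = NULL, y_range = NULL) {
  stop_unless(is_pos_scalar(axial_extent), "axial_extent must be positive")
  stop_unless(is_pos_scalar(threshold), "threshold must be positive")
  structure(list(axial_extent = axial_extent, threshold = threshold,
                 x_range = x_range, y_range = y_range),
            class = "tip_volume_spec")
}

tip_region_bounds <- function(spec, geom = NULL, field = NULL) {
  if (!is.null(spec$x_range) && !is.null(spec$y_range))
    return(list(x = spec$x_range, y = spec$y_range))
  if (is.null(geom) && !is.null(field)) {
    meta <- attr(field, "domain_meta")
    stop_unless(!is.null(meta),
                "tip_volume_spec needs x_range/y_range or a solver field")
    return(list(x = c(meta$x_tip - spec$axial_extent, meta$x_tip),
                y = meta$lumen_y))
  }
  stopifnot(inherits(geom, "tip_geometry"))
  list(x = c(geom$insertion_length - spec$axial_extent,
             geom$insertion_length),
       y = geom$layout$y_lumen)
}

#' Tip-volume flow statistics
#'
#' Volume-weighted statistics of the field over the fixed tip region:
#' maximum node speed, mean scalar shear stress over fluid nodes, and the
#' percentage of fluid volume with stress above the threshold. Stress is
#' evaluated from the discrete shear-rate field and the supplied rheology.
#'
#' @param field A [structured_field()].
#' @param spec A [tip_volume_spec()].
#' @param rheo A [carreau_parameters()].
#' @param geometry Optional [tip_geometry()] to place the region (not
#'   needed for solver fields, which carry their geometry).
#' @return Named list: `max_speed` (m/s), `mean_stress` (Pa),
#'   `pct_above` (0-100), `n_nodes`.
#' @export
tip_volume_stats <- function(field, spec, rheo, geometry = NULL) {
  stopifnot(inherits(field, "structured_field"),
            inherits(spec, "tip_volume_spec"))
  b <- tip_region_bounds(spec, geometry, field)
  inx <- field$x >= b$x[1] - 1e-12 & field$x <= b$x[2] + 1e-12
  iny <- field$y >= b$y[1] - 1e-12 & field$y <= b$y[2] + 1e-12
  stop_unless(any(inx) && any(iny), "tip region contains no grid nodes")
  sel_mask <- field$mask[inx, iny, drop = FALSE]
  stop_unless(any(sel_mask), "tip region contains no fluid nodes")

  # solver fields carry their own wall-aware discrete shear-rate field;
  # bare fields fall back to central differences of the node velocities
  gam <- attr(field, "shear_rate")
  if (is.null(gam)) {
    gr <- field_gradients(field)
    gam <- shear_rate_components(gr$dudx, gr$dudy, gr$dvdx, gr$dvdy)
  }
  tau <- matrix(scalar_shear_stress(rheo, as.vector(gam)),
                length(field$x), length(field$y))
  sp <- sqrt(field$u^2 + field$v^2)

  # node volume weights from coordinate spacings (midpoint rule)
  wx <- node_weights(field$x)[inx]
  wy <- node_weights(field$y)[iny]
  W <- outer(wx, wy)
  W[!sel_mask] <- 0
  tau_r <- tau[inx, iny, drop = FALSE]
  sp_r <- sp[inx, iny, drop = FALSE]
  Wtot <- sum(W)
  list(max_speed = max(sp_r[sel_mask]),
       mean_stress = sum(W * tau_r) / Wtot,
       pct_above = 100 * sum(W[tau_r > spec$threshold]) / Wtot,
       n_nodes = sum(sel_mask))
}

node_weights <- function(ax) {
  n <- length(ax)
  if (n == 1) return(1)
  w <- numeric(n)
  w[1] <- (ax[2] - ax[1]) / 2
  w[n] <- (ax[n] - ax[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (ax[3:n] - ax[1:(n - 2)]) / 2
  w
}

# ---- fluxes -----------------------------------------------------------------

#' Side-hole flow rate of a converged solve
#'
#' Signed volumetric flux through a side-hole opening, integrated exactly
#' over the staggered faces on the lumen-side wall surface; positive into
#' the lumen. Reported on the 2D-equivalent volumetric scale (mL/min).
#' The sum of all hole fluxes and the tip-opening flux equals the lumen
#' outflow to within the continuity tolerance (discrete mass
#' conservation over the lumen control volume).
#'
#' @param sol A [solve_steady()] solution.
#' @param hole Hole index (1 = most proximal after ordering by position).
#' @return Flow rate (mL/min, 2D-equivalent).
#' @export
hole_flow_rate <- function(sol, hole = 1L) {
  stopifnot(inherits(sol, "flow_solution"))
  dom <- sol$domain
  stop_unless(length(dom$hole_cols) >= hole, "no such side-hole")
  cols <- dom$hole_cols[[hole]]
  # v on the inner wall surface face row; inflow into the lumen is -v
  q2d <- -sum(sol$v[cols, dom$j_face_top]) * dom$hx
  flux2d_to_ml_min(q2d, dom$geom$lumen_height)
}

#' Tip-opening flow rate of a converged solve
#'
#' Flux entering the lumen through the tip opening: the open end face plus
#' the upper cut-back, positive into the lumen (mL/min 2D-equivalent).
#'
#' @param sol A [solve_steady()] solution.
#' @return Flow rate (mL/min, 2D-equivalent).
#' @export
tip_opening_flow_rate <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  dom <- sol$domain
  stop_unless(length(dom$lumen_rows) > 0, "domain has no catheter lumen")
  q_end <- -sum(sol$u[dom$i_face_tip, dom$lumen_rows]) * dom$hy
  q_cut <- if (length(dom$tipcut_cols))
    -sum(sol$v[dom$tipcut_cols, dom$j_face_top]) * dom$hx else 0
  flux2d_to_ml_min(q_end + q_cut, dom$geom$lumen_height)
}

#' Volume flux through a horizontal segment of a field
#'
#' Integrates the interpolated vertical velocity across `x_range` at
#' height `y` by the midpoint rule on the grid columns (downward flux
#' positive, matching "into the lumen" for a hole in the upper catheter
#' wall). Used for flux checks on analytic fields.
#'
#' @param field A [structured_field()].
#' @param y Segment height (m).
#' @param x_range `c(x0, x1)` (m).
#' @param n Number of quadrature points (default 200).
#' @return Per-depth volumetric flux (m^2/s), downward positive.
#' @export
segment_flux <- function(field, y, x_range, n = 200) {
  xs <- seq(x_range[1], x_range[2], length.out = n + 1)
  xm <- (xs[-1] + xs[-(n + 1)]) / 2
  vel <- sample_velocity(field, cbind(xm, y))
  stop_unless(!anyNA(vel), "segment lies outside the field domain")
  -sum(vel[, 2]) * diff(x_range) / n
}

# ---- report -----------------------------------------------------------------

#' Per-design damage report
#'
#' Assembles the standard comparison row for one design: tip-volume
#' metrics (max speed, mean stress, % volume above threshold), side-hole
#' and tip-opening flows, and platelet metrics (mean residence time,
#' overall PLI, exposure-weighted stress/shear statistics).
#'
#' @param label Design label.
#' @param sol A [solve_steady()] solution (or `NULL` in fixture mode).
#' @param field The field scored (defaults to `sol$field`).
#' @param lines A `pathline_set` (or `NULL` if tracking was skipped).
#' @param tip_spec A [tip_volume_spec()].
#' @param pli_params A [pli_parameters()].
#' @param rheo A [carreau_parameters()].
#' @param geometry Optional [tip_geometry()] for region placement.
#' @return A one-row `data.frame` of class `damage_report`.
#' @export
damage_report <- function(label, sol = NULL, field = NULL, lines = NULL,
                          tip_spec = tip_volume_spec(),
                          pli_params = pli_parameters(),
                          rheo = carreau_parameters(), geometry = NULL) {
  if (is.null(field)) field <- sol$field
  stop_unless(!is.null(field), "need a solution or a field to score")
  tv <- tip_volume_stats(field, tip_spec, rheo, geometry)
  n_holes <- if (!is.null(sol)) length(sol$domain$hole_cols) else 0L
  hole_q <- if (n_holes > 0)
    vapply(seq_len(n_holes), function(k) hole_flow_rate(sol, k), 0)
  else numeric(0)
  rep <- data.frame(
    design = label,
    max_speed_m_s = tv$max_speed,
    mean_stress_pa = tv$mean_stress,
    pct_volume_above = tv$pct_above,
    side_hole_flow_ml_min = if (n_holes > 0) sum(hole_q) else NA_real_,
    tip_opening_flow_ml_min = if (!is.null(sol) &&
                                    length(sol$domain$lumen_rows) > 0)
      tip_opening_flow_rate(sol) else NA_real_,
    mean_residence_s = NA_real_, pli = NA_real_,
    platelet_mean_stress_pa = NA_real_, platelet_pct_above = NA_real_,
    platelet_mean_shear_s = NA_real_,
    stringsAsFactors = FALSE)
  if (n_holes > 0)
    for (k in seq_len(n_holes))
      rep[[sprintf("hole%d_flow_ml_min", k)]] <- hole_q[k]
  if (!is.null(lines)) {
    ll <- as_pathline_list(lines)
    ps <- platelet_shear_stats(ll, threshold = tip_spec$threshold)
    rep$mean_residence_s <- mean(vapply(ll, residence_time, 0))
    rep$pli <- ensemble_pli(pli_params, ll)
    rep$platelet_mean_stress_pa <- ps$mean_stress
    rep$platelet_pct_above <- ps$pct_above
    rep$platelet_mean_shear_s <- ps$mean_shear_rate
  }
  class(rep) <- c("damage_report", class(rep))
  rep
}

#' @exportS3Method
print.damage_report <- function(x, ...) {
  cat(sprintf("damage_report: %s\n", x$design[1]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
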