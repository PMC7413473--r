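# Orchestration: a single hierarchical run configuration, the
# rasterize -> solve -> seed -> track -> score pipeline with persisted
# artifacts, design comparison against a reference, and the
# grid-convergence study. The default pipeline is fully deterministic:
# identical configurations reproduce identical artifacts byte for byte.

#' Run configuration
#'
#' Bundles every stage's parameters for one design. All physical defaults
#' are the standard study conditions: 0.3 m/s vessel inflow, 400 mL/min
#' lumen outflow target, Carreau whole-blood constants, 2 um neutrally
#' buoyant platelets seeded 1 mm above the catheter surface, 0.5 um
#' tracking step, 10 Pa stress threshold, 16.5 mm hole-to-tip distance.
#'
#' @param geometry A [tip_geometry()].
#' @param boundary A [boundary_spec()].
#' @param rheology A [carreau_parameters()].
#' @param solver A [solver_settings()].
#' @param seeding A [seed_spec()].
#' @param integration An [integration_settings()].
#' @param pli A [pli_parameters()].
#' @param tip_volume A [tip_volume_spec()].
#' @param label Design label used in reports and file names.
#' @param field_source `"solve"`, or an [analytic_field_spec()] for
#'   fixture mode (the solver stage is bypassed and the analytic field is
#'   scored directly).
#' @param field_resolution `c(nx, ny)` nodes for fixture mode.
#' @param seed Random seed recorded in the config (the default pipeline
#'   has no stochastic stage; the seed exists for forward compatibility
#'   and is included in the config hash).
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = toy_tip_design("single"),
                       boundary = boundary_spec(),
                       rheology = carreau_parameters(),
                       solver = solver_settings(),
                       seeding = seed_spec(),
                       integration = integration_settings(),
                       pli = pli_parameters(),
                       tip_volume = tip_volume_spec(),
                       label = "design",
                       field_source = "solve",
                       field_resolution = c(161, 81),
                       seed = 1L) {
  stopifnot(inherits(geometry, "tip_geometry"),
            inherits(boundary, "boundary_spec"),
            inherits(rheology, "carreau_parameters"),
            inherits(solver, "solver_settings"),
            inherits(seeding, "seed_spec"),
            inherits(integration, "integration_settings"),
            inherits(pli, "pli_parameters"),
            inherits(tip_volume, "tip_volume_spec"))
  fixture <- inherits(field_source, "analytic_field_spec")
  if (!fixture)
    stop_unless(identical(field_source, "solve"),
                "field_source must be 'solve' or an analytic_field_spec")
  # cross-field consistency
  if (!fixture && length(geometry$holes) > 0) {
    y_plane <- geometry$layout$y_wall_up[2] + seeding$offset
    stop_unless(y_plane < geometry$vessel_width,
                "seeding plane (%g m) lies outside the vessel", y_plane)
  }
  if (!fixture && is.null(tip_volume$x_range)) {
    stop_unless(tip_volume$axial_extent <= geometry$insertion_length,
                "tip volume extends beyond the catheter base")
  }
  structure(list(geometry = geometry, boundary = boundary,
                 rheology = rheology, solver = solver, seeding = seeding,
                 integration = integration, pli = pli,
                 tip_volume = tip_volume, label = label,
                 field_source = field_source,
                 field_resolution = field_resolution,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @exportS3Method
print.run_config <- function(x, ...) {
  cat(sprintf("run_config '%s' (%s mode, hash %s)\n", x$label,
              if (identical(x$field_source, "solve")) "solve" else "fixture",
              config_hash(x)))
  print(x$geometry)
  invisible(x)
}

#' Configuration hash
#'
#' MD5 of the canonical YAML serialization; stamped on every artifact so
#' outputs can be traced to the exact configuration.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config_to_list(config)), tmp)
  unname(tools::md5sum(tmp))
}

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  geom <- config$geometry
  list(
    label = config$label, seed = config$seed,
    field_source = if (identical(config$field_source, "solve")) "solve"
      else strip(config$field_source),
    field_resolution = config$field_resolution,
    geometry = list(
      vessel_width = geom$vessel_width, vessel_length = geom$vessel_length,
      insertion_length = geom$insertion_length,
      lumen_height = geom$lumen_height,
      wall_thickness = geom$wall_thickness,
      tip_opening_length = geom$tip_opening_length,
      wall_offset = geom$wall_offset,
      holes = lapply(geom$holes, strip)),
    boundary = strip(config$boundary),
    rheology = strip(config$rheology),
    solver = strip(config$solver),
    seeding = strip(config$seeding),
    integration = strip(config$integration),
    pli = strip(config$pli),
    tip_volume = strip(config$tip_volume))
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(config_to_list(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  stop_unless(file.exists(path), "no such file: %s", path)
  l <- yaml::read_yaml(path)
  holes <- lapply(l$geometry$holes, function(h)
    side_hole(h$profile, h$length, h$tip_distance, h$chamfer_angle))
  geom_args <- l$geometry[setdiff(names(l$geometry), "holes")]
  geometry <- do.call(tip_geometry, c(geom_args, list(holes = holes)))
  fs <- l$field_source
  field_source <- if (identical(fs, "solve")) "solve"
    else analytic_field_spec(fs$kind, fs$speed, fs$length, fs$extent)
  run_config(
    geometry = geometry,
    boundary = do.call(boundary_spec, l$boundary),
    rheology = do.call(carreau_parameters, l$rheology),
    solver = do.call(solver_settings, l$solver),
    seeding = seed_spec(l$seeding$count, l$seeding$offset, l$seeding$span),
    integration = do.call(integration_settings, l$integration),
    pli = do.call(pli_parameters, l$pli),
    tip_volume = do.call(tip_volume_spec, l$tip_volume),
    label = l$label, field_source = field_source,
    field_resolution = l$field_resolution, seed = l$seed)
}

#' Run the full pipeline for one design
#'
#' Executes rasterize -> solve (or analytic-fixture evaluation) -> seed ->
#' track -> score. When `outdir` is given, persists the artifacts: the
#' field (VTK), path lines (CSV), the damage report (CSV), the
#' convergence history (CSV) and a log; every artifact carries the config
#' hash. Re-running a configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory (created if missing).
#' @param track Run the platelet-tracking stage (default TRUE).
#' @param init Optional warm-start solution passed to [solve_steady()].
#' @param verbose Print stage progress.
#' @return List of class `design_run`: `report` ([damage_report()]),
#'   `solution` (or `NULL` in fixture mode), `field`, `lines`, `config`,
#'   `hash`, `artifacts` (paths, if written).
#' @export
run_design <- function(config, outdir = NULL, track = TRUE, init = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  say("run_design '%s' (config %s)", config$label, hash)

  fixture <- inherits(config$field_source, "analytic_field_spec")
  sol <- NULL
  if (fixture) {
    say("fixture mode: evaluating analytic '%s' field",
        config$field_source$kind)
    field <- make_analytic_field(config$field_source,
                                 config$field_resolution[1],
                                 config$field_resolution[2],
                                 rheo = config$rheology)
  } else {
    say("stage solve: spacing %g m", config$solver$spacing)
    sol <- solve_steady(config$geometry, config$boundary, config$rheology,
                        config$solver, init = init)
    stage_check(sol$converged, "solve",
                sprintf("residual %.3g after %d iterations",
                        sol$residual, sol$iterations))
    field <- sol$field
    say("solve converged: %d iterations, residual %.3e, outflow %.2f mL/min",
        sol$iterations, sol$residual, sol$outflow_ml_min)
  }

  lines <- NULL
  if (track) {
    say("stage track: %d seeds per plane", config$seeding$count)
    lines <- tryCatch(
      track_ensemble(config$seeding, field, config$rheology,
                     settings = config$integration,
                     geometry = if (fixture) NULL else config$geometry),
      error = function(e) stop(sprintf("stage track failed: %s",
                                       conditionMessage(e)), call. = FALSE))
    say("tracking done: %s",
        paste(sprintf("%s=%d", names(lines$terminations),
                      as.integer(lines$terminations)), collapse = " "))
  }

  say("stage metrics")
  report <- damage_report(config$label, sol = sol, field = field,
                          lines = lines, tip_spec = config$tip_volume,
                          pli_params = config$pli, rheo = config$rheology,
                          geometry = if (fixture) NULL else config$geometry)
  report$config_hash <- hash

  artifacts <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(outdir, gsub("[^A-Za-z0-9_.-]", "_", config$label))
    artifacts$field <- paste0(stem, "_field.vtk")
    write_field(field, artifacts$field)
    if (!is.null(sol)) {
      artifacts$history <- paste0(stem, "_history.csv")
      h <- sol$history
      h$config_hash <- hash
      utils::write.csv(h, artifacts$history, row.names = FALSE)
    }
    if (!is.null(lines)) {
      artifacts$pathlines <- paste0(stem, "_pathlines.csv")
      write_pathlines(lines, artifacts$pathlines)
    }
    artifacts$report <- paste0(stem, "_report.csv")
    utils::write.csv(report, artifacts$report, row.names = FALSE)
    artifacts$config <- paste0(stem, "_config.yaml")
    write_run_config(config, artifacts$config)
    artifacts$log <- paste0(stem, "_log.txt")
    say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    writeLines(c(sprintf("config_hash: %s", hash), log), artifacts$log)
  }

  structure(list(report = report, solution = sol, field = field,
                 lines = lines, config = config, hash = hash,
                 artifacts = artifacts),
            class = "design_run")
}

stage_check <- function(ok, stage, diag) {
  if (!isTRUE(ok))
    warning(sprintf("stage %s: %s", stage, diag), call. = FALSE)
  invisible(ok)
}

#' @exportS3Method
print.design_run <- function(x, ...) {
  cat(sprintf("design_run '%s' (config %s)\n", x$config$label, x$hash))
  print(x$report)
  invisible(x)
}

#' Compare designs against a reference
#'
#' Runs (or accepts pre-run) designs and tabulates all damage-report
#' columns with deltas of the key metrics relative to a declared reference
#' design (the no-hole baseline, by convention). All configurations must
#' score the same tip region; differing regions draw a warning.
#'
#' @param configs List of [run_config()]s, or of [run_design()] results.
#' @param reference Index of the reference design (default 1).
#' @param ... Passed to [run_design()] (e.g. `track = FALSE`).
#' @return A `data.frame` of class `design_comparison` with one row per
#'   design and `delta_*` columns relative to the reference.
#' @export
compare_designs <- function(configs, reference = 1L, ...) {
  stop_unless(length(configs) >= 2, "need at least two designs to compare")
  runs <- lapply(configs, function(cf) {
    if (inherits(cf, "design_run")) cf
    else run_design(cf, ...)
  })
  tips <- lapply(runs, function(r) {
    b <- tip_region_bounds(r$config$tip_volume,
                           if (identical(r$config$field_source, "solve"))
                             r$config$geometry else NULL, r$field)
    unlist(b)
  })
  for (k in seq_along(tips)[-1])
    if (max(abs(tips[[k]] - tips[[1]])) > 1e-9)
      warning("designs score different tip regions; deltas compare unlike volumes",
              call. = FALSE)
  reports <- lapply(runs, `[[`, "report")
  cols <- Reduce(union, lapply(reports, names))
  tab <- do.call(rbind, lapply(reports, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA_real_
    r[cols]
  }))
  ref <- tab[reference, ]
  for (nm in c("max_speed_m_s", "mean_stress_pa", "pct_volume_above",
               "mean_residence_s", "pli")) {
    tab[[paste0("delta_", nm)]] <- tab[[nm]] - ref[[nm]]
  }
  attr(tab, "reference") <- tab$design[reference]
  class(tab) <- c("design_comparison", "data.frame")
  tab
}

#' @exportS3Method
print.design_comparison <- function(x, ...) {
  cat(sprintf("design_comparison (reference: %s)\n", attr(x, "reference")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- grid convergence -------------------------------------------------------

# Tip-region metrics evaluated on a fixed probe lattice, so successive
# grids are compared at identical physical locations.
tip_probe_metrics <- function(field, spec, rheo, geometry,
                              nprobe = c(120, 24)) {
  b <- tip_region_bounds(spec, geometry, field)
  margin_x <- diff(b$x) * 1e-3
  margin_y <- diff(b$y) * 0.05
  xs <- seq(b$x[1] + margin_x, b$x[2] - margin_x, length.out = nprobe[1])
  ys <- seq(b$y[1] + margin_y, b$y[2] - margin_y, length.out = nprobe[2])
  sp_u <- sample_matrix_on(field$u, field$x, field$y, xs, ys)
  sp_v <- sample_matrix_on(field$v, field$x, field$y, xs, ys)
  gm <- attr(field, "shear_rate")
  gam <- if (!is.null(gm)) {
    sample_matrix_on(gm, field$x, field$y, xs, ys)
  } else {
    gr <- field_gradients(field)
    g11 <- sample_matrix_on(gr$dudx, field$x, field$y, xs, ys)
    g12 <- sample_matrix_on(gr$dudy, field$x, field$y, xs, ys)
    g21 <- sample_matrix_on(gr$dvdx, field$x, field$y, xs, ys)
    g22 <- sample_matrix_on(gr$dvdy, field$x, field$y, xs, ys)
    shear_rate_components(g11, g12, g21, g22)
  }
  list(max_speed = max(sqrt(sp_u^2 + sp_v^2)), mean_shear = mean(gam))
}

#' Grid-convergence study
#'
#' Solves the configured design on a sequence of strictly decreasing grid
#' spacings (each solve warm-started from the previous level), evaluates
#' the maximum tip-region speed and average tip-region shear rate on a
#' fixed probe lattice, and reports the percentage change of both metrics
#' between successive levels. The first level at which both changes drop
#' below `criterion_pct` is flagged as mesh-converged; a sequence that
#' never meets the criterion is flagged (`converged_level = NA`), not
#' failed.
#'
#' @param config A [run_config()] (solve mode).
#' @param spacings Strictly decreasing spacings (m), length >= 3.
#' @param criterion_pct Convergence criterion on the percentage
#'   differences (default 0.5).
#' @param verbose Print per-level progress.
#' @return A list of class `grid_study`: `table` (spacing, cells, metrics,
#'   percentage differences), `converged_level` (index into the sequence
#'   or `NA`), `criterion_pct`, `solutions` (the per-level solves).
#' @export
grid_convergence_study <- function(config, spacings,
                                   criterion_pct = 0.5, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stop_unless(length(spacings) >= 3 && all(diff(spacings) < 0),
              "need >= 3 strictly decreasing spacings")
  stop_unless(identical(config$field_source, "solve"),
              "grid study requires solve mode")
  n <- length(spacings)
  ms <- mg <- cells <- numeric(n)
  sols <- vector("list", n)
  init <- NULL
  for (k in seq_len(n)) {
    st <- config$solver
    st$spacing <- spacings[k]
    sol <- solve_steady(config$geometry, config$boundary, config$rheology,
                        st, init = init, verbose = verbose)
    pm <- tip_probe_metrics(sol$field, config$tip_volume, config$rheology,
                            config$geometry)
    ms[k] <- pm$max_speed
    mg[k] <- pm$mean_shear
    cells[k] <- sol$domain$nx * sol$domain$ny
    sols[[k]] <- sol
    init <- sol
    if (verbose)
      message(sprintf(
        "level %d: spacing %.3g m (%d cells), max speed %.5g, mean shear %.5g",
        k, spacings[k], cells[k], ms[k], mg[k]))
  }
  pd_speed <- c(NA, abs(diff(ms)) / ms[-n] * 100)
  pd_shear <- c(NA, abs(diff(mg)) / mg[-n] * 100)
  both <- pd_speed < criterion_pct & pd_shear < criterion_pct
  flagged <- which(both)[1]
  tab <- data.frame(level = seq_len(n), spacing = spacings, cells = cells,
                    max_tip_speed = ms, mean_tip_shear = mg,
                    pct_diff_speed = pd_speed, pct_diff_shear = pd_shear,
                    converged = !is.na(both) & both)
  structure(list(table = tab, converged_level = flagged,
                 criterion_pct = criterion_pct, solutions = sols),
            class = "grid_study")
}

#' @exportS3Method
print.grid_study <- function(x, ...) {
  cat(sprintf("grid_convergence_study (criterion %.2f%%)\n", x$criterion_pct))
  print(x$table, row.names = FALSE, digits = 5)
  if (is.na(x$converged_level))
    cat("  no level meets the criterion\n")
  else
    cat(sprintf("  converged at level %d (spacing %g m)\n",
                x$converged_level, x$table$spacing[x$converged_level]))
  invisible(x)
}
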