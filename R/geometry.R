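# Parameterized 2D catheter-tip geometry and its rasterization onto the
# solver grid. The planar layout is the desk-scale analog of a catheter
# inserted along a vein: a channel (the vessel) with the catheter body as
# two horizontal wall strips enclosing the inflow lumen. The lumen opens at
# the distal tip (end face plus an upper cut-back, mimicking a skived tip)
# and optionally through one or two side-holes in the upper wall.
#
# Coordinates: x axial (vessel inlet at x = 0), y transverse, origin at the
# vessel inlet lower corner. The catheter base sits on the inlet plane; the
# lumen outlet (to the dialysis circuit) is the west boundary segment of
# the lumen.

#' Side-hole description
#'
#' @param profile `"straight_cut"` (drilled/punched, square edges) or
#'   `"angled_cut"` (skived, chamfered edges).
#' @param length Opening length at the inner (lumen-side) wall surface (m).
#' @param tip_distance Distance from the hole's distal edge to the catheter
#'   tip (m). Held constant across compared designs (default 16.5 mm).
#' @param chamfer_angle Chamfer angle for `angled_cut`, degrees from the
#'   wall surface plane (default 45). The opening widens linearly from the
#'   inner to the outer wall surface by `wall_thickness / tan(angle)` per
#'   edge.
#' @return An object of class `side_hole`.
#' @export
side_hole <- function(profile = c("straight_cut", "angled_cut"),
                      length = 3e-3, tip_distance = 16.5e-3,
                      chamfer_angle = 45) {
  profile <- match.arg(profile)
  stop_unless(is_pos_scalar(length), "hole length must be positive")
  stop_unless(is_pos_scalar(tip_distance), "tip_distance must be positive")
  stop_unless(is_pos_scalar(chamfer_angle) && chamfer_angle < 90,
              "chamfer_angle must be in (0, 90) degrees")
  structure(list(profile = profile, length = length,
                 tip_distance = tip_distance, chamfer_angle = chamfer_angle),
            class = "side_hole")
}

#' Parameterized 2D catheter-tip geometry
#'
#' @param vessel_width Vessel (channel) width (m); planar analog of the
#'   20 mm vena-cava diameter.
#' @param vessel_length Vessel length (m).
#' @param insertion_length Catheter insertion length: the tip sits at
#'   `x = insertion_length` (m).
#' @param lumen_height Lumen interior height (m); analog of the 2.5 mm
#'   semicircular lumen radius.
#' @param wall_thickness Catheter wall thickness (m).
#' @param tip_opening_length Length of the upper-wall cut-back at the tip
#'   (m); together with the open end face it forms the tip opening.
#' @param wall_offset Distance from the bottom vessel wall to the
#'   catheter's lower surface (m). The default 0 lays the catheter along
#'   the vessel wall, the typical clinical position; it also gives the
#'   planar analog a single free shear layer past the tip (step-down
#'   topology), which admits the steady laminar solution the solver
#'   computes. A centered catheter (`wall_offset` about half the free
#'   width) exposes two shear layers whose planar vortex street has no
#'   steady state.
#' @param holes List of [side_hole()] objects (0-2). Two holes form the
#'   `dual_linear` arrangement (axially in line); a circumferential
#'   "parallel" pair has no planar analog and is not representable.
#' @return An object of class `tip_geometry` with derived layout fields
#'   (wall y-extents, hole x-spans).
#' @export
tip_geometry <- function(vessel_width = 20e-3, vessel_length = 60e-3,
                         insertion_length = 24e-3, lumen_height = 2.5e-3,
                         wall_thickness = 2e-3, tip_opening_length = 2.5e-3,
                         wall_offset = 0, holes = list()) {
  for (nm in c("vessel_width", "vessel_length", "lumen_height"))
    stop_unless(is_pos_scalar(get(nm)), "%s must be positive", nm)
  stop_unless(is_pos_scalar(wall_thickness), "wall_thickness must be positive")
  stop_unless(is_nonneg_scalar(insertion_length),
              "insertion_length must be >= 0")
  stop_unless(is_nonneg_scalar(tip_opening_length),
              "tip_opening_length must be >= 0")
  stop_unless(insertion_length < vessel_length,
              "catheter must not reach the vessel outlet")
  stop_unless(is_nonneg_scalar(wall_offset), "wall_offset must be >= 0")
  stop_unless(is.list(holes) && length(holes) <= 2,
              "at most two side-holes are supported (dual_linear)")
  for (h in holes) stopifnot(inherits(h, "side_hole"))
  body_height <- 2 * wall_thickness + lumen_height
  stop_unless(insertion_length == 0 ||
                wall_offset + body_height < vessel_width,
              "catheter body exceeds the vessel width")
  if (length(holes) > 0)
    stop_unless(insertion_length > 0, "side-holes require an inserted catheter")
  stop_unless(tip_opening_length < insertion_length || insertion_length == 0,
              "tip_opening_length must be shorter than the insertion length")

  y_lower <- wall_offset
  layout <- list(
    y_wall_lo = c(y_lower, y_lower + wall_thickness),
    y_lumen   = c(y_lower + wall_thickness,
                  y_lower + wall_thickness + lumen_height),
    y_wall_up = c(y_lower + wall_thickness + lumen_height,
                  y_lower + body_height))

  # hole spans at the inner wall surface: [distal - length, distal]
  spans <- lapply(holes, function(h) {
    xd <- insertion_length - h$tip_distance
    stop_unless(xd - h$length > 0 && xd < insertion_length,
                "side-hole [%g, %g] m lies outside the inserted wall",
                xd - h$length, xd)
    c(xd - h$length, xd)
  })
  if (length(spans) == 2) {
    o <- order(vapply(spans, `[`, 0, 1))
    spans <- spans[o]; holes <- holes[o]
    stop_unless(spans[[1]][2] < spans[[2]][1],
                "side-hole openings overlap ([%g, %g] vs [%g, %g] m)",
                spans[[1]][1], spans[[1]][2], spans[[2]][1], spans[[2]][2])
  }
  for (s in spans)
    stop_unless(s[2] <= insertion_length - tip_opening_length,
                "side-hole overlaps the tip opening cut-back")

  structure(list(vessel_width = vessel_width, vessel_length = vessel_length,
                 insertion_length = insertion_length,
                 lumen_height = lumen_height,
                 wall_thickness = wall_thickness,
                 tip_opening_length = tip_opening_length,
                 wall_offset = wall_offset,
                 holes = holes, hole_spans = spans, layout = layout,
                 arrangement = c("none", "single", "dual_linear")[
                   length(holes) + 1L]),
            class = "tip_geometry")
}

#' @exportS3Method
print.tip_geometry <- function(x, ...) {
  cat(sprintf("tip_geometry: vessel %g x %g mm, catheter inserted %g mm\n",
              x$vessel_length * 1e3, x$vessel_width * 1e3,
              x$insertion_length * 1e3))
  cat(sprintf("  lumen %g mm, wall %g mm, tip cut-back %g mm, arrangement: %s\n",
              x$lumen_height * 1e3, x$wall_thickness * 1e3,
              x$tip_opening_length * 1e3, x$arrangement))
  for (i in seq_along(x$holes)) {
    h <- x$holes[[i]]; s <- x$hole_spans[[i]]
    cat(sprintf("  hole %d: %s, %g mm opening at x = [%g, %g] mm (tip distance %g mm)\n",
                i, h$profile, h$length * 1e3, s[1] * 1e3, s[2] * 1e3,
                h$tip_distance * 1e3))
  }
  invisible(x)
}

#' Standard toy tip designs
#'
#' Convenience constructors for the compared design family: the no-hole
#' reference tip, a single side-hole (straight or chamfered profile), and
#' the dual in-line arrangement in which the single hole's opening length
#' is split into two equal holes (distal hole at the standard tip
#' distance).
#'
#' @param design One of `"no_hole"`, `"single"`, `"dual_linear"`.
#' @param profile Hole profile, see [side_hole()].
#' @param hole_length Single-hole opening length (m); split in two for
#'   `dual_linear`.
#' @param gap Axial gap between the dual holes (m).
#' @param ... Passed to [tip_geometry()].
#' @return A [tip_geometry()].
#' @export
toy_tip_design <- function(design = c("single", "no_hole", "dual_linear"),
                           profile = "straight_cut", hole_length = 3e-3,
                           gap = 2e-3, ...) {
  design <- match.arg(design)
  holes <- switch(design,
    no_hole = list(),
    single = list(side_hole(profile, length = hole_length)),
    dual_linear = {
      len2 <- hole_length / 2
      list(side_hole(profile, length = len2),
           side_hole(profile, length = len2,
                     tip_distance = 16.5e-3 + len2 + gap))
    })
  tip_geometry(holes = holes, ...)
}

# ---- rasterization ----------------------------------------------------------

#' Rasterize a tip geometry onto a uniform solver grid
#'
#' Builds the fluid/solid cell mask and labels the boundary segments
#' (vessel inlet, lumen outlet, vessel outlet, walls). A cell is solid when
#' its center lies inside a catheter wall. `angled_cut` holes produce a
#' stair-stepped chamfer whose edge slope matches the requested angle to
#' within one cell. The achieved (rasterized) opening length of each hole
#' at the inner wall surface is reported and converges to the requested
#' length as the spacing is refined (error bounded by one cell).
#'
#' @param geom A [tip_geometry()].
#' @param spacing Target grid spacing (m); the actual spacings divide the
#'   vessel extents exactly. Every geometric feature (wall thickness,
#'   lumen, gaps, hole openings, tip cut-back) must span at least 3 cells.
#' @return An object of class `raster_domain`: grid axes, mask, boundary
#'   types per west-row, lumen rows, hole/tip face bookkeeping.
#' @export
rasterize_geometry <- function(geom, spacing) {
  stopifnot(inherits(geom, "tip_geometry"))
  stop_unless(is_pos_scalar(spacing), "spacing must be positive")
  nx <- max(2L, round(geom$vessel_length / spacing))
  ny <- max(2L, round(geom$vessel_width / spacing))
  hx <- geom$vessel_length / nx
  hy <- geom$vessel_width / ny

  # feature resolution: >= 3 cells per thinnest feature
  feats <- list()
  if (geom$insertion_length > 0) {
    feats$`wall thickness (y)` <- c(geom$wall_thickness, hy)
    feats$`lumen height (y)` <- c(geom$lumen_height, hy)
    gap_lo <- geom$layout$y_wall_lo[1]
    gap_up <- geom$vessel_width - geom$layout$y_wall_up[2]
    if (gap_lo > 0) feats$`vessel gap below catheter (y)` <- c(gap_lo, hy)
    feats$`vessel gap above catheter (y)` <- c(gap_up, hy)
    if (geom$tip_opening_length > 0)
      feats$`tip opening cut-back (x)` <- c(geom$tip_opening_length, hx)
    for (i in seq_along(geom$holes))
      feats[[sprintf("side-hole %d opening (x)", i)]] <-
        c(geom$holes[[i]]$length, hx)
    if (length(geom$hole_spans) == 2)
      feats$`inter-hole wall segment (x)` <-
        c(geom$hole_spans[[2]][1] - geom$hole_spans[[1]][2], hx)
  }
  for (nm in names(feats)) {
    f <- feats[[nm]]
    if (f[1] / f[2] < 3 - 1e-9)
      stop(sprintf(
        "spacing %g m under-resolves feature '%s' (%g m spans %.2f cells; need >= 3)",
        spacing, nm, f[1], f[1] / f[2]), call. = FALSE)
  }

  xc <- (seq_len(nx) - 0.5) * hx
  yc <- (seq_len(ny) - 0.5) * hy
  solid <- matrix(FALSE, nx, ny)
  lay <- geom$layout
  x_tip <- geom$insertion_length

  # snap a feature edge to the nearest grid face; cells between faces f0
  # and f1 are (f0+1):f1 (deterministic, no center/edge ties)
  fx <- function(p) as.integer(round(p / hx + 1e-9))
  fy <- function(p) as.integer(round(p / hy + 1e-9))
  cells_between <- function(f0, f1, nmax) {
    r <- if (f1 > f0) (f0 + 1L):f1 else integer(0)
    r[r >= 1L & r <= nmax]
  }

  if (x_tip > 0) {
    j_lo <- cells_between(fy(lay$y_wall_lo[1]), fy(lay$y_wall_lo[2]), ny)
    j_up <- cells_between(fy(lay$y_wall_up[1]), fy(lay$y_wall_up[2]), ny)
    i_tip <- fx(x_tip)
    i_upwall <- cells_between(0L, fx(x_tip - geom$tip_opening_length), nx)
    solid[cells_between(0L, i_tip, nx), j_lo] <- TRUE
    solid[i_upwall, j_up] <- TRUE
    # carve the side-hole openings out of the upper wall
    wt <- geom$wall_thickness
    for (k in seq_along(geom$holes)) {
      h <- geom$holes[[k]]; s <- geom$hole_spans[[k]]
      if (h$profile == "straight_cut") {
        solid[cells_between(fx(s[1]), fx(s[2]), nx), j_up] <- FALSE
      } else {
        run <- wt / tan(h$chamfer_angle * pi / 180)
        for (j in j_up) {
          f <- (yc[j] - lay$y_wall_up[1]) / wt  # 0 inner -> 1 outer
          open_x <- cells_between(fx(s[1] - f * run), fx(s[2] + f * run), nx)
          solid[open_x, j] <- FALSE
        }
      }
    }
  }
  mask <- !solid

  # west boundary classification per row
  y_lum <- lay$y_lumen
  lumen_rows <- if (x_tip > 0)
    cells_between(fy(y_lum[1]), fy(y_lum[2]), ny) else integer(0)
  west_type <- ifelse(!mask[1, ], "solid", "inlet")
  west_type[lumen_rows] <- "lumen_outlet"

  # bookkeeping for flux integration (faces on the inner wall surface line)
  j_face_top <- if (x_tip > 0) fy(y_lum[2]) + 1L else NA_integer_
  i_face_tip <- if (x_tip > 0) fx(x_tip) + 1L else NA_integer_
  hole_cols <- lapply(geom$hole_spans, function(s) {
    cells_between(fx(s[1]), fx(s[2]), nx)
  })
  achieved <- vapply(hole_cols, function(ix) length(ix) * hx, 0)
  tipcut_cols <- if (x_tip > 0 && geom$tip_opening_length > 0)
    cells_between(fx(x_tip - geom$tip_opening_length), fx(x_tip), nx)
  else integer(0)

  structure(list(geom = geom, nx = nx, ny = ny, hx = hx, hy = hy,
                 xc = xc, yc = yc,
                 xf = seq(0, geom$vessel_length, length.out = nx + 1),
                 yf = seq(0, geom$vessel_width, length.out = ny + 1),
                 mask = mask, west_type = west_type,
                 lumen_rows = lumen_rows, j_face_top = j_face_top,
                 i_face_tip = i_face_tip, hole_cols = hole_cols,
                 tipcut_cols = tipcut_cols,
                 achieved_hole_lengths = achieved),
            class = "raster_domain")
}

#' @exportS3Method
print.raster_domain <- function(x, ...) {
  cat(sprintf("raster_domain: %d x %d cells (hx = %g, hy = %g m), %d fluid\n",
              x$nx, x$ny, x$hx, x$hy, sum(x$mask)))
  cat(sprintf("  west rows: %d inlet, %d lumen outlet, %d solid\n",
              sum(x$west_type == "inlet"), sum(x$west_type == "lumen_outlet"),
              sum(x$west_type == "solid")))
  if (length(x$achieved_hole_lengths))
    cat(sprintf("  achieved hole lengths: %s mm\n",
                paste(signif(x$achieved_hole_lengths * 1e3, 4),
                      collapse = ", ")))
  invisible(x)
}

# Plain-channel raster (no catheter): used for analytic verification solves.
channel_domain <- function(width, length, spacing) {
  rasterize_geometry(
    tip_geometry(vessel_width = width, vessel_length = length,
                 insertion_length = 0, tip_opening_length = 0),
    spacing)
}
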