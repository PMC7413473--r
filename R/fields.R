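# Flow-field data model: node-centered rectilinear velocity fields with a
# fluid/solid mask, multilinear sampling, finite-difference gradients, and
# the analytic fixtures (uniform, Couette, Poiseuille, stagnation) that give
# every downstream stage a closed-form reference solution.

#' Structured rectilinear flow field
#'
#' A steady planar velocity field sampled on a node-centered rectilinear
#' grid. Two-dimensional fields are stored with an implicit singleton third
#' dimension so the same containers serve planar and (future) 3D data.
#' Solid nodes always carry zero velocity (no-slip); any nonzero velocity
#' supplied on solid nodes is zeroed.
#'
#' @param x,y Strictly increasing node coordinates (m).
#' @param u,v Velocity components (m/s), `length(x)` x `length(y)` matrices
#'   (row index runs along x).
#' @param viscosity Optional dynamic viscosity at nodes (Pa s), same shape.
#' @param mask Optional logical (or 0/1) matrix, `TRUE`/1 = fluid. Defaults
#'   to all-fluid.
#' @return An object of class `structured_field`.
#' @examples
#' f <- make_analytic_field(analytic_field_spec("uniform", speed = 0.3,
#'                          length = 0.01, extent = c(0.04, 0.02)), 17, 9)
#' sample_velocity(f, c(0.01, 0.005))
#' @export
structured_field <- function(x, y, u, v, viscosity = NULL, mask = NULL) {
  stop_unless(is.numeric(x) && length(x) >= 2 && all(diff(x) > 0),
              "x coordinates must be strictly increasing (>= 2 nodes)")
  stop_unless(is.numeric(y) && length(y) >= 2 && all(diff(y) > 0),
              "y coordinates must be strictly increasing (>= 2 nodes)")
  nx <- length(x); ny <- length(y)
  stop_unless(is.matrix(u) && all(dim(u) == c(nx, ny)),
              "u must be a %d x %d matrix", nx, ny)
  stop_unless(is.matrix(v) && all(dim(v) == c(nx, ny)),
              "v must be a %d x %d matrix", nx, ny)
  stop_unless(all(is.finite(u)) && all(is.finite(v)),
              "velocity components must be finite")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nx, ny)
  } else {
    mask <- matrix(as.logical(mask), nx, ny)
    stop_unless(!anyNA(mask), "mask must be logical/0-1 with no NA")
  }
  if (!is.null(viscosity)) {
    stop_unless(is.matrix(viscosity) && all(dim(viscosity) == c(nx, ny)) &&
                  all(is.finite(viscosity)) && all(viscosity > 0),
                "viscosity must be a positive %d x %d matrix", nx, ny)
  }
  # no-slip: solid nodes carry zero velocity
  u[!mask] <- 0
  v[!mask] <- 0
  structure(list(x = x, y = y, u = u, v = v,
                 viscosity = viscosity, mask = mask, dim = "2D"),
            class = "structured_field")
}

#' @exportS3Method
print.structured_field <- function(x, ...) {
  sp <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("structured_field: %d x %d nodes, extent [%g, %g] x [%g, %g] m\n",
              length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  fluid nodes: %d/%d, max speed %.4g m/s\n",
              sum(x$mask), length(x$mask), max(sp)))
  if (!is.null(x$viscosity))
    cat(sprintf("  viscosity: [%.4g, %.4g] Pa s\n",
                min(x$viscosity), max(x$viscosity)))
  invisible(x)
}

#' @exportS3Method
plot.structured_field <- function(x, what = c("speed", "u", "v", "viscosity"),
                                  ...) {
  what <- match.arg(what)
  z <- switch(what,
              speed = sqrt(x$u^2 + x$v^2),
              u = x$u, v = x$v,
              viscosity = {
                stop_unless(!is.null(x$viscosity), "field has no viscosity")
                x$viscosity
              })
  z[!x$mask] <- NA
  graphics::image(x$x, x$y, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = what, col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Analytic flow-field specification
#'
#' Describes one of the closed-form laminar fixtures used in place of a
#' numerical solve: uniform stream, Couette shear, planar or tube
#' Poiseuille flow, or planar stagnation flow. These have exact velocity,
#' gradient and shear-rate fields, so interpolation, tracking and metric
#' stages can be verified without running the solver.
#'
#' @param kind One of `"uniform"`, `"couette"`, `"poiseuille_planar"`,
#'   `"poiseuille_tube"`, `"stagnation"`.
#' @param speed Characteristic speed (m/s): free-stream speed (uniform),
#'   moving-wall speed (Couette), mean speed (Poiseuille), strain scale
#'   times `length` (stagnation).
#' @param length Characteristic length (m): channel height / tube diameter /
#'   strain length scale. Defaults to the y-extent.
#' @param extent Domain extents `c(Lx, Ly)` (m).
#' @return An object of class `analytic_field_spec`.
#' @export
analytic_field_spec <- function(kind = c("uniform", "couette",
                                         "poiseuille_planar",
                                         "poiseuille_tube", "stagnation"),
                                speed, length = NULL, extent) {
  kind <- match.arg(kind)
  stop_unless(is_pos_scalar(speed), "speed must be a positive scalar")
  stop_unless(is.numeric(extent) && length(extent) == 2 && all(extent > 0),
              "extent must be c(Lx, Ly), both positive")
  if (is.null(length)) length <- extent[2]
  stop_unless(is_pos_scalar(length), "length must be a positive scalar")
  structure(list(kind = kind, speed = speed, length = length,
                 extent = as.numeric(extent)),
            class = "analytic_field_spec")
}

#' Evaluate an analytic fixture field on a grid
#'
#' Node values equal the closed form exactly; the construction is fully
#' deterministic. The Poiseuille profiles are centered on the y-extent;
#' the stagnation field is \eqn{(u, v) = (kx, -ky)} with
#' \eqn{k = \mathrm{speed} / \mathrm{length}} (divergence-free at every
#' node).
#'
#' @param spec An [analytic_field_spec()].
#' @param nx,ny Number of nodes per axis.
#' @param rheo Optional [carreau_parameters()]; if supplied, the nodal
#'   viscosity is filled in from the closed-form shear rate.
#' @return A [structured_field()].
#' @export
make_analytic_field <- function(spec, nx, ny, rheo = NULL) {
  stopifnot(inherits(spec, "analytic_field_spec"))
  stop_unless(nx >= 2 && ny >= 2, "need at least 2 nodes per axis")
  x <- seq(0, spec$extent[1], length.out = nx)
  y <- seq(0, spec$extent[2], length.out = ny)
  Y <- matrix(rep(y, each = nx), nx, ny)
  X <- matrix(rep(x, times = ny), nx, ny)
  U0 <- spec$speed; L <- spec$length; H <- spec$extent[2]
  zero <- matrix(0, nx, ny)
  uv <- switch(spec$kind,
    uniform = list(u = matrix(U0, nx, ny), v = zero),
    couette = list(u = U0 * Y / L, v = zero),
    poiseuille_planar = {
      c0 <- H / 2; b <- L / 2
      list(u = 1.5 * U0 * (1 - ((Y - c0) / b)^2), v = zero)
    },
    poiseuille_tube = {
      c0 <- H / 2; R <- L / 2
      list(u = 2 * U0 * (1 - ((Y - c0) / R)^2), v = zero)
    },
    stagnation = {
      k <- U0 / L
      list(u = k * X, v = -k * Y)
    })
  visc <- NULL
  if (!is.null(rheo)) {
    g <- analytic_shear_rate(spec, X, Y)
    visc <- matrix(carreau_viscosity(rheo, as.vector(g)), nx, ny)
  }
  f <- structured_field(x, y, uv$u, uv$v, viscosity = visc)
  attr(f, "analytic_spec") <- spec
  f
}

# Closed-form shear-rate magnitude of a fixture (same grid layout as above).
analytic_shear_rate <- function(spec, X, Y) {
  U0 <- spec$speed; L <- spec$length; H <- dim_or(Y)
  switch(spec$kind,
    uniform = X * 0,
    couette = X * 0 + U0 / L,
    poiseuille_planar = {
      c0 <- max(Y) / 2; b <- L / 2
      abs(-3 * U0 * (Y - c0) / b^2)
    },
    poiseuille_tube = {
      c0 <- max(Y) / 2; R <- L / 2
      abs(-4 * U0 * (Y - c0) / R^2)
    },
    stagnation = X * 0 + 2 * U0 / L)
}

dim_or <- function(Y) max(Y)

# ---- sampling ---------------------------------------------------------------

# Locate a coordinate in a strictly increasing axis; returns the cell index
# i (node i .. i+1) and the linear weight toward node i+1, or NA outside.
axis_locate <- function(ax, p) {
  n <- length(ax)
  if (p < ax[1] || p > ax[n]) return(c(NA_real_, NA_real_))
  i <- findInterval(p, ax, rightmost.closed = TRUE)
  if (i >= n) i <- n - 1L
  w <- (p - ax[i]) / (ax[i + 1] - ax[i])
  c(i, w)
}

# Bilinear interpolation of one node matrix at (ix, wx, iy, wy).
bilerp <- function(M, ix, wx, iy, wy) {
  (1 - wx) * ((1 - wy) * M[ix, iy] + wy * M[ix, iy + 1]) +
    wx * ((1 - wy) * M[ix + 1, iy] + wy * M[ix + 1, iy + 1])
}

#' Sample velocity at points of a structured field
#'
#' Multilinear (bilinear) interpolation of the node velocities: exact at
#' nodes, and a convex combination of the enclosing nodes elsewhere. Solid
#' nodes hold zero velocity, so interpolation adjacent to walls is no-slip
#' consistent. Positions outside the field bounding box are an
#' *out-of-domain signal*, not an error: the corresponding rows are `NA`
#' (the particle tracker treats this as a legitimate path termination).
#'
#' @param field A [structured_field()].
#' @param points Numeric vector `c(x, y)` or an n x 2 matrix of positions
#'   (m).
#' @return An n x 2 matrix of velocities (m/s); rows of `NA` for positions
#'   outside the domain bounding box.
#' @export
sample_velocity <- function(field, points) {
  stopifnot(inherits(field, "structured_field"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  out <- matrix(NA_real_, nrow(points), 2)
  colnames(out) <- c("u", "v")
  for (r in seq_len(nrow(points))) {
    lx <- axis_locate(field$x, points[r, 1])
    ly <- axis_locate(field$y, points[r, 2])
    if (anyNA(c(lx, ly))) next
    out[r, 1] <- bilerp(field$u, lx[1], lx[2], ly[1], ly[2])
    out[r, 2] <- bilerp(field$v, lx[1], lx[2], ly[1], ly[2])
  }
  out
}

# Nodal gradient components by central differences (one-sided at the domain
# boundary), second-order on uniform grids. Returns four node matrices.
field_gradients <- function(field) {
  list(dudx = ddx(field$u, field$x), dudy = ddy(field$u, field$y),
       dvdx = ddx(field$v, field$x), dvdy = ddy(field$v, field$y))
}

ddx <- function(M, x) {
  n <- length(x)
  out <- M * 0
  if (n > 2) {
    num <- M[3:n, , drop = FALSE] - M[1:(n - 2), , drop = FALSE]
    den <- x[3:n] - x[1:(n - 2)]
    out[2:(n - 1), ] <- num / den
  }
  out[1, ] <- (M[2, ] - M[1, ]) / (x[2] - x[1])
  out[n, ] <- (M[n, ] - M[n - 1, ]) / (x[n] - x[n - 1])
  out
}

ddy <- function(M, y) t(ddx(t(M), y))

#' Velocity-gradient tensor at a point
#'
#' Central finite differences of the node velocities (one-sided at domain
#' boundaries), interpolated bilinearly to the requested position and
#' embedded as the upper-left block of a 3x3 tensor with zero out-of-plane
#' components. On smooth fields the result converges to the closed-form
#' gradient at second order in the grid spacing.
#'
#' @param field A [structured_field()].
#' @param position `c(x, y)` (m), inside the field bounding box.
#' @return A 3x3 velocity-gradient matrix \eqn{G_{ij} = \partial u_i /
#'   \partial x_j} (1/s), suitable for [shear_rate_magnitude()].
#' @export
velocity_gradient_at <- function(field, position) {
  stopifnot(inherits(field, "structured_field"))
  lx <- axis_locate(field$x, position[1])
  ly <- axis_locate(field$y, position[2])
  stop_unless(!anyNA(c(lx, ly)),
              "position (%g, %g) is outside the field domain",
              position[1], position[2])
  gr <- field_gradients(field)
  G <- matrix(0, 3, 3)
  G[1, 1] <- bilerp(gr$dudx, lx[1], lx[2], ly[1], ly[2])
  G[1, 2] <- bilerp(gr$dudy, lx[1], lx[2], ly[1], ly[2])
  G[2, 1] <- bilerp(gr$dvdx, lx[1], lx[2], ly[1], ly[2])
  G[2, 2] <- bilerp(gr$dvdy, lx[1], lx[2], ly[1], ly[2])
  G
}
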