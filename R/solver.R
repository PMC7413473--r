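# Steady laminar incompressible 2D finite-volume solver: SIMPLE
# pressure-velocity coupling on a staggered grid, first-order upwind
# convection, central diffusion, Carreau viscosity re-evaluated from the
# local shear rate each outer iteration (Picard). The catheter-lumen outlet
# is a pressure boundary whose value is adjusted by a secant iteration
# until the recovered outflow matches the prescribed volumetric target,
# mirroring clinical operation where the circuit pump pressure sets the
# flow.
#
# Staggering: p/viscosity at cell centers (nx x ny); u at vertical faces
# ((nx+1) x ny), u[i,j] between cells (i-1,j) and (i,j); v at horizontal
# faces (nx x (ny+1)), v[i,j] between cells (i,j-1) and (i,j).

#' Boundary conditions for the vessel/catheter solve
#'
#' @param inlet_speed Uniform vessel inlet speed (m/s). Default 0.3.
#' @param outflow_ml_min Catheter lumen outflow target on the volumetric
#'   reporting scale (mL/min). Converted internally to a 2D per-depth flux
#'   via the lumen's effective depth (see Details). Default 400.
#' @param outlet_pressure Vessel outlet gauge pressure (Pa). Default 0.
#' @param rho Blood density (kg/m^3). Default 1060.
#' @details The 2D analog carries per-unit-depth fluxes (m^2/s). The
#'   volumetric target is divided by the effective depth
#'   `A_lumen / lumen_height = pi * lumen_height / 2` of a semicircular
#'   lumen whose radius equals the planar lumen height, so reported
#'   "2D-equivalent mL/min" values round-trip the volumetric scale.
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(inlet_speed = 0.3, outflow_ml_min = 400,
                          outlet_pressure = 0, rho = 1060) {
  stop_unless(is_pos_scalar(inlet_speed), "inlet_speed must be positive")
  stop_unless(is_pos_scalar(outflow_ml_min), "outflow target must be positive")
  stop_unless(is.numeric(outlet_pressure) && length(outlet_pressure) == 1 &&
                is.finite(outlet_pressure), "outlet_pressure must be finite")
  stop_unless(is_pos_scalar(rho), "rho must be positive")
  structure(list(inlet_speed = inlet_speed, outflow_ml_min = outflow_ml_min,
                 outlet_pressure = outlet_pressure, rho = rho),
            class = "boundary_spec")
}

#' Solver settings
#'
#' @param spacing Grid spacing (m). Default 0.25 mm.
#' @param relax_u,relax_p Under-relaxation factors for momentum and
#'   pressure, in (0, 1]. Textbook defaults 0.7 / 0.3.
#' @param relax_mu Under-relaxation of the Picard viscosity update.
#'   Shear-thinning couples the near-wall viscosity tightly to the local
#'   shear rate; the conservative default 0.3 damps the lag oscillation
#'   this can excite at fine spacings.
#' @param max_iter Maximum outer iterations.
#' @param tol_continuity Scaled continuity residual tolerance (sum of
#'   absolute cell mass imbalances over the inlet flux). Default 1e-5.
#' @param tol_momentum Scaled momentum residual tolerance (sum of absolute
#'   momentum-equation imbalances over the `aP |u|` scale, the usual
#'   segregated-solver normalization). Default 1e-5.
#' @param tol_outflow Relative tolerance on the recovered lumen outflow
#'   (default 0.0025, the analog of +/-1 mL/min on 400).
#' @param convection_blend Deferred-correction blending toward
#'   second-order (linear) upwind convection: 0 (default) keeps pure
#'   first-order upwind; positive values add a lagged defect that
#'   recovers higher-order accuracy at convergence on smooth flows. On
#'   the separated catheter-tip flows the defect feedback destabilizes
#'   the segregated iteration for blends much above 0.5, so the robust
#'   first-order scheme is the default and its discretization error is
#'   quantified by [grid_convergence_study()] instead.
#' @param momentum_sweeps Jacobi sweeps per momentum solve.
#' @param refactor_every Outer iterations between pressure-matrix
#'   refactorizations. The default rebuilds every iteration (the sparse
#'   factorization is cheap at these problem sizes); larger values trade
#'   consistency of the correction for a little speed.
#' @param max_secant Maximum outlet-pressure secant updates.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(spacing = 0.25e-3, relax_u = 0.7, relax_p = 0.3,
                            relax_mu = 0.3, max_iter = 40000,
                            tol_continuity = 1e-5, tol_momentum = 1e-5,
                            tol_outflow = 0.0025, convection_blend = 0,
                            momentum_sweeps = 4, refactor_every = 1,
                            max_secant = 20) {
  stop_unless(is_pos_scalar(spacing), "spacing must be positive")
  for (nm in c("relax_u", "relax_p", "relax_mu"))
    stop_unless(is_pos_scalar(get(nm)) && get(nm) <= 1,
                "%s must lie in (0, 1]", nm)
  stop_unless(is_pos_scalar(tol_continuity), "tol_continuity must be positive")
  stop_unless(is_pos_scalar(tol_momentum), "tol_momentum must be positive")
  stop_unless(is_pos_scalar(tol_outflow), "tol_outflow must be positive")
  stop_unless(is.numeric(convection_blend) && length(convection_blend) == 1 &&
                convection_blend >= 0 && convection_blend <= 1,
              "convection_blend must lie in [0, 1]")
  structure(list(spacing = spacing, relax_u = relax_u, relax_p = relax_p,
                 relax_mu = relax_mu, max_iter = as.integer(max_iter),
                 tol_continuity = tol_continuity, tol_momentum = tol_momentum,
                 tol_outflow = tol_outflow,
                 convection_blend = convection_blend,
                 momentum_sweeps = as.integer(momentum_sweeps),
                 refactor_every = as.integer(refactor_every),
                 max_secant = as.integer(max_secant)),
            class = "solver_settings")
}

# ---- static solver prep -----------------------------------------------------

# Classify unknowns and precompute geometry-dependent index structures.
solver_prep <- function(dom, bc) {
  nx <- dom$nx; ny <- dom$ny
  mask <- dom$mask
  # u classes: 0 fixed, 1 interior unknown, 2 west pressure half-CV,
  # 3 east pressure half-CV
  u_class <- matrix(0L, nx + 1, ny)
  if (nx >= 2)
    u_class[2:nx, ] <- ifelse(mask[1:(nx - 1), ] & mask[2:nx, ], 1L, 0L)
  u_class[1, ] <- ifelse(dom$west_type == "lumen_outlet", 2L, 0L)
  u_class[nx + 1, ] <- ifelse(mask[nx, ], 3L, 0L)
  u_fix <- matrix(0, nx + 1, ny)
  u_fix[1, dom$west_type == "inlet"] <- bc$inlet_speed

  # v classes: 0 fixed, 1 unknown
  v_class <- matrix(0L, nx, ny + 1)
  if (ny >= 2)
    v_class[, 2:ny] <- ifelse(mask[, 1:(ny - 1)] & mask[, 2:ny], 1L, 0L)

  # wall-at-half-distance doubling flags for momentum diffusion
  solid <- !mask
  # u north: wall on the face above row j (both cells in row j+1 solid, or
  # domain top). Arrays are (nx+1) x ny; cell columns i-1, i clamped.
  u_solid_row <- function(jshift) {
    # TRUE when both cells adjacent to u face are solid in row j+jshift
    s <- solid
    if (jshift == 1) s <- cbind(s[, -1, drop = FALSE], TRUE)  # row j+1, top wall
    else s <- cbind(TRUE, s[, -ny, drop = FALSE])             # row j-1, bottom wall
    left <- rbind(s[1, ], s)     # cell i-1 clamped
    right <- rbind(s, s[nx, ])   # cell i clamped
    left & right
  }
  uN_wall <- u_solid_row(1)
  uS_wall <- u_solid_row(-1)

  # v east/west doubling: both cells in column i+1 (i-1) solid; domain
  # west column handled via west boundary types.
  v_solid_col <- function(ishift) {
    s <- solid
    if (ishift == 1) s <- rbind(s[-1, , drop = FALSE], TRUE)
    else s <- rbind(TRUE, s[-nx, , drop = FALSE])
    lo <- cbind(s[, 1], s)       # cell row j-1 clamped
    hi <- cbind(s, s[, ny])      # cell row j clamped
    lo & hi
  }
  vE_wall <- v_solid_col(1)
  vW_wall <- v_solid_col(-1)
  # domain-boundary columns: west treated as Dirichlet-0 plane (inlet or
  # wall rows) or zero-gradient (lumen outlet rows); east is a pressure
  # outlet, zero-gradient.
  wt <- dom$west_type
  # (v[1, j], j = 2..ny uses rows j-1, j; represented on ny+1 face rows)
  v_west_zgrad <- logical(ny + 1)
  v_west_zgrad[2:ny] <- wt[1:(ny - 1)] == "lumen_outlet" &
    wt[2:ny] == "lumen_outlet"

  inlet_rows <- which(dom$west_type == "inlet")
  q_in <- bc$inlet_speed * length(inlet_rows) * dom$hy

  list(u_class = u_class, v_class = v_class, u_fix = u_fix,
       uN_wall = uN_wall, uS_wall = uS_wall,
       vE_wall = vE_wall, vW_wall = vW_wall, v_west_zgrad = v_west_zgrad,
       q_in = q_in, inlet_rows = inlet_rows)
}

# cell-center shear-rate magnitude from the staggered velocities. Corner
# cross-derivatives are wall-aware: where a corner row/column of faces
# lies on a no-slip surface (domain wall or interior solid strip), the
# one-sided gradient over the half-cell distance to the surface is used,
# so near-wall shear is not systematically underestimated.
cell_shear_rate <- function(u, v, dom) {
  nx <- dom$nx; ny <- dom$ny; hx <- dom$hx; hy <- dom$hy
  solid <- !dom$mask
  dudx <- (u[2:(nx + 1), ] - u[1:nx, ]) / hx
  dvdy <- (v[, 2:(ny + 1)] - v[, 1:ny]) / hy

  # both-solid indicator per u-face position (clamped cell columns i-1, i)
  row_solid <- {
    left <- rbind(solid[1, ], solid)
    right <- rbind(solid, solid[nx, ])
    left & right                               # (nx+1) x ny
  }
  # du/dy at corners (x_f(i), y_f(j)), face row j between cell rows j-1, j
  dudy_c <- matrix(0, nx + 1, ny + 1)
  dudy_c[, 2:ny] <- (u[, 2:ny] - u[, 1:(ny - 1)]) / hy
  dudy_c[, 1] <- u[, 1] / (hy / 2)
  dudy_c[, ny + 1] <- -u[, ny] / (hy / 2)
  if (ny > 1) {
    wall_above <- row_solid[, 2:ny] & !row_solid[, 1:(ny - 1)]
    wall_below <- row_solid[, 1:(ny - 1)] & !row_solid[, 2:ny]
    inner <- dudy_c[, 2:ny]
    inner[wall_above] <- (-u[, 1:(ny - 1)] / (hy / 2))[wall_above]
    inner[wall_below] <- (u[, 2:ny] / (hy / 2))[wall_below]
    dudy_c[, 2:ny] <- inner
  }
  dudy <- 0.25 * (dudy_c[1:nx, 1:ny] + dudy_c[2:(nx + 1), 1:ny] +
                    dudy_c[1:nx, 2:(ny + 1)] + dudy_c[2:(nx + 1), 2:(ny + 1)])

  col_solid <- {
    lo <- cbind(solid[, 1], solid)
    hi <- cbind(solid, solid[, ny])
    lo & hi                                    # nx x (ny+1)
  }
  dvdx_c <- matrix(0, nx + 1, ny + 1)
  dvdx_c[2:nx, ] <- (v[2:nx, ] - v[1:(nx - 1), ]) / hx
  dvdx_c[1, ] <- v[1, ] / (hx / 2)
  dvdx_c[nx + 1, ] <- -v[nx, ] / (hx / 2)
  if (nx > 1) {
    wall_east <- col_solid[2:nx, ] & !col_solid[1:(nx - 1), ]
    wall_west <- col_solid[1:(nx - 1), ] & !col_solid[2:nx, ]
    inner <- dvdx_c[2:nx, ]
    inner[wall_east] <- (-v[1:(nx - 1), ] / (hx / 2))[wall_east]
    inner[wall_west] <- (v[2:nx, ] / (hx / 2))[wall_west]
    dvdx_c[2:nx, ] <- inner
  }
  dvdx <- 0.25 * (dvdx_c[1:nx, 1:ny] + dvdx_c[2:(nx + 1), 1:ny] +
                    dvdx_c[1:nx, 2:(ny + 1)] + dvdx_c[2:(nx + 1), 2:(ny + 1)])

  shear_rate_components(dudx, dudy, dvdx, dvdy)
}

# cell-center viscosity from the staggered velocities (Carreau at the local
# shear-rate magnitude)
cell_viscosity <- function(u, v, dom, rheo) {
  gam <- cell_shear_rate(u, v, dom)
  matrix(carreau_viscosity(rheo, as.vector(gam)), dom$nx, dom$ny)
}

# corner (vertex) viscosity from cell viscosities, clamped at boundaries
corner_viscosity <- function(mu, nx, ny) {
  mp <- rbind(mu[1, ], mu, mu[nx, ])          # (nx+2) x ny
  mp <- cbind(mp[, 1], mp, mp[, ny])          # (nx+2) x (ny+2)
  0.25 * (mp[1:(nx + 1), 1:(ny + 1)] + mp[2:(nx + 2), 1:(ny + 1)] +
            mp[1:(nx + 1), 2:(ny + 2)] + mp[2:(nx + 2), 2:(ny + 2)])
}

# Deferred-correction defect of one CV face: flux times (linear-upwind
# minus first-order-upwind) interpolation of the transported velocity,
# subtracted from the source. The converged solution sees second-order
# upwind convection while the implicit coefficients remain the bounded
# first-order ones. phiPup / phiNBup are the second-upstream values for
# the two flux directions; `ok` masks faces where they exist.
face_defect <- function(F, phiP, phiNB, phiPup, phiNBup, ok) {
  d <- ifelse(F > 0, F * 0.5 * (phiP - phiPup),
              F * 0.5 * (phiNB - phiNBup))
  d[!ok] <- 0
  d
}

# ---- momentum assembly ------------------------------------------------------

# u-momentum coefficients. Returns list(aE, aW, aN, aS, aP, S) over the
# (nx+1) x ny u array; entries only meaningful where u_class > 0.
assemble_u <- function(u, v, p, mu, dom, bc, prep, p_out, sigma = 0) {
  nx <- dom$nx; ny <- dom$ny; hx <- dom$hx; hy <- dom$hy
  rho <- bc$rho

  # convective volumetric fluxes through the u-CV faces (per depth), x rho
  Fe <- Fw <- matrix(0, nx + 1, ny)
  Fe[1:nx, ] <- rho * hy * 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  Fe[nx + 1, ] <- rho * hy * u[nx + 1, ]          # boundary face itself
  Fw[2:(nx + 1), ] <- rho * hy * 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  Fw[1, ] <- rho * hy * u[1, ]

  # transverse fluxes: average the two v faces beside the u face; boundary
  # columns use the single adjacent column on a half-width CV
  vtop <- v[, 2:(ny + 1), drop = FALSE]   # nx x ny, v at face above cell
  vbot <- v[, 1:ny, drop = FALSE]
  Fn <- Fs <- matrix(0, nx + 1, ny)
  Fn[2:nx, ] <- rho * hx * 0.5 * (vtop[1:(nx - 1), ] + vtop[2:nx, ])
  Fs[2:nx, ] <- rho * hx * 0.5 * (vbot[1:(nx - 1), ] + vbot[2:nx, ])
  Fn[1, ] <- rho * (hx / 2) * vtop[1, ]
  Fn[nx + 1, ] <- rho * (hx / 2) * vtop[nx, ]
  Fs[1, ] <- rho * (hx / 2) * vbot[1, ]
  Fs[nx + 1, ] <- rho * (hx / 2) * vbot[nx, ]

  # diffusion conductances
  De <- Dw <- matrix(0, nx + 1, ny)
  De[1:nx, ] <- mu * hy / hx
  Dw[2:(nx + 1), ] <- mu * hy / hx
  muc <- corner_viscosity(mu, nx, ny)            # (nx+1) x (ny+1)
  width <- c(hx / 2, rep(hx, nx - 1), hx / 2)
  Dn <- muc[, 2:(ny + 1)] * width / hy
  Ds <- muc[, 1:ny] * width / hy
  # wall at half distance: double conductance, kill convection; a deferred
  # correction below upgrades the wall shear to the quadratic (two-node)
  # one-sided gradient (9 u_1 - u_2) / (3 h), restoring second-order wall
  # accuracy while keeping the implicit operator an M-matrix
  D0n <- Dn; D0s <- Ds
  Dn[prep$uN_wall] <- 2 * Dn[prep$uN_wall]; Fn[prep$uN_wall] <- 0
  Ds[prep$uS_wall] <- 2 * Ds[prep$uS_wall]; Fs[prep$uS_wall] <- 0
  Swall <- matrix(0, nx + 1, ny)
  nw <- prep$uN_wall & col(Swall) >= 2
  if (any(nw)) {
    uS1 <- cbind(0, u[, -ny, drop = FALSE])     # u[i, j-1]
    Swall[nw] <- Swall[nw] - D0n[nw] * u[nw] + (D0n[nw] / 3) * uS1[nw]
  }
  sw <- prep$uS_wall & col(Swall) <= ny - 1
  if (any(sw)) {
    uN1 <- cbind(u[, -1, drop = FALSE], 0)      # u[i, j+1]
    Swall[sw] <- Swall[sw] - D0s[sw] * u[sw] + (D0s[sw] / 3) * uN1[sw]
  }

  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  dF <- Fe - Fw + Fn - Fs
  aP <- aE + aW + aN + aS + dF

  # pressure-boundary half CVs: fold the boundary-face convection into aP
  # (outflow of uP momentum), drop the absent neighbor link
  aW[1, ] <- 0
  aP[1, ] <- aE[1, ] + aN[1, ] + aS[1, ] +
    (Fe[1, ] + Fn[1, ] - Fs[1, ] + pmax(-Fw[1, ], 0))
  aE[nx + 1, ] <- 0
  aP[nx + 1, ] <- aW[nx + 1, ] + aN[nx + 1, ] + aS[nx + 1, ] +
    (pmax(Fe[nx + 1, ], 0) - Fw[nx + 1, ] + Fn[nx + 1, ] - Fs[nx + 1, ])

  S <- Swall
  S[2:nx, ] <- S[2:nx, ] + (p[1:(nx - 1), ] - p[2:nx, ]) * hy
  S[1, ] <- S[1, ] + (p_out - p[1, ]) * hy
  S[nx + 1, ] <- S[nx + 1, ] + (p[nx, ] - bc$outlet_pressure) * hy

  if (sigma > 0) {
    shE <- function(M) rbind(M[-1, , drop = FALSE], 0)
    shW <- function(M) rbind(0, M[-nrow(M), , drop = FALSE])
    shN <- function(M) cbind(M[, -1, drop = FALSE], 0)
    shS <- function(M) cbind(0, M[, -ncol(M), drop = FALSE])
    uE1 <- shE(u); uE2 <- shE(uE1); uW1 <- shW(u); uW2 <- shW(uW1)
    uN1 <- shN(u); uN2 <- shN(uN1); uS1 <- shS(u); uS2 <- shS(uS1)
    ii <- row(u); jj <- col(u)
    # east face between u[i] and u[i+1]: upstreams u[i-1] / u[i+2]
    de <- face_defect(Fe, u, uE1, uW1, uE2,
                      ok = ii >= 2 & ii <= nx - 1)
    dw <- face_defect(Fw, uW1, u, uW2, uE1,
                      ok = ii >= 3 & ii <= nx)
    dn <- face_defect(Fn, u, uN1, uS1, uN2,
                      ok = jj >= 2 & jj <= ny - 1)
    ds <- face_defect(Fs, uS1, u, uS2, uN1,
                      ok = jj >= 3 & jj <= ny)
    S <- S - sigma * (de - dw + dn - ds)
  }

  aP <- pmax(aP, 1e-300)
  list(aE = aE, aW = aW, aN = aN, aS = aS, aP = aP, S = S)
}

# v-momentum coefficients over the nx x (ny+1) v array.
assemble_v <- function(u, v, p, mu, dom, bc, prep, sigma = 0) {
  nx <- dom$nx; ny <- dom$ny; hx <- dom$hx; hy <- dom$hy
  rho <- bc$rho

  Fn <- Fs <- matrix(0, nx, ny + 1)
  Fn[, 1:ny] <- rho * hx * 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])
  Fs[, 2:(ny + 1)] <- rho * hx * 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])

  # axial fluxes through the v-CV east/west faces (u faces at rows j-1, j)
  Fe <- Fw <- matrix(0, nx, ny + 1)
  ue <- u[2:(nx + 1), , drop = FALSE]  # nx x ny, u at east face of cell
  uw <- u[1:nx, , drop = FALSE]
  Fe[, 2:ny] <- rho * hy * 0.5 * (ue[, 1:(ny - 1)] + ue[, 2:ny])
  Fw[, 2:ny] <- rho * hy * 0.5 * (uw[, 1:(ny - 1)] + uw[, 2:ny])

  Dn <- Ds <- matrix(0, nx, ny + 1)
  Dn[, 1:ny] <- mu * hx / hy
  Ds[, 2:(ny + 1)] <- mu * hx / hy
  muc <- corner_viscosity(mu, nx, ny)            # (nx+1) x (ny+1)
  De <- muc[2:(nx + 1), ] * hy / hx
  Dw <- muc[1:nx, ] * hy / hx
  De[nx, ] <- 0                                   # east pressure outlet: zero-gradient
  # interior solid-column walls at half distance, with the same deferred
  # quadratic wall-shear correction as the u momentum
  D0e <- De; D0w <- Dw
  De[prep$vE_wall] <- 2 * De[prep$vE_wall]; Fe[prep$vE_wall] <- 0
  Dw[prep$vW_wall] <- 2 * Dw[prep$vW_wall]; Fw[prep$vW_wall] <- 0
  Swall <- matrix(0, nx, ny + 1)
  ew <- prep$vE_wall & row(Swall) >= 2
  if (any(ew)) {
    vW1 <- rbind(0, v[-nx, , drop = FALSE])      # v[i-1, j]
    Swall[ew] <- Swall[ew] - D0e[ew] * v[ew] + (D0e[ew] / 3) * vW1[ew]
  }
  ww <- prep$vW_wall & row(Swall) <= nx - 1
  if (any(ww)) {
    vE1 <- rbind(v[-1, , drop = FALSE], 0)       # v[i+1, j]
    Swall[ww] <- Swall[ww] - D0w[ww] * v[ww] + (D0w[ww] / 3) * vE1[ww]
  }
  # domain west plane: Dirichlet v=0 at hx/2 (inlet/wall rows) or
  # zero-gradient (lumen outlet rows)
  Dw[1, ] <- ifelse(prep$v_west_zgrad, 0, 2 * muc[1, ] * hy / hx)
  wpl <- !prep$v_west_zgrad
  Swall[1, wpl] <- Swall[1, wpl] - (muc[1, wpl] * hy / hx) * v[1, wpl] +
    (muc[1, wpl] * hy / hx / 3) * v[2, wpl]

  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  dF <- Fe - Fw + Fn - Fs
  aP <- aE + aW + aN + aS + dF

  # boundary folds: east outlet (value = vP), west lumen-outlet rows
  aP[nx, ] <- aW[nx, ] + aN[nx, ] + aS[nx, ] +
    (pmax(Fe[nx, ], 0) - Fw[nx, ] + Fn[nx, ] - Fs[nx, ])
  aE[nx, ] <- 0
  zg <- prep$v_west_zgrad
  if (any(zg)) {
    aP[1, zg] <- aE[1, zg] + aN[1, zg] + aS[1, zg] +
      (Fe[1, zg] + pmax(-Fw[1, zg], 0) + Fn[1, zg] - Fs[1, zg])
    aW[1, zg] <- 0
  }
  # aW[1, !zg] links to the Dirichlet 0 value: keep in aP sum, neighbor
  # contribution is zero via the shift padding.

  S <- Swall
  S[, 2:ny] <- S[, 2:ny] + (p[, 1:(ny - 1)] - p[, 2:ny]) * hx

  if (sigma > 0) {
    shE <- function(M) rbind(M[-1, , drop = FALSE], 0)
    shW <- function(M) rbind(0, M[-nrow(M), , drop = FALSE])
    shN <- function(M) cbind(M[, -1, drop = FALSE], 0)
    shS <- function(M) cbind(0, M[, -ncol(M), drop = FALSE])
    vE1 <- shE(v); vE2 <- shE(vE1); vW1 <- shW(v); vW2 <- shW(vW1)
    vN1 <- shN(v); vN2 <- shN(vN1); vS1 <- shS(v); vS2 <- shS(vS1)
    ii <- row(v); jj <- col(v)
    de <- face_defect(Fe, v, vE1, vW1, vE2,
                      ok = ii >= 2 & ii <= nx - 2)
    dw <- face_defect(Fw, vW1, v, vW2, vE1,
                      ok = ii >= 3 & ii <= nx - 1)
    dn <- face_defect(Fn, v, vN1, vS1, vN2,
                      ok = jj >= 2 & jj <= ny)
    ds <- face_defect(Fs, vS1, v, vS2, vN1,
                      ok = jj >= 3 & jj <= ny + 1)
    S <- S - sigma * (de - dw + dn - ds)
  }

  aP <- pmax(aP, 1e-300)
  list(aE = aE, aW = aW, aN = aN, aS = aS, aP = aP, S = S)
}

# Scaled residual of the unrelaxed momentum system at the current state:
# sum |aP u - (sum aNB uNB + S)| over unknowns, with the aP|u| scale
# returned separately so u and v can share one normalization.
momentum_imbalance <- function(val, co, active) {
  nr <- nrow(val); nc <- ncol(val)
  vE <- rbind(val[-1, , drop = FALSE], 0)
  vW <- rbind(0, val[-nr, , drop = FALSE])
  vN <- cbind(val[, -1, drop = FALSE], 0)
  vS <- cbind(0, val[, -nc, drop = FALSE])
  imb <- co$aP * val - (co$aE * vE + co$aW * vW + co$aN * vN +
                          co$aS * vS + co$S)
  c(sum(abs(imb[active])), sum(abs((co$aP * val)[active])))
}

# Damped Jacobi sweeps on the (under-relaxed) momentum system; fixed
# entries keep their values, which neighbor shifts then pick up naturally.
jacobi_sweep <- function(val, co, active, u0, alpha, nsweep) {
  nr <- nrow(val); nc <- ncol(val)
  aPr <- co$aP / alpha
  Sfull <- co$S + (1 - alpha) / alpha * co$aP * u0
  for (s in seq_len(nsweep)) {
    vE <- rbind(val[-1, , drop = FALSE], 0)
    vW <- rbind(0, val[-nr, , drop = FALSE])
    vN <- cbind(val[, -1, drop = FALSE], 0)
    vS <- cbind(0, val[, -nc, drop = FALSE])
    upd <- (co$aE * vE + co$aW * vW + co$aN * vN + co$aS * vS + Sfull) / aPr
    val[active] <- upd[active]
  }
  val
}

# ---- pressure correction ----------------------------------------------------

# Build the pressure-correction matrix from the current face d-coefficients
# (d = face area / relaxed aP). Symmetric positive definite; Dirichlet
# p' = 0 at the pressure boundaries enters through diagonal-only terms.
build_pressure_matrix <- function(du, dv, dom, prep) {
  nx <- dom$nx; ny <- dom$ny; hx <- dom$hx; hy <- dom$hy
  idx <- function(i, j) i + (j - 1L) * nx
  II <- matrix(rep(seq_len(nx), ny), nx, ny)
  JJ <- matrix(rep(seq_len(ny), each = nx), nx, ny)

  cE <- matrix(0, nx, ny)
  cE[1:(nx - 1), ] <- du[2:nx, ] * hy * (prep$u_class[2:nx, ] == 1L)
  cN <- matrix(0, nx, ny)
  cN[, 1:(ny - 1)] <- dv[, 2:ny] * hx * (prep$v_class[, 2:ny] == 1L)
  # boundary (diagonal-only) terms
  cBw <- numeric(ny); cBe <- numeric(ny)
  cBw[prep$u_class[1, ] == 2L] <- du[1, prep$u_class[1, ] == 2L] * hy
  cBe[prep$u_class[nx + 1, ] == 3L] <- du[nx + 1, prep$u_class[nx + 1, ] == 3L] * hy

  diag_v <- cE + cN
  diag_v[2:nx, ] <- diag_v[2:nx, ] + cE[1:(nx - 1), ]
  diag_v[, 2:ny] <- diag_v[, 2:ny] + cN[, 1:(ny - 1)]
  diag_v[1, ] <- diag_v[1, ] + cBw
  diag_v[nx, ] <- diag_v[nx, ] + cBe
  diag_v[!dom$mask] <- 1
  diag_v[diag_v == 0] <- 1   # isolated fluid cells (none expected)

  eM <- cE > 0
  nM <- cN > 0
  i0 <- c(idx(II, JJ)[eM], idx(II, JJ)[nM], idx(II, JJ)[eM] + 1L,
          idx(II, JJ)[nM] + nx, seq_len(nx * ny))
  j0 <- c(idx(II, JJ)[eM] + 1L, idx(II, JJ)[nM] + nx, idx(II, JJ)[eM],
          idx(II, JJ)[nM], seq_len(nx * ny))
  x0 <- c(-cE[eM], -cN[nM], -cE[eM], -cN[nM], as.vector(diag_v))
  Matrix::sparseMatrix(i = i0, j = j0, x = x0, dims = c(nx * ny, nx * ny))
}

# ---- main driver ------------------------------------------------------------

#' Solve steady laminar flow in a catheter-tip domain
#'
#' Runs SIMPLE pressure-velocity coupling with upwind convection, central
#' diffusion and Picard-updated Carreau viscosity until the scaled
#' continuity residual drops below tolerance *and* (when the domain has a
#' catheter lumen) the recovered lumen outflow lies within tolerance of
#' the volumetric target. The lumen-outlet gauge pressure is adjusted by a
#' secant iteration between residual-converged states to hit the flow
#' target; the adjusted pressure and the full convergence history are
#' returned.
#'
#' @param domain A [tip_geometry()] (rasterized at `settings$spacing`) or a
#'   prebuilt [rasterize_geometry()] result.
#' @param bc A [boundary_spec()].
#' @param rheo A [carreau_parameters()]. A Newtonian fluid is the special
#'   case `mu_zero == mu_inf` (use [newtonian_parameters()]).
#' @param settings A [solver_settings()].
#' @param init Optional previous [solve_steady()] solution (possibly on a
#'   coarser grid) used as the initial state; its outlet pressure and
#'   flow measurement also seed the secant iteration.
#' @param verbose Print residual progress.
#' @return An object of class `flow_solution`: the cell-centered
#'   [structured_field()] (with viscosity and mask), staggered face
#'   velocities, pressure, the adjusted outlet pressure `p_out`, recovered
#'   outflow (mL/min 2D-equivalent), convergence flag and per-iteration
#'   history (continuity residual, outflow error).
#' @export
solve_steady <- function(domain, bc = boundary_spec(),
                         rheo = carreau_parameters(),
                         settings = solver_settings(), init = NULL,
                         verbose = FALSE) {
  dom <- if (inherits(domain, "tip_geometry"))
    rasterize_geometry(domain, settings$spacing) else domain
  stopifnot(inherits(dom, "raster_domain"), inherits(bc, "boundary_spec"),
            inherits(rheo, "carreau_parameters"))
  nx <- dom$nx; ny <- dom$ny; hx <- dom$hx; hy <- dom$hy
  geom <- dom$geom
  prep <- solver_prep(dom, bc)
  has_lumen <- length(dom$lumen_rows) > 0
  q_t <- if (has_lumen) ml_min_to_flux2d(bc$outflow_ml_min, geom$lumen_height)
         else NA_real_

  # initial state
  u <- prep$u_fix
  v <- matrix(0, nx, ny + 1)
  p <- matrix(0, nx, ny)
  p_out <- -400
  secant_pts <- list()
  if (is.null(init)) {
    open_rows <- dom$west_type == "inlet"
    for (j in which(open_rows)) u[prep$u_class[, j] > 0L, j] <- bc$inlet_speed
    if (has_lumen)
      for (j in dom$lumen_rows)
        u[prep$u_class[, j] > 0L & dom$xf <= geom$insertion_length, j] <-
          -q_t / geom$lumen_height
  } else {
    stopifnot(inherits(init, "flow_solution"))
    su <- sample_field_matrix(init$field, "u", dom$xf, dom$yc)
    sv <- sample_field_matrix(init$field, "v", dom$xc, dom$yf)
    u[prep$u_class > 0L] <- su[prep$u_class > 0L]
    v[prep$v_class > 0L] <- sv[prep$v_class > 0L]
    p <- sample_matrix_on(init$p, init$field$x, init$field$y, dom$xc, dom$yc)
    p_out <- init$p_out
    if (length(init$secant) >= 1)
      secant_pts <- init$secant[length(init$secant)]
  }

  mu <- cell_viscosity(u, v, dom, rheo)
  u_active <- prep$u_class > 0L
  v_active <- prep$v_class == 1L
  maskv <- as.vector(dom$mask)

  hist_res <- numeric(0); hist_mom <- numeric(0)
  hist_q <- numeric(0); hist_p <- numeric(0)
  # the higher-order convective defect switches on only after the upwind
  # transient has settled (it is a correction about a physical state, not
  # a startup scheme)
  sigma_iter <- if (!is.null(init)) 0L else NA_integer_
  ch <- NULL
  converged <- FALSE
  last_change <- 0L
  n_secant <- 0L
  resid <- Inf
  Q <- NA_real_

  for (iter in seq_len(settings$max_iter)) {
    mu_new <- cell_viscosity(u, v, dom, rheo)
    mu <- mu + settings$relax_mu * (mu_new - mu)

    u0 <- u; v0 <- v
    # ramp the defect in over 500 iterations once the transient settles
    sigma_cur <- if (is.na(sigma_iter)) 0 else
      settings$convection_blend * min(1, (iter - sigma_iter) / 500)
    co_u <- assemble_u(u, v, p, mu, dom, bc, prep, p_out, sigma = sigma_cur)
    u <- jacobi_sweep(u, co_u, u_active, u0, settings$relax_u,
                      settings$momentum_sweeps)
    co_v <- assemble_v(u, v, p, mu, dom, bc, prep, sigma = sigma_cur)
    v <- jacobi_sweep(v, co_v, v_active, v0, settings$relax_u,
                      settings$momentum_sweeps)

    du <- matrix(0, nx + 1, ny)
    du[u_active] <- hy / (co_u$aP[u_active] / settings$relax_u)
    dv <- matrix(0, nx, ny + 1)
    dv[v_active] <- hx / (co_v$aP[v_active] / settings$relax_u)

    m <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) * hy +
      (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) * hx
    m[!dom$mask] <- 0
    resid <- sum(abs(m)) / prep$q_in
    mi_u <- momentum_imbalance(u, co_u, u_active)
    mi_v <- momentum_imbalance(v, co_v, v_active)
    resid_mom <- (mi_u[1] + mi_v[1]) / max(mi_u[2] + mi_v[2], 1e-300)
    Q <- if (has_lumen) -sum(u[1, dom$lumen_rows]) * hy else NA_real_

    hist_res <- c(hist_res, resid)
    hist_mom <- c(hist_mom, resid_mom)
    hist_q <- c(hist_q, Q)
    hist_p <- c(hist_p, p_out)

    if (is.na(sigma_iter) && resid < 1e-2) sigma_iter <- iter
    if (!is.finite(resid) || resid > 1e6)
      stop(sprintf(
        "solver diverged at iteration %d (scaled continuity residual %g)",
        iter, resid), call. = FALSE)

    if (is.null(ch) || iter %% settings$refactor_every == 0L) {
      A <- build_pressure_matrix(du, dv, dom, prep)
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
    }
    pp <- matrix(as.vector(Matrix::solve(ch, -as.vector(m))), nx, ny)
    pp[!dom$mask] <- 0

    p <- p + settings$relax_p * pp
    u[2:nx, ] <- u[2:nx, ] +
      du[2:nx, ] * (pp[1:(nx - 1), ] - pp[2:nx, ]) *
        (prep$u_class[2:nx, ] == 1L)
    u[1, ] <- u[1, ] - du[1, ] * pp[1, ] * (prep$u_class[1, ] == 2L)
    u[nx + 1, ] <- u[nx + 1, ] +
      du[nx + 1, ] * pp[nx, ] * (prep$u_class[nx + 1, ] == 3L)
    v[, 2:ny] <- v[, 2:ny] +
      dv[, 2:ny] * (pp[, 1:(ny - 1)] - pp[, 2:ny]) *
        (prep$v_class[, 2:ny] == 1L)

    if (verbose && iter %% 200 == 0)
      message(sprintf("  iter %6d  resid %.3e  mom %.3e  Q %.4g  p_out %.1f",
                      iter, resid, resid_mom, Q, p_out))

    if (resid < settings$tol_continuity &&
          resid_mom < settings$tol_momentum && iter - last_change >= 50L) {
      if (!has_lumen || abs(Q - q_t) <= settings$tol_outflow * q_t) {
        converged <- TRUE
        break
      }
      secant_pts[[length(secant_pts) + 1]] <- c(p_out = p_out, Q = Q)
      n_secant <- n_secant + 1L
      if (n_secant > settings$max_secant) break
      np <- length(secant_pts)
      if (np == 1L) {
        p_out <- if (Q > 0.05 * q_t) p_out * q_t / Q else p_out * 4
      } else {
        a <- secant_pts[[np - 1]]; b <- secant_pts[[np]]
        dQ <- b["Q"] - a["Q"]
        p_out <- if (abs(dQ) > 1e-12 * q_t)
          unname(b["p_out"] - (b["Q"] - q_t) * (b["p_out"] - a["p_out"]) / dQ)
        else p_out * 1.2
      }
      p_out <- min(max(p_out, -1e6), 1e4)
      last_change <- iter
    }
  }

  if (!converged)
    warning(sprintf(
      "solve_steady did not converge (residual %.3g, outflow error %.3g%%)",
      resid, if (has_lumen) 100 * abs(Q - q_t) / q_t else 0), call. = FALSE)

  # cell-centered output field with exact Carreau viscosity
  uc <- 0.5 * (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE])
  gam_exact <- cell_shear_rate(u, v, dom)
  mu_exact <- matrix(carreau_viscosity(rheo, as.vector(gam_exact)), nx, ny)
  field <- structured_field(dom$xc, dom$yc, uc, vc, viscosity = mu_exact,
                            mask = dom$mask)
  attr(field, "shear_rate") <- gam_exact
  attr(field, "domain_meta") <- list(
    x_tip = geom$insertion_length,
    lumen_y = if (has_lumen) geom$layout$y_lumen else NULL)

  structure(list(
    field = field, p = p, u = u, v = v, p_out = p_out,
    outflow_ml_min = if (has_lumen)
      flux2d_to_ml_min(Q, geom$lumen_height) else NA_real_,
    converged = converged, iterations = length(hist_res),
    residual = resid,
    history = data.frame(iteration = seq_along(hist_res),
                         continuity_residual = hist_res,
                         momentum_residual = hist_mom,
                         outflow = hist_q, p_out = hist_p),
    secant = secant_pts, domain = dom, bc = bc, rheo = rheo,
    settings = settings), class = "flow_solution")
}

#' Newtonian parameter set
#'
#' Degenerate Carreau parameters with equal plateaus, giving a constant
#' viscosity (used for analytic channel-flow verification).
#'
#' @param mu Constant viscosity (Pa s).
#' @return A `carreau_parameters` object with `mu_zero` infinitesimally
#'   above `mu_inf`.
#' @export
newtonian_parameters <- function(mu = 0.0035) {
  stop_unless(is_pos_scalar(mu), "mu must be positive")
  structure(list(mu_inf = mu, mu_zero = mu * (1 + 1e-12), lambda_time = 1,
                 n_index = 1), class = "carreau_parameters")
}

# bilinear sampling helpers used for warm starts --------------------------------

# sample one velocity component of a field on an arbitrary lattice,
# clamping outside coordinates to the field hull
sample_field_matrix <- function(field, comp, xs, ys) {
  M <- field[[comp]]
  sample_matrix_on(M, field$x, field$y, xs, ys)
}

sample_matrix_on <- function(M, x0, y0, xs, ys) {
  xs <- pmin(pmax(xs, x0[1]), x0[length(x0)])
  ys <- pmin(pmax(ys, y0[1]), y0[length(y0)])
  ix <- pmin(pmax(findInterval(xs, x0), 1L), length(x0) - 1L)
  iy <- pmin(pmax(findInterval(ys, y0), 1L), length(y0) - 1L)
  wx <- (xs - x0[ix]) / (x0[ix + 1] - x0[ix])
  wy <- (ys - y0[iy]) / (y0[iy + 1] - y0[iy])
  out <- matrix(0, length(xs), length(ys))
  for (jj in seq_along(ys)) {
    c1 <- M[cbind(ix, iy[jj])] * (1 - wx) + M[cbind(ix + 1L, iy[jj])] * wx
    c2 <- M[cbind(ix, iy[jj] + 1L)] * (1 - wx) +
      M[cbind(ix + 1L, iy[jj] + 1L)] * wx
    out[, jj] <- c1 * (1 - wy[jj]) + c2 * wy[jj]
  }
  out
}

# ---- diagnostics ------------------------------------------------------------

#' Scaled continuity residual
#'
#' Sum of absolute per-cell volumetric imbalances, normalized by the vessel
#' inlet flux (for solver solutions) or by `max speed x domain height` (for
#' bare fields). Zero for any discretely divergence-free field; strictly
#' positive off the divergence-free set.
#'
#' @param x A `flow_solution` or [structured_field()].
#' @param ... Unused.
#' @return Scalar residual (dimensionless).
#' @export
continuity_residual <- function(x, ...) UseMethod("continuity_residual")

#' @export
continuity_residual.flow_solution <- function(x, ...) {
  dom <- x$domain
  prep_qin <- x$bc$inlet_speed * sum(dom$west_type == "inlet") * dom$hy
  nx <- dom$nx; ny <- dom$ny
  m <- (x$u[2:(nx + 1), , drop = FALSE] - x$u[1:nx, , drop = FALSE]) * dom$hy +
    (x$v[, 2:(ny + 1), drop = FALSE] - x$v[, 1:ny, drop = FALSE]) * dom$hx
  m[!dom$mask] <- 0
  sum(abs(m)) / prep_qin
}

#' @export
continuity_residual.structured_field <- function(x, ...) {
  nx <- length(x$x); ny <- length(x$y)
  dx <- diff(x$x); dy <- diff(x$y)
  ue <- 0.5 * (x$u[, 1:(ny - 1), drop = FALSE] + x$u[, 2:ny, drop = FALSE])
  vn <- 0.5 * (x$v[1:(nx - 1), , drop = FALSE] + x$v[2:nx, , drop = FALSE])
  m <- sweep(ue[2:nx, , drop = FALSE] - ue[1:(nx - 1), , drop = FALSE],
             2, dy, `*`) +
    sweep(vn[, 2:ny, drop = FALSE] - vn[, 1:(ny - 1), drop = FALSE],
          1, dx, `*`)
  uref <- max(sqrt(x$u^2 + x$v^2))
  if (uref == 0) return(0)
  sum(abs(m)) / (uref * (max(x$y) - min(x$y)))
}

#' Boundary volume fluxes of a converged solve
#'
#' Per-depth volumetric fluxes (m^2/s) through each boundary segment,
#' positive into the domain, and their net sum (which vanishes to within
#' the continuity tolerance at convergence).
#'
#' @param sol A `flow_solution`.
#' @return Named list: `inlet`, `vessel_outlet`, `lumen_outlet`, `net`.
#' @export
boundary_fluxes <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  dom <- sol$domain
  inlet <- sum(sol$u[1, dom$west_type == "inlet"]) * dom$hy
  lumen <- sum(sol$u[1, dom$lumen_rows]) * dom$hy          # negative = out
  vout <- -sum(sol$u[dom$nx + 1, dom$mask[dom$nx, ]]) * dom$hy
  list(inlet = inlet, vessel_outlet = vout, lumen_outlet = lumen,
       net = inlet + vout + lumen)
}

#' @exportS3Method
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d x %d cells, %s after %d iterations\n",
              x$domain$nx, x$domain$ny,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  continuity residual: %.3e\n", x$residual))
  if (is.finite(x$outflow_ml_min))
    cat(sprintf("  lumen outflow: %.2f mL/min (2D-equivalent) at p_out = %.1f Pa\n",
                x$outflow_ml_min, x$p_out))
  cat(sprintf("  max speed: %.4g m/s\n", max(sqrt(x$field$u^2 + x$field$v^2))))
  invisible(x)
}

#' @exportS3Method
summary.flow_solution <- function(object, ...) {
  bf <- boundary_fluxes(object)
  sp <- sqrt(object$field$u^2 + object$field$v^2)
  out <- list(
    converged = object$converged, iterations = object$iterations,
    residual = object$residual, p_out = object$p_out,
    outflow_ml_min = object$outflow_ml_min,
    max_speed = max(sp),
    viscosity_range = range(object$field$viscosity),
    net_flux = bf$net, fluxes = bf)
  class(out) <- "summary.flow_solution"
  out
}

#' @exportS3Method
print.summary.flow_solution <- function(x, ...) {
  cat(sprintf(
    "SIMPLE solve: %s, %d iterations, residual %.3e\n",
    if (x$converged) "converged" else "not converged", x$iterations,
    x$residual))
  cat(sprintf("  p_out %.1f Pa, outflow %.2f mL/min, max speed %.4g m/s\n",
              x$p_out, x$outflow_ml_min, x$max_speed))
  cat(sprintf("  viscosity [%.4g, %.4g] Pa s, net boundary flux %.3e m^2/s\n",
              x$viscosity_range[1], x$viscosity_range[2], x$net_flux))
  invisible(x)
}

#' @exportS3Method
plot.flow_solution <- function(x, ...) plot(x$field, ...)
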