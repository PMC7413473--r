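# Shear-thinning blood rheology: scalar shear rate from a velocity gradient
# and the asymptotic Carreau viscosity law.

#' Carreau rheology parameters
#'
#' Parameter set for the asymptotic Carreau shear-thinning viscosity model
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}.}
#' The defaults are the standard whole-blood constants used for laminar
#' catheter-inflow modelling: a zero-shear plateau of 0.025 Pa s, an
#' infinite-shear plateau of 0.00345 Pa s, a relaxation time of 25 s and a
#' power-law index of 0.25.
#'
#' @param mu_inf Viscosity at infinite shear (Pa s).
#' @param mu_zero Viscosity at zero shear (Pa s). Must exceed `mu_inf`.
#' @param lambda_time Relaxation time \eqn{\lambda} (s).
#' @param n_index Power-law index \eqn{n}, in (0, 1].
#' @return An object of class `carreau_parameters`.
#' @examples
#' cp <- carreau_parameters()
#' carreau_viscosity(cp, 0)     # zero-shear plateau, 0.025 Pa s
#' carreau_viscosity(cp, 1e9)   # infinite-shear plateau, ~0.00345 Pa s
#' @export
carreau_parameters <- function(mu_inf = 0.00345, mu_zero = 0.025,
                               lambda_time = 25, n_index = 0.25) {
  stop_unless(is_pos_scalar(mu_inf), "mu_inf must be a positive finite scalar")
  stop_unless(is_pos_scalar(mu_zero), "mu_zero must be a positive finite scalar")
  stop_unless(mu_zero > mu_inf, "mu_zero must exceed mu_inf")
  stop_unless(is_pos_scalar(lambda_time), "lambda_time must be positive")
  stop_unless(is_pos_scalar(n_index) && n_index <= 1,
              "n_index must lie in (0, 1]")
  structure(list(mu_inf = mu_inf, mu_zero = mu_zero,
                 lambda_time = lambda_time, n_index = n_index),
            class = "carreau_parameters")
}

#' @exportS3Method
print.carreau_parameters <- function(x, ...) {
  cat("Carreau parameters:\n")
  cat(sprintf("  mu_inf  = %g Pa s\n  mu_zero = %g Pa s\n", x$mu_inf, x$mu_zero))
  cat(sprintf("  lambda  = %g s\n  n       = %g\n", x$lambda_time, x$n_index))
  invisible(x)
}

#' Scalar shear-rate magnitude of a velocity gradient
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\, D_{ij} D_{ij}}} where
#' \eqn{D = (G + G^T)/2} is the strain-rate (deformation) tensor of the
#' velocity-gradient tensor \eqn{G_{ij} = \partial u_i / \partial x_j}.
#' Antisymmetric (rigid-rotation) parts of the gradient do not contribute,
#' and the result is invariant under rotation of the coordinate frame.
#'
#' @param grad Velocity gradient: a 3x3 (or 2x2, embedded as zero
#'   out-of-plane components) numeric matrix, entries in 1/s.
#' @return Scalar shear rate (1/s), non-negative.
#' @examples
#' G <- matrix(0, 3, 3); G[1, 2] <- 100  # simple shear du/dy = 100/s
#' shear_rate_magnitude(G)               # 100
#' @export
shear_rate_magnitude <- function(grad) {
  grad <- as_gradient3(grad)
  D <- (grad + t(grad)) / 2
  sqrt(2 * sum(D * D))
}

# Accept 2x2 or 3x3, validate finiteness.
as_gradient3 <- function(grad) {
  stop_unless(is.matrix(grad) && nrow(grad) == ncol(grad) &&
                nrow(grad) %in% c(2L, 3L),
              "velocity gradient must be a 2x2 or 3x3 matrix")
  stop_unless(all(is.finite(grad)),
              "velocity gradient contains non-finite entries")
  if (nrow(grad) == 2L) {
    G <- matrix(0, 3, 3)
    G[1:2, 1:2] <- grad
    G
  } else {
    grad
  }
}

#' Carreau viscosity at a given shear rate
#'
#' Evaluates the asymptotic Carreau law (see [carreau_parameters()]).
#' The viscosity is bounded in \eqn{[\mu_\infty, \mu_0]} and is strictly
#' decreasing in the shear rate for \eqn{n < 1}.
#'
#' @param params A [carreau_parameters()] object.
#' @param gamma_dot Shear rate(s), 1/s, non-negative. Vectorized.
#' @return Viscosity (Pa s), same length as `gamma_dot`.
#' @export
carreau_viscosity <- function(params, gamma_dot) {
  stopifnot(inherits(params, "carreau_parameters"))
  stop_unless(all(is.finite(gamma_dot)) && all(gamma_dot >= 0),
              "gamma_dot must be finite and non-negative")
  params$mu_inf + (params$mu_zero - params$mu_inf) *
    (1 + (params$lambda_time * gamma_dot)^2)^((params$n_index - 1) / 2)
}

#' Scalar viscous shear stress
#'
#' The scalar stress magnitude \eqn{\tau = \mu(\dot\gamma)\,\dot\gamma}
#' used for laminar non-Newtonian reporting: the Carreau viscosity at the
#' local shear rate times that shear rate. Zero exactly when the shear rate
#' is zero, and strictly increasing in the shear rate (the viscosity is
#' bounded below by \eqn{\mu_\infty > 0}).
#'
#' @inheritParams carreau_viscosity
#' @return Stress (Pa), same length as `gamma_dot`.
#' @export
scalar_shear_stress <- function(params, gamma_dot) {
  carreau_viscosity(params, gamma_dot) * gamma_dot
}

# Vectorized shear-rate magnitude on gradient-component arrays (2D planar).
# Used by the solver and tracker on whole grids.
shear_rate_components <- function(dudx, dudy, dvdx, dvdy) {
  d12 <- (dudy + dvdx) / 2
  sqrt(2 * (dudx^2 + dvdy^2 + 2 * d12^2))
}
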