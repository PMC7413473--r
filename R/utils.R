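# Small internal validation and unit helpers.

stop_unless <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

is_pos_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

is_nonneg_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}

# Volumetric conversions. 2D fields carry per-unit-depth fluxes (m^2/s);
# reports use the volumetric scale via an effective depth (m).
M3S_PER_MLMIN <- 1e-6 / 60

ml_min_to_m3s <- function(q) q * M3S_PER_MLMIN
m3s_to_ml_min <- function(q) q / M3S_PER_MLMIN

# Effective out-of-plane depth of the 2D lumen analog: area of a semicircular
# lumen whose radius equals the 2D lumen height, divided by that height.
lumen_effective_depth <- function(lumen_height) pi * lumen_height / 2

# Per-depth 2D flux (m^2/s) equivalent to a volumetric rate (mL/min).
ml_min_to_flux2d <- function(q_ml_min, lumen_height) {
  ml_min_to_m3s(q_ml_min) / lumen_effective_depth(lumen_height)
}

flux2d_to_ml_min <- function(q2d, lumen_height) {
  m3s_to_ml_min(q2d * lumen_effective_depth(lumen_height))
}
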