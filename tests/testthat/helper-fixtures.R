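# Shared fixtures, built in code at test time.

# downscaled pit spec that fits a 96^3 grid at 26 nm
tiny_pit_spec <- function(scale = 1) {
  pit_spec(chamber_diameter_nm = 1560 * scale,
           membrane_thickness_nm = 260 * scale,
           canal_slit_width_nm = 520 * scale,
           canal_slit_minor_nm = 208 * scale,
           chamber_depth_nm = 780 * scale,
           wall_thickness_nm = 702 * scale)
}

tiny_pit_phantom <- function(grid = 96, ...) {
  build_pit_pair_phantom(tiny_pit_spec(), grid_shape = rep(grid, 3),
                         pitch_nm = 26, ...)
}

# compact weak-phase blob phantom: a sphere of dilute material; at the
# default delta the projected |phi| peaks near 0.07 rad (weak object)
weak_blob_phantom <- function(n = 128, delta = 8e-7, radius_frac = 0.25) {
  c0 <- (n + 1) / 2
  r2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
  lab <- array(0L, dim = c(n, n, n))
  rad <- radius_frac * n
  for (k in seq_len(n)) {
    lab[, , k] <- (r2 + (k - c0)^2 <= rad^2) * 1L
  }
  mats <- list("0" = material("air", 0, 0),
               "1" = material("dilute", delta, 0))
  as_phantom_volume(lab, 26, mats)
}

# geometry whose per-pixel Fresnel number is large enough that a small
# frame contains the holographic fringes (short defocus distances)
near_geometry <- function(n = 128, defocus_mm = c(0.25, 0.3, 0.36),
                          n_projections = 12L) {
  geometry_config(defocus_mm = defocus_mm,
                  n_detector_pixels = n,
                  n_projections = n_projections,
                  angle_step_deg = 180 / n_projections)
}

# centred Gaussian complex field (amplitude waist w0 pixels)
gauss_field <- function(n, w0) {
  c0 <- (n + 1) / 2
  r2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
  exp(-r2 / w0^2)
}

# analytic parallel-beam sinogram of a centred disc
disc_sinogram <- function(n, radius, value, n_angles, n_slices = 1) {
  u <- seq_len(n) - (n + 1) / 2
  p <- ifelse(abs(u) < radius,
              2 * value * sqrt(pmax(radius^2 - u^2, 0)), 0)
  array(rep(p, n_slices * n_angles), dim = c(n, n_slices, n_angles))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
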