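# X-ray optical constants. The refractive index of a material at hard X-ray
# energies is n = 1 - delta + i beta; delta (the decrement) drives the phase
# shift, beta the absorption. Far from absorption edges delta follows the
# classical electron-density relation
#   delta = r_e lambda^2 n_e / (2 pi),  n_e = rho N_A (Z/A),
# which is accurate enough for light organic matter and is used here for
# defaults; beta is set as a configurable fraction of delta (weak
# absorption).

.r_e_nm <- 2.8179403262e-6      # classical electron radius in nm
.N_A <- 6.02214076e23

#' X-ray material
#'
#' @param name Material name.
#' @param delta Refractive index decrement (>= 0).
#' @param beta Absorption index (>= 0).
#' @param density_g_cm3 Optional mass density.
#' @return An object of class `nfh_material`.
#' @export
material <- function(name, delta, beta, density_g_cm3 = NA_real_) {
  if (delta < 0 || beta < 0) stop("invalid-argument: delta and beta must be >= 0")
  structure(list(name = name, delta = delta, beta = beta,
                 density_g_cm3 = density_g_cm3),
            class = "nfh_material")
}

#' Material from mass density via the electron-density relation
#'
#' `delta = r_e lambda^2 n_e / (2 pi)` with electron density
#' `n_e = rho N_A (Z/A)`; `beta = delta * beta_over_delta`.
#'
#' @param name Material name.
#' @param density_g_cm3 Mass density (g/cm^3), positive.
#' @param Z_over_A Electrons per atomic mass unit (0 < Z/A <= 1); about 0.53
#'   for cellulose, 31/69.72 for gallium.
#' @param energy_keV Photon energy (keV).
#' @param beta_over_delta Ratio beta/delta (weak absorption default 0.01).
#' @return An `nfh_material`.
#' @examples
#' material_from_density("cellulose", 1.5, 0.53, 11.0) # delta ~ 2.7e-6
#' @export
material_from_density <- function(name, density_g_cm3, Z_over_A, energy_keV,
                                  beta_over_delta = 0.01) {
  if (density_g_cm3 <= 0) stop("invalid-argument: density must be positive")
  if (Z_over_A <= 0 || Z_over_A > 1) {
    stop("invalid-argument: Z_over_A must be in (0, 1]")
  }
  lam <- wavelength_from_energy(energy_keV)          # nm
  n_e <- density_g_cm3 * .N_A * Z_over_A * 1e-21     # electrons per nm^3
  delta <- .r_e_nm * lam^2 * n_e / (2 * pi)
  material(name, delta, delta * beta_over_delta, density_g_cm3)
}

#' Default material table for wood phantoms
#'
#' Labels: 0 = air/void (vacuum), 1 = cell wall (cellulose-like, density
#' 1.5 g/cm^3), 2 = pit membrane (same wall polymer), 3 = gallium
#' (FIB-implanted surface layer, density 5.91 g/cm^3). Gallium has a
#' strictly larger delta than the wall, mirroring its higher refractive
#' index in the reconstructions.
#'
#' @param energy_keV Photon energy (keV).
#' @param beta_over_delta_wood,beta_over_delta_ga Absorption ratios.
#' @return Named list of `nfh_material`, names are the label integers.
#' @export
default_materials <- function(energy_keV = 11.0,
                              beta_over_delta_wood = 0.01,
                              beta_over_delta_ga = 0.05) {
  wall <- material_from_density("cell wall", 1.5, 0.53, energy_keV,
                                beta_over_delta_wood)
  list("0" = material("air", 0, 0),
       "1" = wall,
       "2" = material("pit membrane", wall$delta, wall$beta, 1.5),
       "3" = material_from_density("gallium", 5.91, 31 / 69.72, energy_keV,
                                   beta_over_delta_ga))
}

#' @export
print.nfh_material <- function(x, ...) {
  cat(sprintf("material '%s': delta = %.4g, beta = %.4g\n",
              x$name, x$delta, x$beta))
  invisible(x)
}
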