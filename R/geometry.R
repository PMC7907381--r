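# Cone-beam NFH geometry and its effective parallel-beam description.
#
# The instrument places the specimen a short defocus distance z1 behind the
# focus of the optics and the detector far downstream at z_det. The Fresnel
# scaling theorem maps this point-source (cone-beam) arrangement onto an
# equivalent parallel-beam experiment with magnification M = z_det / z1,
# effective propagation distance z_eff = z1 (z_det - z1) / z_det and
# effective pixel = detector pixel / M. Everything downstream of this module
# works exclusively in effective quantities.

#' Photon wavelength from energy
#'
#' @param energy_keV Photon energy in keV; must be positive.
#' @return Wavelength in nanometres (`hc/E` with `hc` = 1.23984193 keV nm).
#' @examples
#' wavelength_from_energy(11.0) # 0.1127 nm
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (!is.numeric(energy_keV) || any(!is.finite(energy_keV)) ||
      any(energy_keV <= 0)) {
    stop("invalid-argument: energy_keV must be positive and finite")
  }
  1.23984193 / energy_keV
}

#' Effective parallel-beam geometry of a point-source hologram
#'
#' Applies the Fresnel scaling theorem: a cone-beam hologram recorded with
#' focus-to-sample distance `z1` and focus-to-detector distance `z_det` is
#' equivalent to a parallel-beam hologram at magnification `M = z_det/z1`
#' and effective distance `z_eff = z1 (z_det - z1) / z_det`.
#'
#' @param z1_mm Focus-to-sample (defocus) distance in mm. Vectorised.
#' @param z_det_m Focus-to-detector distance in metres.
#' @return A list with elements `magnification` and `z_eff_mm`.
#' @examples
#' effective_geometry(70, 16.269) # M = 232.4, z_eff = 69.70 mm
#' @export
effective_geometry <- function(z1_mm, z_det_m) {
  z_det_mm <- z_det_m * 1e3
  if (any(z1_mm <= 0) || z_det_m <= 0) {
    stop("invalid-geometry: distances must be strictly positive")
  }
  if (any(z1_mm >= z_det_mm)) {
    stop("invalid-geometry: every defocus distance z1 must be < z_det")
  }
  list(magnification = z_det_mm / z1_mm,
       z_eff_mm = z1_mm * (z_det_mm - z1_mm) / z_det_mm)
}

#' Fresnel number on the effective pixel
#'
#' `F = pixel^2 / (lambda * z_eff)`, the dimensionless number governing the
#' near-field propagation regime. Defined here on the effective detector
#' pixel (conventions differ; some authors use a feature size or the field
#' of view). For this instrument geometry it is of order 1e-4.
#'
#' @param pixel_nm Effective pixel size in nm.
#' @param wavelength_nm Wavelength in nm.
#' @param z_eff_mm Effective propagation distance in mm. Vectorised.
#' @return Dimensionless Fresnel number, one value per distance.
#' @export
fresnel_number <- function(pixel_nm, wavelength_nm, z_eff_mm) {
  if (any(pixel_nm <= 0) || any(wavelength_nm <= 0) || any(z_eff_mm <= 0)) {
    stop("invalid-argument: all arguments must be positive")
  }
  pixel_nm^2 / (wavelength_nm * (z_eff_mm * 1e6))
}

#' Scanning-geometry configuration
#'
#' Bundles the beamline scan parameters. Derived quantities (wavelength,
#' magnification, effective distance, Fresnel number, angle schedule) are
#' always recomputed from these primitives via [geometry_derived()] and
#' [angle_schedule()], never stored.
#'
#' @param energy_keV Photon energy (keV).
#' @param defocus_mm Vector of focus-to-sample distances z1 (mm).
#' @param detector_distance_m Focus-to-detector distance z_det (m).
#' @param effective_pixel_nm Isotropic effective pixel size (nm).
#' @param n_detector_pixels Detector format per side (the instrument's
#'   53.2 um field of view over 26 nm pixels is about 2046; 2048 is the
#'   assumed camera format and is configurable).
#' @param n_projections Number of projections over the half turn.
#' @param angle_step_deg Rotation step (degrees);
#'   `n_projections * angle_step_deg` must equal 180.
#' @param exposure_s Exposure per frame (s).
#' @return An object of class `geometry_config`.
#' @examples
#' g <- geometry_config()
#' geometry_derived(g)
#' @export
geometry_config <- function(energy_keV = 11.0,
                            defocus_mm = c(70, 71, 72),
                            detector_distance_m = 16.269,
                            effective_pixel_nm = 26,
                            n_detector_pixels = 2048L,
                            n_projections = 900L,
                            angle_step_deg = 0.2,
                            exposure_s = 1) {
  if (energy_keV <= 0) stop("invalid-argument: energy_keV must be positive")
  if (any(defocus_mm <= 0) || detector_distance_m <= 0 ||
      effective_pixel_nm <= 0 || exposure_s <= 0) {
    stop("invalid-argument: all distances and times must be positive")
  }
  if (any(defocus_mm >= detector_distance_m * 1e3)) {
    stop("invalid-geometry: every defocus distance must be < z_det")
  }
  if (abs(n_projections * angle_step_deg - 180) > 1e-9) {
    stop("invalid-argument: n_projections * angle_step_deg must equal 180")
  }
  structure(list(energy_keV = energy_keV,
                 defocus_mm = defocus_mm,
                 detector_distance_m = detector_distance_m,
                 effective_pixel_nm = effective_pixel_nm,
                 n_detector_pixels = as.integer(n_detector_pixels),
                 n_projections = as.integer(n_projections),
                 angle_step_deg = angle_step_deg,
                 exposure_s = exposure_s),
            class = "geometry_config")
}

#' Derived geometry table
#'
#' @param config A [geometry_config()].
#' @return A data.frame with one row per defocus distance: `z1_mm`,
#'   `magnification`, `z_eff_mm`, `fresnel_number`, plus the wavelength as
#'   attribute `wavelength_nm`.
#' @export
geometry_derived <- function(config) {
  stopifnot(inherits(config, "geometry_config"))
  lam <- wavelength_from_energy(config$energy_keV)
  eff <- effective_geometry(config$defocus_mm, config$detector_distance_m)
  out <- data.frame(z1_mm = config$defocus_mm,
                    magnification = eff$magnification,
                    z_eff_mm = eff$z_eff_mm,
                    fresnel_number = fresnel_number(config$effective_pixel_nm,
                                                   lam, eff$z_eff_mm))
  attr(out, "wavelength_nm") <- lam
  out
}

#' Tomographic angle schedule
#'
#' @param config A [geometry_config()], or the number of projections when
#'   `angle_step_deg` is given.
#' @param angle_step_deg Step in degrees (only when `config` is a count).
#' @return Strictly increasing angles in degrees spanning `[0, 180)`.
#' @export
angle_schedule <- function(config, angle_step_deg = NULL) {
  if (inherits(config, "geometry_config")) {
    n <- config$n_projections
    step <- config$angle_step_deg
  } else {
    n <- as.integer(config)
    step <- angle_step_deg
  }
  seq(0, by = step, length.out = n)
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("NFH scan geometry\n")
  cat(sprintf("  energy: %.3f keV (lambda = %.6f nm)\n", x$energy_keV,
              wavelength_from_energy(x$energy_keV)))
  cat(sprintf("  defocus z1: %s mm; detector at %.3f m\n",
              paste(x$defocus_mm, collapse = ", "), x$detector_distance_m))
  d <- geometry_derived(x)
  cat(sprintf("  M = %s; z_eff = %s mm; F = %s\n",
              paste(sprintf("%.2f", d$magnification), collapse = ", "),
              paste(sprintf("%.3f", d$z_eff_mm), collapse = ", "),
              paste(sprintf("%.3g", d$fresnel_number), collapse = ", ")))
  cat(sprintf("  pixel %.1f nm, %d px; %d projections x %.2f deg, %.1f s\n",
              x$effective_pixel_nm, x$n_detector_pixels, x$n_projections,
              x$angle_step_deg, x$exposure_s))
  invisible(x)
}

#' Read a scan geometry from a YAML config file
#'
#' Recognised keys (unit suffixes mandatory): `energy_keV`, `defocus_mm`,
#' `detector_distance_m`, `effective_pixel_nm`, `n_detector_pixels`,
#' `n_projections`, `angle_step_deg`, `exposure_s`.
#'
#' @param path Path to a YAML file.
#' @return A [geometry_config()].
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(geometry_config))
  unknown <- setdiff(names(cfg), c(allowed, "seed"))
  if (length(unknown)) {
    stop("invalid-argument: unknown geometry keys: ",
         paste(unknown, collapse = ", "))
  }
  do.call(geometry_config, cfg[intersect(names(cfg), allowed)])
}
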