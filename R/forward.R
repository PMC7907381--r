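# Wave-optical forward model.
#
# Projection approximation: the exit wave behind a thin object is
#   u = exp(i phi - mu),  phi = -(2 pi / lambda) sum_m delta_m t_m,
#                          mu  =  (2 pi / lambda) sum_m beta_m t_m,
# with t_m the traversed thickness of material m. Free-space propagation to
# the (effective) detector plane uses the Fourier transfer function
#   H(f) = exp(-i pi lambda z |f|^2),
# i.e. the near-field (paraxial) propagator; the recorded hologram is
# |u_z|^2. The cone beam is never simulated explicitly: the Fresnel scaling
# theorem reduces each defocus distance to parallel-beam propagation over
# z_eff at the effective pixel. With the pixel as length unit the
# propagator depends only on the per-pixel Fresnel number F:
# H(nu) = exp(-i pi |nu|^2 / F), nu in cycles/pixel.

#' Per-material projected thickness maps
#'
#' Rotates the phantom about its vertical (z) axis by `angle_deg` and
#' integrates each material's indicator along the beam; rotation uses
#' bilinear interpolation. The integration runs over `ny` unit steps, so
#' the summed thickness over all labels (air included) never exceeds
#' `ny * pitch`.
#'
#' @param vol A `phantom_volume`.
#' @param angle_deg Rotation angle in `[0, 180)`.
#' @return Named list (by label, `"0"` = air) of `nx x nz` thickness maps
#'   in nm, indexed `[u, v]`.
#' @export
project_thickness <- function(vol, angle_deg) {
  stopifnot(inherits(vol, "phantom_volume"))
  if (angle_deg < 0 || angle_deg >= 180) {
    stop("invalid-argument: angle_deg must be in [0, 180)")
  }
  d <- dim(vol$labels)
  th <- angle_deg * pi / 180
  lev <- sort(unique(as.integer(vol$labels)))
  out <- list()
  for (l in lev) {
    ind <- array(as.numeric(vol$labels == l), dim = d)
    out[[as.character(l)]] <-
      cpp_project_volume(ind, d[1], d[2], d[3], th) * vol$pitch_nm
  }
  out
}

#' Exit wave from thickness maps
#'
#' @param thickness_maps Named list of per-material thickness maps (nm),
#'   names matching labels in `materials`.
#' @param materials Label-to-material map (see [default_materials()]).
#' @param wavelength_nm Wavelength (nm).
#' @return Complex matrix; unit amplitude and zero phase where all
#'   thicknesses vanish, nonpositive phase for delta >= 0.
#' @export
exit_wave <- function(thickness_maps, materials, wavelength_nm) {
  dims <- lapply(thickness_maps, dim)
  if (length(unique(dims)) != 1) {
    stop("invalid-argument: thickness maps must share one shape")
  }
  phi <- matrix(0, dims[[1]][1], dims[[1]][2])
  mu <- phi
  for (l in names(thickness_maps)) {
    if (l == "0") next
    m <- materials[[l]]
    if (is.null(m)) stop("invalid-argument: no material for label ", l)
    phi <- phi - (2 * pi / wavelength_nm) * m$delta * thickness_maps[[l]]
    mu <- mu + (2 * pi / wavelength_nm) * m$beta * thickness_maps[[l]]
  }
  exp(-mu) * exp(1i * phi)
}

# propagation by per-pixel Fresnel number (sign of F = sign of z);
# bg is the asymptotic field value: the deviation (field - bg) is tapered,
# zero-padded by pad_factor and propagated, the constant bg passes through
# H(0) = 1 unchanged.
propagate_px <- function(field, F_px, pad_factor = 2, bg = 0,
                         apodize = TRUE) {
  if (!is.finite(F_px)) return(field)
  n <- dim(field)
  d <- field - bg
  if (apodize) {
    w <- max(4L, round(min(n) / 16))
    d <- d * outer(edge_taper(n[1], w), edge_taper(n[2], w))
  }
  N <- pad_factor * n
  D <- matrix(0 + 0i, N[1], N[2])
  o1 <- floor((N[1] - n[1]) / 2); o2 <- floor((N[2] - n[2]) / 2)
  D[o1 + seq_len(n[1]), o2 + seq_len(n[2])] <- d
  chi <- pi * outer(fftfreq(N[1])^2, fftfreq(N[2])^2, "+") / F_px
  out <- ifft2(stats::fft(D) * exp(-1i * chi))
  bg + out[o1 + seq_len(n[1]), o2 + seq_len(n[2])]
}

#' Near-field Fresnel propagation
#'
#' Transfer-function (Fourier) propagation with zero-padding factor 2 and
#' raised-cosine edge apodization of the deviation from `bg`. `z = 0`
#' returns the field unchanged; negative distances back-propagate.
#'
#' @param field Complex (or numeric) matrix.
#' @param wavelength_nm Wavelength (nm), positive.
#' @param distance_mm Propagation distance (mm), any sign.
#' @param pixel_nm Pixel size (nm), positive.
#' @param bg Asymptotic background value of the field (0 for beams, 1 for
#'   exit waves of compact objects in vacuum).
#' @param pad_factor,apodize Padding and apodization controls.
#' @return Complex matrix of the propagated field, input shape.
#' @export
fresnel_propagate <- function(field, wavelength_nm, distance_mm, pixel_nm,
                              bg = 0, pad_factor = 2, apodize = TRUE) {
  if (pixel_nm <= 0 || wavelength_nm <= 0) {
    stop("invalid-argument: pixel_nm and wavelength_nm must be positive")
  }
  if (distance_mm == 0) return(field)
  F_px <- pixel_nm^2 / (wavelength_nm * distance_mm * 1e6)
  propagate_px(field, F_px, pad_factor = pad_factor, bg = bg,
               apodize = apodize)
}

#' Simulate a multi-distance hologram stack
#'
#' For each angle: project the phantom, form the exit wave, propagate by
#' each distance's effective distance, record `|u|^2`, multiply by that
#' distance's flat field and (optionally) apply Poisson photon noise.
#'
#' @param vol A `phantom_volume` whose pitch equals the geometry's
#'   effective pixel.
#' @param geometry A [geometry_config()].
#' @param flats `NULL` (unit flats) or a list/3D array of per-distance flat
#'   fields matching the frame shape, strictly positive.
#' @param photons_per_pixel Mean photon count scale for Poisson noise;
#'   `NULL` disables noise.
#' @param angles_deg Angle list; defaults to [angle_schedule()] of the
#'   geometry.
#' @param seed RNG seed making the noise deterministic.
#' @return A `hologram_stack`: `intensities[u, v, angle, distance]`,
#'   `flats[u, v, distance]`, `angles_deg`, `geometry`.
#' @export
simulate_hologram_stack <- function(vol, geometry, flats = NULL,
                                    photons_per_pixel = NULL,
                                    angles_deg = NULL, seed = NULL) {
  stopifnot(inherits(vol, "phantom_volume"),
            inherits(geometry, "geometry_config"))
  if (abs(vol$pitch_nm - geometry$effective_pixel_nm) > 1e-9) {
    stop("invalid-geometry: phantom pitch must equal the effective pixel")
  }
  d <- dim(vol$labels)
  nu <- d[1]; nv <- d[3]
  angles_deg <- angles_deg %||% angle_schedule(geometry)
  der <- geometry_derived(geometry)
  lam <- attr(der, "wavelength_nm")
  F_px <- der$fresnel_number
  nd <- nrow(der)
  if (is.null(flats)) {
    flats <- array(1, dim = c(nu, nv, nd))
  } else if (is.list(flats)) {
    flats <- array(unlist(flats), dim = c(nu, nv, nd))
  }
  if (!all(dim(flats) == c(nu, nv, nd))) {
    stop("invalid-argument: flats must be [nu, nv, n_distances]")
  }
  if (any(flats <= 0)) stop("invalid-flat: flat fields must be positive")

  dv <- material_volume(vol, "delta")
  bv <- material_volume(vol, "beta")
  any_beta <- any(bv != 0)
  intens <- array(0, dim = c(nu, nv, length(angles_deg), nd))
  with_seed(seed, {
    for (a in seq_along(angles_deg)) {
      th <- angles_deg[a] * pi / 180
      if (any_beta) {
        pr <- cpp_project_volume2(dv, bv, d[1], d[2], d[3], th)
        phi <- -(2 * pi / lam) * pr$a * vol$pitch_nm
        u0 <- exp(-(2 * pi / lam) * pr$b * vol$pitch_nm) * exp(1i * phi)
      } else {
        pd <- cpp_project_volume(dv, d[1], d[2], d[3], th) * vol$pitch_nm
        u0 <- exp(1i * (-(2 * pi / lam) * pd))
      }
      for (k in seq_len(nd)) {
        # exact vacuum-padded propagation: the phantom pillar ends inside
        # the frame, so padding with the vacuum value needs no taper
        I <- Mod(propagate_px(u0, F_px[k], bg = 1, apodize = FALSE))^2
        I <- I * flats[, , k]
        if (!is.null(photons_per_pixel)) {
          I <- matrix(stats::rpois(length(I), I * photons_per_pixel),
                      nu, nv) / photons_per_pixel
        }
        intens[, , a, k] <- I
      }
    }
  })
  structure(list(intensities = intens, flats = flats,
                 angles_deg = angles_deg, geometry = geometry,
                 pitch_nm = vol$pitch_nm),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("hologram stack: %d x %d px, %d angles, %d distances\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
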