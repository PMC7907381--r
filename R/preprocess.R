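# Stage (i): flat-field correction, multi-distance co-registration and
# geometry refinement.

#' Flat-field correction
#'
#' Elementwise `I / I0`. When `I` is a `hologram_stack` every frame is
#' divided by its distance's flat and the stored flats are reset to 1.
#'
#' @param I Intensity frame (matrix) or a `hologram_stack`.
#' @param I0 Flat field, same shape as `I` (ignored for stacks).
#' @return Corrected frame or stack.
#' @export
flat_field_correct <- function(I, I0 = NULL) {
  if (inherits(I, "hologram_stack")) {
    if (any(I$flats <= 0)) stop("invalid-flat: flat field must be positive")
    nd <- dim(I$intensities)[4]
    for (k in seq_len(nd)) {
      I$intensities[, , , k] <- I$intensities[, , , k] /
        as.vector(I$flats[, , k])
    }
    I$flats[] <- 1
    return(I)
  }
  if (!all(dim(I) == dim(I0))) {
    stop("invalid-argument: I and I0 must have equal shapes")
  }
  if (any(I0 <= 0)) stop("invalid-flat: flat field must be positive")
  I / I0
}

#' Magnification rescale factors between defocus distances
#'
#' Factor `M_ref / M_i` that brings distance `i`'s frames to the reference
#' distance's magnification; for z1 = 70 vs 71 mm this is 71/70.
#'
#' @param geometry A [geometry_config()].
#' @param reference Index of the reference distance.
#' @return Numeric vector, one factor per distance (reference = 1).
#' @export
magnification_rescale_factors <- function(geometry, reference = 1) {
  M <- geometry_derived(geometry)$magnification
  M[reference] / M
}

#' Co-register the defocus distances of a hologram stack
#'
#' Rescales each distance's frames to the reference magnification (for
#' data on a per-distance pixel grid) and removes residual translations by
#' cross-correlation with subpixel refinement. The forward simulator emits
#' all distances on one common effective-pixel grid, in which case
#' `rescale = "none"` is appropriate and only shifts are corrected.
#'
#' @param stack A flat-field-corrected `hologram_stack`.
#' @param reference Reference distance index.
#' @param rescale `"magnification"` (factors `M_ref/M_i`) or `"none"`.
#' @param corr_threshold Below this normalized correlation the frame is
#'   left unshifted (with a warning).
#' @return The registered stack; attribute `"registration"` holds a
#'   data.frame of per-frame applied shifts and residuals (px).
#' @export
register_multidistance <- function(stack, reference = 1,
                                   rescale = c("magnification", "none"),
                                   corr_threshold = 0.2) {
  stopifnot(inherits(stack, "hologram_stack"))
  rescale <- match.arg(rescale)
  d <- dim(stack$intensities)
  nd <- d[4]
  if (nd < 2) stop("invalid-argument: need >= 2 distances to register")
  factors <- if (rescale == "magnification") {
    magnification_rescale_factors(stack$geometry, reference)
  } else rep(1, nd)
  log <- NULL
  for (k in seq_len(nd)) {
    if (k == reference) next
    for (a in seq_len(d[3])) {
      fr <- stack$intensities[, , a, k]
      if (factors[k] != 1) fr <- rescale_image(fr, factors[k], fill = 1)
      ref <- stack$intensities[, , a, reference]
      s <- xcorr_shift(ref, fr)
      cc <- attr(s, "correlation")
      if (!is.finite(cc) || cc < corr_threshold) {
        warning("registration correlation below threshold for distance ",
                k, ", angle index ", a, "; identity shift used")
        s <- c(0, 0)
      }
      if (any(s != 0)) fr <- fourier_shift(fr, -s)
      res <- xcorr_shift(ref, fr)
      stack$intensities[, , a, k] <- fr
      log <- rbind(log, data.frame(distance = k, angle_index = a,
                                   shift_u = s[1], shift_v = s[2],
                                   residual_u = res[1], residual_v = res[2],
                                   correlation = cc))
    }
  }
  attr(stack, "registration") <- log
  stack
}

#' Refine the Fresnel number of a hologram
#'
#' Grid search around `F_initial` minimizing the total variation of the
#' single-shot CTF phase estimate (residual defocus fringes raise the TV;
#' the sharpest, cleanest phase map marks the correct F). The criterion
#' function is pluggable.
#'
#' @param hologram Flat-field-corrected hologram (matrix).
#' @param F_initial Starting per-pixel Fresnel number.
#' @param search_halfwidth Relative half-width of the search interval.
#' @param n_grid Number of grid points.
#' @param alpha CTF regularization used by the criterion.
#' @param criterion Function(phase matrix) -> score to minimize.
#' @return The refined Fresnel number; attributes `"grid"` and `"score"`.
#' @export
refine_fresnel_number <- function(hologram, F_initial,
                                  search_halfwidth = 0.1, n_grid = 21,
                                  alpha = 5e-3, criterion = NULL) {
  if (stats::sd(hologram) < 1e-8 * max(abs(mean(hologram)), 1e-12)) {
    stop("cannot-refine: hologram has no contrast")
  }
  if (is.null(criterion)) {
    criterion <- function(phi) {
      sum(abs(diff(phi))) + sum(abs(t(diff(t(phi)))))
    }
  }
  grid <- F_initial * seq(1 - search_halfwidth, 1 + search_halfwidth,
                          length.out = n_grid)
  score <- vapply(grid, function(Fk) {
    criterion(ctf_retrieve(list(hologram), Fk, alpha = alpha))
  }, numeric(1))
  out <- grid[which.min(score)]
  attr(out, "grid") <- grid
  attr(out, "score") <- score
  out
}
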