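# Stage (ii): multi-distance phase retrieval and destriping.
#
# Linear path: contrast-transfer-function (CTF) inversion. For a weak
# pure-phase object the hologram spectrum obeys
#   FT(I - 1)(nu) = 2 sin(pi |nu|^2 / F_d) FT(phi)(nu)
# per distance d, inverted jointly over distances by Tikhonov-regularized
# least squares. Nonlinear path: averaged alternating projections between
# the per-distance data sets (replace modulus by sqrt(I) at the detector)
# and the object constraint set (phase and amplitude ranges, optional
# support), started from the CTF estimate.

#' Multi-distance CTF phase retrieval (single projection)
#'
#' @param holograms List or 3D array `[u, v, distance]` of flat-field
#'   corrected holograms (all same shape).
#' @param F_list Per-pixel Fresnel number per distance.
#' @param alpha Tikhonov regularization added to the summed squared CTF
#'   (stabilizes zero crossings and the near-DC band). With a single
#'   distance and `alpha <= 0` the inversion is ill-posed (warning).
#' @param pad Zero-pad factor-2 before the FFTs.
#' @param offset `"border"` re-zeroes the phase on the frame border median
#'   (the unrecoverable DC term), `"none"` leaves it.
#' @return Phase map in radians (matrix).
#' @export
ctf_retrieve <- function(holograms, F_list, alpha = 1e-3, pad = TRUE,
                         offset = c("border", "none")) {
  offset <- match.arg(offset)
  if (is.array(holograms) && length(dim(holograms)) == 3) {
    holograms <- lapply(seq_len(dim(holograms)[3]),
                        function(k) holograms[, , k])
  }
  nd <- length(holograms)
  if (nd < 1) stop("invalid-argument: need at least one distance")
  if (length(F_list) != nd) {
    stop("invalid-argument: F_list length must match the distance count")
  }
  if (alpha <= 0 && nd == 1) {
    warning("ill-posed: single-distance CTF inversion without regularization")
  }
  n <- dim(holograms[[1]])
  N <- if (pad) 2L * n else n
  nu2 <- outer(fftfreq(N[1])^2, fftfreq(N[2])^2, "+")
  num <- matrix(0 + 0i, N[1], N[2])
  den <- matrix(max(alpha, 0), N[1], N[2])
  for (k in seq_len(nd)) {
    s <- 2 * sin(pi * nu2 / F_list[k])
    num <- num + s * stats::fft(pad_center(holograms[[k]] - 1, N))
    den <- den + s^2
  }
  phi <- Re(ifft2(num / den))
  phi <- crop_center(phi, n)
  if (offset == "border") {
    b <- max(2L, min(8L, floor(min(n) / 16)))
    border <- c(phi[seq_len(b), ], phi[n[1] + 1 - seq_len(b), ],
                phi[, seq_len(b)], phi[, n[2] + 1 - seq_len(b)])
    phi <- phi - stats::median(border)
  }
  phi
}

default_constraints <- function() {
  list(phase_min = -3, phase_max = 0, amp_min = 0.9, amp_max = 1,
       support = NULL)
}

#' Iterative projection phase retrieval (single projection)
#'
#' Averaged alternating projections on a zero-padded (factor-2) grid:
#' (a) data projection — propagate the current padded object estimate to
#' each distance, replace the modulus by `sqrt(I)` on the measured
#' window (the padded margin keeps its computed values, so forward and
#' backward propagation stay exact inverses), back-propagate and average
#' over distances; (b) object projection — clip the phase to
#' `[phase_min, phase_max]` and the amplitude to `[amp_min, amp_max]`,
#' reset the field to vacuum (1) outside the support mask if one is
#' given, and to vacuum outside the measured window (the specimen lies
#' inside the frame).
#'
#' @param holograms As in [ctf_retrieve()].
#' @param F_list Per-pixel Fresnel numbers.
#' @param phi_init Initial phase (e.g. the CTF estimate); zeros if `NULL`.
#' @param constraints List with `phase_min`, `phase_max`, `amp_min`,
#'   `amp_max`, optional logical `support` (frame-shaped); must not be
#'   empty.
#' @param n_iter Maximum iterations.
#' @param tol Stop when the relative change of the data misfit drops below
#'   this.
#' @param pad_factor Padded-grid oversampling factor.
#' @param scheme Update rule: `"aap"` (averaged alternating projections),
#'   `"dm"` (Douglas-Rachford / difference map, typically several times
#'   faster here) or `"raar"` (relaxed averaged alternating reflections,
#'   `beta = 0.75`).
#' @return List: `phase`, `amplitude`, `misfit_trace` (relative RMS data
#'   misfit per iteration, element 1 = at the initial estimate),
#'   `iterations`, `converged`.
#' @export
iterative_retrieve <- function(holograms, F_list, phi_init = NULL,
                               constraints = default_constraints(),
                               n_iter = 50, tol = 1e-6, pad_factor = 2,
                               scheme = c("aap", "dm", "raar")) {
  scheme <- match.arg(scheme)
  if (is.array(holograms) && length(dim(holograms)) == 3) {
    holograms <- lapply(seq_len(dim(holograms)[3]),
                        function(k) holograms[, , k])
  }
  if (length(constraints) == 0) {
    stop("under-constrained: empty constraint set refused")
  }
  if (any(vapply(holograms, function(h) any(!is.finite(h)), logical(1)))) {
    stop("invalid-input: non-finite values in holograms")
  }
  n <- dim(holograms[[1]])
  if (!is.null(phi_init) && !all(dim(phi_init) == n)) {
    stop("invalid-argument: phi_init shape must match the frames")
  }
  cs <- utils::modifyList(default_constraints(), constraints)
  nd <- length(holograms)
  sq <- lapply(holograms, function(h) sqrt(pmax(h, 0)))
  Itot <- sum(vapply(holograms, sum, numeric(1)))
  N <- pad_factor * n
  o1 <- floor((N[1] - n[1]) / 2); o2 <- floor((N[2] - n[2]) / 2)
  w1 <- o1 + seq_len(n[1]); w2 <- o2 + seq_len(n[2])
  nu2 <- outer(fftfreq(N[1])^2, fftfreq(N[2])^2, "+")
  H <- lapply(F_list, function(F) exp(-1i * pi * nu2 / F))
  # averaged data projection; also records the current data misfit
  mis_last <- NA_real_
  proj_data <- function(u) {
    f0 <- stats::fft(u - 1)
    accf <- matrix(0 + 0i, N[1], N[2])
    mis <- 0
    for (k in seq_len(nd)) {
      ud <- 1 + ifft2(f0 * H[[k]])
      m <- Mod(ud[w1, w2])
      mis <- mis + sum((m - sq[[k]])^2)
      ud[w1, w2] <- sq[[k]] * ud[w1, w2] / pmax(m, 1e-12)
      accf <- accf + stats::fft(ud - 1) * Conj(H[[k]])
    }
    mis_last <<- sqrt(mis / Itot)
    1 + ifft2(accf) / nd
  }
  last_ph <- NULL
  last_am <- NULL
  proj_obj <- function(u) {
    uw <- u[w1, w2]
    ph <- Arg(uw)
    # phases can exceed -pi (strong objects); Arg() wraps them to +pi.
    # With a nonpositive phase range the branch is unambiguous: map
    # wrapped values back below -pi when the range allows them.
    if (cs$phase_min < -pi) {
      wrapped <- ph > 2 * pi + cs$phase_min
      ph[wrapped] <- ph[wrapped] - 2 * pi
    }
    ph <- pmin(pmax(ph, cs$phase_min), cs$phase_max)
    am <- pmin(pmax(Mod(uw), cs$amp_min), cs$amp_max)
    if (!is.null(cs$support)) {
      ph[!cs$support] <- 0
      am[!cs$support] <- 1
    }
    last_ph <<- ph
    last_am <<- am
    out <- matrix(1 + 0i, N[1], N[2])
    out[w1, w2] <- am * exp(1i * ph)
    out
  }
  u <- matrix(1 + 0i, N[1], N[2])
  if (!is.null(phi_init)) u[w1, w2] <- exp(1i * phi_init)
  beta <- 0.75
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < n_iter) {
    it <- it + 1
    pd <- proj_data(u)
    trace <- c(trace, mis_last)
    u <- switch(scheme,
      aap = proj_obj(pd),
      dm = u + proj_obj(2 * pd - u) - pd,
      raar = {
        rd <- 2 * pd - u
        beta / 2 * (2 * proj_obj(rd) - rd + u) + (1 - beta) * pd
      })
    nt <- length(trace)
    if (nt >= 2 &&
        abs(trace[nt] - trace[nt - 1]) < tol * max(trace[nt - 1], 1e-15)) {
      converged <- TRUE
      break
    }
  }
  # report the constrained estimate (for dm/raar the iterate itself is not
  # feasible; project it once)
  if (scheme != "aap") u <- proj_obj(proj_data(u))
  if (is.null(last_ph)) u <- proj_obj(u)
  list(phase = last_ph, amplitude = last_am,
       misfit_trace = trace, iterations = it, converged = converged)
}

#' Retrieve phases for every projection of a hologram stack
#'
#' @param stack A flat-field-corrected `hologram_stack`.
#' @param method `"ctf"` or `"iterative"` (CTF initialization + projection
#'   iterations).
#' @param alpha CTF regularization.
#' @param n_iter,constraints,tol,scheme Iterative-path controls (see
#'   [iterative_retrieve()]).
#' @param warm_start Initialize each angle's iterations from the previous
#'   angle's solution (adjacent views differ by a fraction of a degree, so
#'   most of the work carries over). Cheaper per angle, but the residual
#'   errors become correlated across angles and can backproject into ring
#'   artifacts near the rotation axis; the default keeps every angle
#'   independent.
#' @param n_iter_first Iterations for the first (cold-started) angle.
#' @param n_passes Sweeps over the angle set. The first sweep warm-chains
#'   along the rotation; later sweeps refine every angle from its own
#'   previous estimate, removing the slight rotational lag of the chain.
#' @return A `phase_projection_set`: `phases[u, v, angle]` (radians),
#'   `angles_deg`, `pitch_nm`, `provenance`.
#' @export
retrieve_phases <- function(stack, method = c("ctf", "iterative"),
                            alpha = 1e-3, n_iter = 6,
                            constraints = default_constraints(),
                            tol = 1e-6, scheme = "dm", warm_start = FALSE,
                            n_iter_first = NULL, n_passes = 1) {
  stopifnot(inherits(stack, "hologram_stack"))
  method <- match.arg(method)
  d <- dim(stack$intensities)
  F_list <- geometry_derived(stack$geometry)$fresnel_number
  phases <- array(0, dim = d[1:3])
  n_iter_first <- n_iter_first %||% max(3L * n_iter, 25L)
  if (method == "ctf") n_passes <- 1
  iters <- 0
  prev <- NULL
  for (p in seq_len(n_passes)) {
    for (a in seq_len(d[3])) {
      holos <- lapply(seq_len(d[4]),
                      function(k) stack$intensities[, , a, k])
      if (p == 1 && (method == "ctf" || !warm_start || is.null(prev))) {
        phi <- ctf_retrieve(holos, F_list, alpha = alpha)
      }
      if (method == "iterative") {
        if (p > 1) {
          init <- phases[, , a]
          ni <- n_iter
        } else if (warm_start && !is.null(prev)) {
          init <- prev
          ni <- n_iter
        } else {
          init <- pmin(phi, 0)
          # n_iter_first is the cold start of a warm chain; independent
          # angles all run n_iter
          ni <- if (warm_start) n_iter_first else n_iter
        }
        r <- iterative_retrieve(holos, F_list, phi_init = init,
                                constraints = constraints, n_iter = ni,
                                tol = tol, scheme = scheme)
        phi <- r$phase
        prev <- phi
        iters <- iters + r$iterations
      }
      phases[, , a] <- phi
    }
  }
  structure(list(phases = phases, angles_deg = stack$angles_deg,
                 pitch_nm = stack$pitch_nm,
                 provenance = list(method = method, alpha = alpha,
                                   scheme = if (method == "iterative") scheme,
                                   total_iterations = iters)),
            class = "phase_projection_set")
}

#' @export
print.phase_projection_set <- function(x, ...) {
  d <- dim(x$phases)
  cat(sprintf("phase projections: %d x %d px, %d angles (%s)\n",
              d[1], d[2], d[3], x$provenance$method %||% "unknown"))
  invisible(x)
}

# one-level 2D Haar split along both dims: returns list(LL, HL, LH, HH)
# where the first letter refers to dim 1 (u) and the second to dim 2 (v)
haar_split <- function(m) {
  o1 <- seq(1, nrow(m), by = 2)
  a1 <- (m[o1, , drop = FALSE] + m[o1 + 1, , drop = FALSE]) / sqrt(2)
  d1 <- (m[o1, , drop = FALSE] - m[o1 + 1, , drop = FALSE]) / sqrt(2)
  o2 <- seq(1, ncol(m), by = 2)
  list(LL = (a1[, o2, drop = FALSE] + a1[, o2 + 1, drop = FALSE]) / sqrt(2),
       LH = (a1[, o2, drop = FALSE] - a1[, o2 + 1, drop = FALSE]) / sqrt(2),
       HL = (d1[, o2, drop = FALSE] + d1[, o2 + 1, drop = FALSE]) / sqrt(2),
       HH = (d1[, o2, drop = FALSE] - d1[, o2 + 1, drop = FALSE]) / sqrt(2))
}

haar_merge <- function(b) {
  a1 <- matrix(0, nrow(b$LL), 2 * ncol(b$LL))
  d1 <- a1
  o2 <- seq(1, ncol(a1), by = 2)
  a1[, o2] <- (b$LL + b$LH) / sqrt(2)
  a1[, o2 + 1] <- (b$LL - b$LH) / sqrt(2)
  d1[, o2] <- (b$HL + b$HH) / sqrt(2)
  d1[, o2 + 1] <- (b$HL - b$HH) / sqrt(2)
  m <- matrix(0, 2 * nrow(a1), ncol(a1))
  o1 <- seq(1, nrow(m), by = 2)
  m[o1, ] <- (a1 + d1) / sqrt(2)
  m[o1 + 1, ] <- (a1 - d1) / sqrt(2)
  m
}

# Remove the stripe-consistent component of a v-detail band. Stripes
# are exactly coherent along u, so they live in the zero u-frequency
# row and tower above the band's spectrum there; object structure of
# finite u-extent continues smoothly across the zero frequency. The
# zero-frequency coefficients are therefore damped only down to 1.25x
# the magnitude of their immediate nonzero-frequency neighbours
# (outlier-limited notch): stripes lose their coherent excess, object
# content passes. sigma > 1 adds a plain Gaussian notch on the lowest
# nonzero frequencies for stripes that are not perfectly uniform.
damp_dc_dim1 <- function(band, sigma) {
  m <- nrow(band)
  if (m < 6) return(band)
  fb <- stats::mvfft(band)
  ref <- 1.25 * pmax(Mod(fb[2, ]), Mod(fb[3, ]),
                     Mod(fb[m, ]), Mod(fb[m - 1, ]))
  fac <- pmin(1, ref / pmax(Mod(fb[1, ]), 1e-300))
  fb[1, ] <- fb[1, ] * fac
  if (sigma > 1) {
    k <- pmin(seq(0, m - 1), seq(m, 1))
    g <- 1 - exp(-k^2 / (2 * sigma^2))
    g[1] <- 1
    fb <- fb * g
  }
  Re(stats::mvfft(fb, inverse = TRUE)) / m
}

destripe_frame <- function(m, orientation, levels, sigma) {
  flip <- orientation == "vertical"
  if (flip) m <- t(m)
  n0 <- dim(m)
  mult <- 2^levels
  N <- ceiling(n0 / mult) * mult
  if (any(N != n0)) {
    big <- matrix(0, N[1], N[2])
    big[seq_len(n0[1]), seq_len(n0[2])] <- m
    if (N[1] > n0[1]) big[(n0[1] + 1):N[1], seq_len(n0[2])] <-
      m[n0[1] + 1 - seq_len(N[1] - n0[1]), , drop = FALSE]
    if (N[2] > n0[2]) big[, (n0[2] + 1):N[2]] <-
      big[, n0[2] + 1 - seq_len(N[2] - n0[2]), drop = FALSE]
    m <- big
  }
  rec <- function(x, lev) {
    if (lev == 0 || nrow(x) < 4 || ncol(x) < 4) return(x)
    b <- haar_split(x)
    # stripes constant along u live in the u-low-passed, v-high-passed band
    b$LH <- damp_dc_dim1(b$LH, sigma)
    b$LL <- rec(b$LL, lev - 1)
    haar_merge(b)
  }
  m <- rec(m, levels)
  m <- m[seq_len(n0[1]), seq_len(n0[2]), drop = FALSE]
  if (flip) t(m) else m
}

#' Remove stripe artifacts from phase projections
#'
#' Wavelet-Fourier destriping: per frame, a multiscale Haar decomposition
#' isolates the band that is low-pass along the stripe axis and high-pass
#' across it; a Gaussian notch suppresses its near-DC coefficients along
#' the stripe axis, removing structure that is constant along the stripes
#' while preserving object texture.
#'
#' @param x Matrix or `phase_projection_set`.
#' @param orientation `"horizontal"` (stripes constant along u, the
#'   default for monochromator artifacts) or `"vertical"`.
#' @param levels Decomposition depth.
#' @param damping_sigma Additional Gaussian notch width
#'   (frequency-index units) applied when greater than 1. Flat-field
#'   stripes are exactly constant along the stripe axis and are always
#'   handled by the outlier-limited zero-frequency damping; values above
#'   1 additionally damp the lowest nonzero frequencies for stripes that
#'   are not perfectly uniform (at the cost of eroding stripe-shaped
#'   anatomy, so the default leaves them alone).
#' @param ... Unused.
#' @return Same type as `x`, destriped.
#' @export
destripe <- function(x, orientation = c("horizontal", "vertical"),
                     levels = 6, damping_sigma = 0.6, ...) {
  orientation <- match.arg(orientation)
  if (inherits(x, "phase_projection_set")) {
    for (a in seq_len(dim(x$phases)[3])) {
      x$phases[, , a] <- destripe_frame(x$phases[, , a], orientation,
                                        levels, damping_sigma)
    }
    x$provenance$destriped <- TRUE
    return(x)
  }
  destripe_frame(x, orientation, levels, damping_sigma)
}

#' Stripe-band energy of a frame
#'
#' Energy of the Fourier coefficients that are constant along the stripe
#' axis (zero frequency along `u` for horizontal stripes), DC excluded;
#' the metric behind the destriping efficiency checks.
#'
#' @param m Matrix.
#' @param orientation As in [destripe()].
#' @return Scalar band energy.
#' @export
stripe_band_energy <- function(m, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (orientation == "vertical") m <- t(m)
  f <- stats::fft(m)
  sum(Mod(f[1, -1])^2) / length(m)
}
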