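# small internal numerics helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code with a temporarily seeded RNG, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# DFT sample frequencies in cycles per sample, numpy-style ordering
fftfreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1))
  k / n
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# centred zero-padding of a matrix into shape N (vector of 2)
pad_center <- function(m, N, fill = 0) {
  out <- matrix(fill, N[1], N[2])
  o1 <- floor((N[1] - nrow(m)) / 2)
  o2 <- floor((N[2] - ncol(m)) / 2)
  out[o1 + seq_len(nrow(m)), o2 + seq_len(ncol(m))] <- m
  out
}

crop_center <- function(m, n) {
  o1 <- floor((nrow(m) - n[1]) / 2)
  o2 <- floor((ncol(m) - n[2]) / 2)
  m[o1 + seq_len(n[1]), o2 + seq_len(n[2])]
}

# separable raised-cosine edge taper, 1 in the interior, ->0 at the border
edge_taper <- function(n, width) {
  t1 <- rep(1, n)
  if (width > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(width) - 0.5) / width))
    t1[seq_len(width)] <- ramp
    t1[n + 1 - seq_len(width)] <- ramp
  }
  t1
}

# subpixel Fourier shift: out(x) = img(x - s)
fourier_shift <- function(img, s) {
  f1 <- fftfreq(nrow(img))
  f2 <- fftfreq(ncol(img))
  ph <- exp(-2i * pi * outer(f1 * s[1], f2 * s[2], "+"))
  Re(ifft2(stats::fft(img) * ph))
}

# Displacement of image b relative to image a (b(x) ~ a(x - s)) by
# cross-correlation with local DFT upsampling. Returns c(s1, s2) and the
# normalized correlation peak as attribute "correlation".
xcorr_shift <- function(a, b, upsample = 50, refine_halfwidth = 1) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0) {
    out <- c(0, 0); attr(out, "correlation") <- 0
    return(out)
  }
  Fa <- stats::fft(a0); Fb <- stats::fft(b0)
  Q <- Conj(Fa) * Fb
  cc <- Re(ifft2(Q))
  p <- arrayInd(which.max(cc), dim(cc)) - 1L
  n <- dim(a)
  s <- ifelse(p > n / 2, p - n, p)
  # refine on a fine grid around the integer peak via direct DFT
  if (upsample > 1) {
    gr <- seq(-refine_halfwidth, refine_halfwidth, by = 1 / upsample)
    f1 <- fftfreq(n[1]); f2 <- fftfreq(n[2])
    E1 <- exp(2i * pi * outer(s[1] + gr, f1))          # (ng x n1)
    E2 <- exp(2i * pi * outer(f2, s[2] + gr))          # (n2 x ng)
    C <- Re(E1 %*% Q %*% E2) / length(a)
    pk <- arrayInd(which.max(C), dim(C))
    s <- c(s[1] + gr[pk[1]], s[2] + gr[pk[2]])
    peak <- max(C)
  } else {
    peak <- max(cc)
  }
  attr(s, "correlation") <- peak / (na * nb)
  s
}

# separable 3D Gaussian smoothing (reflected borders); sigma in voxels
gaussian_smooth_3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-hw:hw, sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  pad_idx <- function(n) c(rev(seq_len(hw)), seq_len(n),
                           n + 1 - seq_len(hw))
  for (ax in 1:3) {
    idx <- pad_idx(d[ax])
    xp <- switch(ax, x[idx, , ], x[, idx, ], x[, , idx])
    out <- array(0, dim = d)
    for (j in seq_along(k)) {
      sl <- switch(ax,
                   xp[j:(j + d[1] - 1), , , drop = FALSE],
                   xp[, j:(j + d[2] - 1), , drop = FALSE],
                   xp[, , j:(j + d[3] - 1), drop = FALSE])
      out <- out + k[j] * sl
    }
    x <- out
  }
  x
}

# trilinear sampling of a 3D array at fractional 1-based coordinates
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  p0 <- pmin(pmax(floor(pts), 1), matrix(rep(d - 1, each = nrow(pts)),
                                         ncol = 3, byrow = FALSE))
  f <- pts - p0
  f <- pmin(pmax(f, 0), 1)
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(p0[, 1] + dx, p0[, 2] + dy, p0[, 3] + dz)
    acc <- acc + w * vol[idx]
  }
  acc
}

# bilinear zoom about the image centre: out(x) = img(c + (x - c)/factor)
rescale_image <- function(img, factor, fill = 1) {
  n <- dim(img)
  c1 <- (n[1] + 1) / 2; c2 <- (n[2] + 1) / 2
  xs <- c1 + (seq_len(n[1]) - c1) / factor
  ys <- c2 + (seq_len(n[2]) - c2) / factor
  i0 <- pmin(pmax(floor(xs), 1), n[1] - 1); fx <- pmin(pmax(xs - i0, 0), 1)
  j0 <- pmin(pmax(floor(ys), 1), n[2] - 1); fy <- pmin(pmax(ys - j0, 0), 1)
  v00 <- img[i0, j0]; v10 <- img[i0 + 1, j0]
  v01 <- img[i0, j0 + 1]; v11 <- img[i0 + 1, j0 + 1]
  wx <- matrix(fx, n[1], n[2]); wy <- matrix(fy, n[1], n[2], byrow = TRUE)
  out <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
  oob <- (xs < 1 | xs > n[1])
  oob2 <- (ys < 1 | ys > n[2])
  out[oob, ] <- fill
  out[, oob2] <- fill
  out
}
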