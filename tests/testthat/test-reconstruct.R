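# Rotation-centre finding, jitter alignment, filtered backprojection.

# noise-free true-phase projections of a small pit phantom
tiny_projection_set <- function(grid = 64, n_angles = 60, spec_scale = 0.6) {
  s <- tiny_pit_spec(spec_scale)
  v <- build_pit_pair_phantom(s, grid_shape = rep(grid, 3), pitch_nm = 26)
  dv <- material_volume(v, "delta")
  lam <- wavelength_from_energy(11)
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  ph <- array(0, dim = c(grid, grid, n_angles))
  for (a in seq_len(n_angles)) {
    pd <- holoxylem:::cpp_project_volume(dv, grid, grid, grid,
                                         angles[a] * pi / 180) * 26
    ph[, , a] <- -(2 * pi / lam) * pd
  }
  structure(list(phases = ph, angles_deg = angles, pitch_nm = 26,
                 provenance = list(method = "truth"), phantom = v),
            class = "phase_projection_set")
}

test_that("rotation centre is found from an opposing pair", {
  pps <- tiny_projection_set(n_angles = 2)
  p0 <- pps$phases[, , 1]
  # a true 180-degree view is the mirrored 0-degree view
  p180 <- p0[rev(seq_len(nrow(p0))), ]
  c0 <- find_rotation_center(p0, p180)
  expect_lt(abs(as.numeric(c0) - (64 + 1) / 2), 0.25)
  # injected sinogram shift moves the centre with the object
  p0s <- holoxylem:::fourier_shift(p0, c(3.7, 0))
  p180s <- holoxylem:::fourier_shift(p180, c(3.7, 0))
  cs <- find_rotation_center(p0s, p180s)
  expect_lt(abs(as.numeric(cs) - ((64 + 1) / 2 + 3.7)), 0.25)
  expect_error(find_rotation_center(matrix(0, 32, 32), matrix(0, 32, 32)),
               "cannot-align")
})

test_that("reprojection alignment recovers injected per-angle jitter", {
  pps <- tiny_projection_set(grid = 64, n_angles = 90)
  al0 <- align_projections(pps)
  expect_lt(max(abs(al0$shifts)), 0.1)        # jitter-free data
  set.seed(17)
  jit <- cbind(rnorm(90, 0, 2), rnorm(90, 0, 2))
  jpps <- pps
  for (a in 1:90) {
    jpps$phases[, , a] <- holoxylem:::fourier_shift(pps$phases[, , a],
                                                    jit[a, ])
  }
  al <- align_projections(jpps)
  err <- al$shifts - jit
  frac <- mean(sqrt(rowSums(err^2)) <= 0.5)
  expect_gte(frac, 0.95)
  # idempotence: a second pass finds almost nothing left
  al2 <- align_projections(al$projections)
  expect_lt(stats::quantile(abs(al2$shifts), 0.95), 0.25)
})

test_that("FBP reproduces an analytic disc at instrument sampling", {
  n <- 128; r <- 40; f0 <- 3
  angles <- seq(0, 179.8, by = 0.2)            # 900 views
  proj <- disc_sinogram(n, r, f0, length(angles))
  tomo <- fbp_reconstruct(proj, angles_deg = angles, filter = "ramlak",
                          pitch_nm = 26)
  sl <- tomo$values[, , 1]
  c0 <- (n + 1) / 2
  rr <- sqrt(outer((1:n - c0)^2, (1:n - c0)^2, "+"))
  truth <- f0 * (rr < r)
  sel <- abs(rr - r) > 2                        # off the rasterized rim
  expect_lt(sqrt(mean((sl[sel] - truth[sel])^2)) / f0, 0.02)
  expect_rel_equal(mean(sl[rr < r - 3]), f0, 0.05)
  # linearity
  tomo3 <- fbp_reconstruct(3 * proj, angles_deg = angles,
                           filter = "ramlak", pitch_nm = 26)
  expect_equal(tomo3$values, 3 * tomo$values, tolerance = 1e-10)
  # all-zero projections reconstruct to zero
  z <- fbp_reconstruct(0 * proj, angles_deg = angles, pitch_nm = 26)
  expect_true(all(z$values == 0))
  expect_error(fbp_reconstruct(proj[, , 1:2], angles_deg = c(0, 90)),
               "invalid-input")
})

test_that("reconstructed contrast preserves the material ordering", {
  pps <- tiny_projection_set(grid = 64, n_angles = 90)
  v <- pps$phantom
  vg <- add_gallium_layer(v, 52)
  # rebuild projections with the gallium layer present
  dv <- material_volume(vg, "delta")
  lam <- wavelength_from_energy(11)
  for (a in seq_along(pps$angles_deg)) {
    pd <- holoxylem:::cpp_project_volume(dv, 64, 64, 64,
                                         pps$angles_deg[a] * pi / 180) * 26
    pps$phases[, , a] <- -(2 * pi / lam) * pd
  }
  tomo <- fbp_reconstruct(pps, wavelength_nm = lam, output = "delta")
  m_air <- mean(tomo$values[vg$labels == 0L])
  m_wall <- mean(tomo$values[vg$labels == 1L])
  m_ga <- mean(tomo$values[vg$labels == 3L])
  expect_gt(m_ga, m_wall)
  expect_gt(m_wall, m_air)
  # delta scaling: wall voxels reconstruct near the true decrement
  expect_rel_equal(m_wall, vg$materials[["1"]]$delta, 0.15)
})

test_that("angle decimation degrades reconstructions monotonically", {
  # halving the instrument's 900-view schedule degrades but does not
  # destroy: the disc-oracle error grows monotonically through
  # 900 -> 450 -> 225 -> 100 views
  n <- 128; r <- 40; f0 <- 3
  rr <- sqrt(outer((1:n - 64.5)^2, (1:n - 64.5)^2, "+"))
  truth <- f0 * (rr < r)
  sel <- abs(rr - r) > 2
  rmse <- vapply(c(900, 450, 225, 100), function(na) {
    ang <- seq(0, 180, length.out = na + 1)[seq_len(na)]
    proj <- disc_sinogram(n, r, f0, na)
    tomo <- fbp_reconstruct(proj, angles_deg = ang, filter = "ramlak",
                            pitch_nm = 26)
    sqrt(mean((tomo$values[, , 1][sel] - truth[sel])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
  expect_lt(rmse[4], 0.02 * f0)   # degraded, not destroyed
})
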