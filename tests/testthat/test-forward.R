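# Wave-optical forward model: projection, exit wave, propagation,
# hologram simulation.

test_that("projected thickness reproduces analytic box projections", {
  # 20 x 40 x 12 voxel box of wall material in a 64^3 grid
  lab <- array(0L, dim = c(64, 64, 64))
  lab[23:42, 13:52, 27:38] <- 1L
  v <- as_phantom_volume(lab, 26)
  t0 <- project_thickness(v, 0)      # beam along y
  # footprint interior: thickness = 40 voxels * pitch
  expect_equal(t0[["1"]][30, 30], 40 * 26, tolerance = 1e-6)
  expect_equal(t0[["1"]][10, 30], 0)
  t90 <- project_thickness(v, 90)    # beam along x: footprint swaps axes
  expect_equal(t90[["1"]][33, 30], 20 * 26, tolerance = 26 * 1.5)
  # u extent now reflects the y-extent of the box
  occ0 <- range(which(rowSums(t0[["1"]]) > 0))
  occ90 <- range(which(rowSums(t90[["1"]]) > 0))
  expect_lt(abs(diff(occ0) - 20), 3)
  expect_lt(abs(diff(occ90) - 40), 3)
  # conservation: total path never exceeds the grid depth
  tot <- Reduce(`+`, project_thickness(v, 33.3))
  expect_true(all(tot <= 64 * 26 + 1e-6))
  expect_error(project_thickness(v, 180), "invalid-argument")
})

test_that("exit wave implements the projection approximation", {
  z <- matrix(0, 8, 8)
  mats <- list("1" = material("cellulose", 2.7e-6, 0))
  expect_equal(exit_wave(list("1" = z), mats, 0.112713),
               matrix(1 + 0i, 8, 8))
  tmap <- z; tmap[4, 4] <- 3617
  u <- exit_wave(list("1" = tmap), mats, 0.112713)
  expect_equal(Arg(u[4, 4]), -0.5444, tolerance = 1e-3)
  expect_equal(Mod(u), matrix(1, 8, 8))   # beta = 0: pure phase
  expect_true(all(Arg(u) <= 0))
  expect_error(exit_wave(list("1" = z, "2" = matrix(0, 4, 4)),
                         mats, 0.1127), "invalid-argument")
})

test_that("Fresnel propagator is unitary and matches Gaussian beam optics", {
  lam <- 0.112713; px <- 26
  g <- gauss_field(128, 8)
  expect_identical(fresnel_propagate(g, lam, 0, px), g)
  # inverse: forward then backward propagation restores the field
  zR_mm <- pi * (8 * px)^2 / lam * 1e-6
  gp <- fresnel_propagate(g, lam, zR_mm, px, apodize = FALSE)
  back <- fresnel_propagate(gp, lam, -zR_mm, px, apodize = FALSE)
  expect_lt(sqrt(mean(Mod(back - g)^2)), 1e-8)
  # energy conservation for a compact beam
  expect_equal(sum(Mod(gp)^2) / sum(Mod(g)^2), 1, tolerance = 1e-6)
  # waist follows w(z) = w0 sqrt(1 + (z/zR)^2); measure via 2nd moments
  g2 <- fresnel_propagate(g, lam, 2 * zR_mm, px, apodize = FALSE)
  I <- Mod(g2)^2
  xg <- outer(seq_len(128), rep(1, 128))
  mu <- sum(I * xg) / sum(I)
  w_est <- sqrt(4 * sum(I * (xg - mu)^2) / sum(I))
  expect_rel_equal(w_est, 8 * sqrt(1 + 4), 0.005)
  expect_error(fresnel_propagate(g, -1, 10, px), "invalid-argument")
  expect_error(fresnel_propagate(g, lam, 10, 0), "invalid-argument")
})

test_that("empty phantom with unit flats gives unit holograms", {
  lab <- array(0L, dim = c(32, 32, 32))
  v <- as_phantom_volume(lab, 26)
  g <- near_geometry(32, n_projections = 3L)
  st <- simulate_hologram_stack(v, g)
  expect_equal(max(abs(st$intensities - 1)), 0, tolerance = 1e-10)
})

test_that("weak-object hologram spectra follow the CTF closed form", {
  v <- weak_blob_phantom(128)
  g <- near_geometry(128, n_projections = 3L)
  der <- geometry_derived(g)
  lam <- attr(der, "wavelength_nm")
  st <- simulate_hologram_stack(v, g, angles_deg = 0)
  tm <- project_thickness(v, 0)
  phi <- -(2 * pi / lam) * v$materials[["1"]]$delta * tm[["1"]]
  expect_lt(max(abs(phi)), 0.12)            # weak-object regime
  nu2 <- outer(holoxylem:::fftfreq(128)^2, holoxylem:::fftfreq(128)^2, "+")
  for (k in 1:3) {
    I <- st$intensities[, , 1, k]
    lhs <- stats::fft(I - 1)
    rhs <- 2 * sin(pi * nu2 / der$fresnel_number[k]) * stats::fft(phi)
    relrms <- sqrt(sum(Mod(lhs - rhs)^2) / sum(Mod(rhs)^2))
    expect_lt(relrms, 0.03)
  }
})

test_that("hologram stacks are seeded-deterministic with distinct fringes", {
  v <- weak_blob_phantom(64, delta = 4e-7)
  g <- near_geometry(64, n_projections = 4L)
  s1 <- simulate_hologram_stack(v, g, photons_per_pixel = 2000, seed = 5)
  s2 <- simulate_hologram_stack(v, g, photons_per_pixel = 2000, seed = 5)
  expect_identical(s1$intensities, s2$intensities)
  s3 <- simulate_hologram_stack(v, g, photons_per_pixel = 2000, seed = 6)
  expect_false(identical(s1$intensities, s3$intensities))
  # the three defocus distances give three distinct fringe systems
  clean <- simulate_hologram_stack(v, g)
  for (a in 1:2) for (k1 in 1:2) for (k2 in (k1 + 1):3) {
    expect_gt(sum(abs(clean$intensities[, , a, k1] -
                        clean$intensities[, , a, k2])), 1e-3)
  }
  # energy conservation: pure-phase no-noise hologram has unit mean
  expect_equal(mean(clean$intensities[, , 1, 1]), 1, tolerance = 1e-4)
  # pitch mismatch is rejected
  v2 <- v; v2$pitch_nm <- 13
  expect_error(simulate_hologram_stack(v2, g), "invalid-geometry")
})
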