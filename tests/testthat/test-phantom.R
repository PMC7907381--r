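# Synthetic wood-anatomy phantoms and illumination flats.

test_that("pit phantom ground truth echoes the construction spec", {
  v <- tiny_pit_phantom()
  s <- tiny_pit_spec()
  expect_equal(v$ground_truth$chamber_diameter_nm, s$chamber_diameter_nm)
  expect_equal(v$ground_truth$membrane_thickness_nm,
               s$membrane_thickness_nm)
  expect_equal(v$ground_truth$canal_width_nm, s$canal_slit_width_nm)
  expect_true(any(v$labels == 2L))          # membrane present
  lev <- sort(unique(as.integer(v$labels)))
  expect_true(all(as.character(setdiff(lev, 0L)) %in% names(v$materials)))
  # deterministic construction
  expect_identical(v$labels, tiny_pit_phantom()$labels)
})

test_that("pit spec validation names the offending dimension", {
  expect_error(pit_spec(membrane_thickness_nm = 5000),
               "membrane_thickness_nm")
  expect_error(pit_spec(canal_slit_minor_nm = 2000), "canal_slit_minor_nm")
  expect_error(pit_spec(chamber_diameter_nm = -1), "chamber_diameter_nm")
  expect_error(
    build_pit_pair_phantom(pit_spec(), grid_shape = c(64, 64, 64)),
    "invalid-spec")
})

test_that("membrane filling the whole chamber leaves no chamber void", {
  s <- tiny_pit_spec()
  s2 <- pit_spec(chamber_diameter_nm = s$chamber_diameter_nm,
                 membrane_thickness_nm = s$chamber_depth_nm - 2,
                 canal_slit_width_nm = s$canal_slit_width_nm,
                 canal_slit_minor_nm = s$canal_slit_minor_nm,
                 chamber_depth_nm = s$chamber_depth_nm,
                 wall_thickness_nm = s$wall_thickness_nm)
  v <- build_pit_pair_phantom(s2, grid_shape = c(96, 96, 96))
  # chamber region between membrane face and lens apex holds no void
  # voxels inside the chamber radius
  co <- (1:96 - 1 - 95 / 2) * 26
  cap_zone <- abs(co) > s2$membrane_thickness_nm / 2 &
    abs(co) <= s2$chamber_depth_nm / 2
  r2 <- outer(co^2, co^2, "+")   # (y, z) radial distance from canal axis
  inside <- r2 <= (s2$chamber_diameter_nm / 2)^2
  void_in_chamber <- sum(vapply(which(cap_zone), function(i) {
    sum(v$labels[i, , ][inside] == 0L)
  }, numeric(1)))
  expect_equal(void_in_chamber, 0)
  # only the canals contribute void volume in this degenerate spec
  canal_len <- s2$wall_thickness_nm - s2$chamber_depth_nm / 2
  v_canals <- 2 * ((s2$canal_slit_width_nm - s2$canal_slit_minor_nm) *
                     s2$canal_slit_minor_nm +
                     pi * (s2$canal_slit_minor_nm / 2)^2) * canal_len * 1e-9
  # the 1-nm residual caps add under 5%
  expect_equal(v$ground_truth$void_volume_um3, v_canals, tolerance = 0.05)
})

test_that("rasterized pit void volume matches the analytic CSG volume", {
  # count the pit void (chamber + canals) geometrically: void voxels in
  # the wall slab within the chamber radius of the canal axis
  pit_void_count <- function(vol, spec) {
    n <- dim(vol$labels)
    p <- vol$pitch_nm
    xs <- (seq_len(n[1]) - 1 - (n[1] - 1) / 2) * p
    r2 <- outer(((seq_len(n[2]) - 1 - (n[2] - 1) / 2) * p)^2,
                ((seq_len(n[3]) - 1 - (n[3] - 1) / 2) * p)^2, "+")
    ok <- r2 <= (spec$chamber_diameter_nm / 2)^2
    sum(vapply(which(abs(xs) <= spec$wall_thickness_nm), function(i) {
      sum(vol$labels[i, , ][ok] == 0L)
    }, numeric(1)))
  }
  s <- tiny_pit_spec()
  v <- tiny_pit_phantom()
  raster_um3 <- pit_void_count(v, s) * (26e-3)^3
  expect_rel_equal(raster_um3, v$ground_truth$void_volume_um3, 0.03)
  # oracle: the same CSG rasterized on a 2x finer grid converges further
  vf <- build_pit_pair_phantom(s, grid_shape = rep(192, 3), pitch_nm = 13)
  fine_um3 <- pit_void_count(vf, s) * (13e-3)^3
  expect_rel_equal(fine_um3, v$ground_truth$void_volume_um3, 0.015)
})

test_that("tracheid phantom rasterizes the analytic wall volume", {
  v <- build_tracheid_phantom(grid_shape = c(192, 192, 32),
                              pillar_radius_nm = Inf,
                              pillar_height_nm = Inf)
  expect_equal(v$ground_truth$wall_thickness_um, 3.617)
  count <- sum(v$labels == 1L)
  analytic <- v$ground_truth$wall_volume_nm3_unclipped / 26^3
  # one voxel layer per slab face in-plane
  slack <- 4 * 192 * 32
  expect_lt(abs(count - analytic), slack)
  # zero wall thickness -> all air
  v0 <- build_tracheid_phantom(wall_thickness_nm = 0,
                               grid_shape = c(64, 64, 16))
  expect_true(all(v0$labels == 0L))
})

test_that("gallium coating equals the iterated boundary peel", {
  v <- build_tracheid_phantom(grid_shape = c(192, 192, 24),
                              pillar_radius_nm = Inf,
                              pillar_height_nm = Inf)
  vg <- add_gallium_layer(v, 78)           # 3 voxels
  # oracle: 3-fold 6-neighbour erosion of the wall, computed independently
  wall <- v$labels == 1L
  erode6 <- function(m) {
    d <- dim(m)
    out <- m
    out[-1, , ] <- out[-1, , ] & m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
    out[, -1, ] <- out[, -1, ] & m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
    out[, , -1] <- out[, , -1] & m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
    out
  }
  core <- erode6(erode6(erode6(wall)))
  expect_identical(vg$labels == 3L, wall & !core)
  # gallium is optically denser than the wall
  expect_gt(vg$materials[["3"]]$delta, vg$materials[["1"]]$delta)
  # zero thickness is a no-op; too-thick coating is rejected
  expect_identical(add_gallium_layer(v, 0)$labels, v$labels)
  expect_error(add_gallium_layer(v, 5000), "invalid-spec")
})

test_that("illumination flats are mean-one, positive and seeded", {
  f0 <- make_illumination(c(32, 48), ripple_amplitude = 0, n_stripes = 0)
  expect_equal(f0, matrix(1, 32, 48))
  for (s in c(1, 7, 99)) {
    f <- make_illumination(c(64, 64), seed = s)
    expect_equal(mean(f), 1, tolerance = 1e-6)
    expect_true(all(f > 0))
    expect_identical(f, make_illumination(c(64, 64), seed = s))
  }
  expect_error(make_illumination(ripple_amplitude = 1), "invalid-argument")
  expect_error(make_illumination(ripple_amplitude = 0.9,
                                 stripe_amplitude = 0.4),
               "invalid-argument")
})
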