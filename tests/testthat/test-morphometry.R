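# Region growing, gallium exclusion, void volume, wall thickness and pit
# measurements.

test_that("region growing floods by grayscale similarity and adjacency", {
  u <- array(5, dim = c(12, 12, 12))
  g <- region_grow(u, c(6, 6, 6), tolerance = 0.1)
  expect_true(all(g$mask))                       # uniform: full volume
  # two-level step with tolerance below the step: only the seed plateau
  step <- array(0, dim = c(20, 10, 10))
  step[11:20, , ] <- 10
  g1 <- region_grow(step, c(3, 5, 5), tolerance = 4)
  expect_identical(g1$mask, step == 0)
  g2 <- region_grow(step, c(15, 5, 5), tolerance = 4)
  expect_identical(g2$mask, step == 10)
  expect_error(region_grow(step, c(25, 5, 5), 1), "invalid-seed")
  expect_error(region_grow(step, c(3, 5, 5), -1), "invalid-argument")
})

test_that("region growing equals global thresholding on a clean sphere", {
  n <- 48
  c0 <- (n + 1) / 2
  vol <- array(0, dim = rep(n, 3))
  for (k in 1:n) {
    vol[, , k] <- (outer((1:n - c0)^2, (1:n - c0)^2, "+") +
                     (k - c0)^2 <= 15^2) * 2.5
  }
  for (conn in c(6, 26)) {
    g <- region_grow(vol, rep(round(c0), 3), tolerance = 1,
                     connectivity = conn)
    expect_identical(g$mask, vol >= 1.5)        # voxel-for-voxel
  }
  # invariance to relabeling values outside [seed +/- tol]
  vol2 <- vol; vol2[vol == 0] <- -7
  g2 <- region_grow(vol2, rep(round(c0), 3), tolerance = 1)
  expect_identical(g2$mask, vol >= 1.5)
})

test_that("gallium exclusion removes the coating, keeps the wall", {
  v <- tiny_pit_phantom()
  vg <- add_gallium_layer(v, 78)
  dvol <- material_volume(vg, "delta")
  wall_d <- vg$materials[["1"]]$delta
  ga_d <- vg$materials[["3"]]$delta
  mask <- array(vg$labels %in% c(1L, 3L), dim(vg$labels)) # segmented solid
  thr <- (wall_d + ga_d) / 2                     # midpoint threshold
  out <- exclude_gallium(dvol, mask, thr)
  ga_removed <- sum((vg$labels == 3L) & !out) / sum(vg$labels == 3L)
  wall_kept <- sum((vg$labels == 1L) & out) / sum(vg$labels == 1L)
  expect_gte(ga_removed, 0.95)
  expect_gte(wall_kept, 0.98)
  # degenerate thresholds
  expect_identical(exclude_gallium(dvol, mask, max(dvol) + 1), mask)
  expect_true(!any(exclude_gallium(dvol, mask, min(dvol) - 1)))
})

test_that("void volume is exact voxel-count arithmetic", {
  expect_error(void_volume(array(TRUE, c(2, 2, 2)), -1), "invalid-argument")
  vv <- void_volume(array(TRUE, c(1, 1, 1)), 26)
  expect_equal(vv$volume_um3, 1.7576e-5, tolerance = 1e-6)
  expect_equal(void_volume(array(FALSE, c(3, 3, 3)), 26)$volume_um3, 0)
  # additivity over disjoint masks
  m1 <- array(FALSE, c(10, 10, 10)); m1[1:3, , ] <- TRUE
  m2 <- array(FALSE, c(10, 10, 10)); m2[7:9, , ] <- TRUE
  expect_equal(void_volume(m1 | m2, 26)$volume_um3,
               void_volume(m1, 26)$volume_um3 +
                 void_volume(m2, 26)$volume_um3)
})

test_that("wall thickness comes from 50%-contrast edge crossings", {
  # ideal binary slab of 3617/26 = 139.1 voxel widths
  n <- 200
  vol <- array(0, dim = c(n, 24, 24))
  xs <- (1:n - (n + 1) / 2) * 26
  vol[abs(xs) <= 3617 / 2, , ] <- 2.7e-6
  probes <- lapply(c(8, 12, 16), function(y)
    list(start = c(5, y, 12), direction = c(1, 0, 0), length = 190))
  wt <- wall_thickness(vol, probes, pitch_nm = 26)
  expect_lt(abs(as.numeric(wt) - 3.617), 0.026)
  # a blurred (erf) edge keeps the midpoint crossing in place
  prof <- as.numeric(stats::filter(vol[, 12, 12],
                                   dnorm(-6:6, sd = 2) / sum(dnorm(-6:6, sd = 2)),
                                   sides = 2))
  prof[is.na(prof)] <- 0
  volb <- array(rep(prof, 24 * 24), dim = c(n, 24, 24))
  wtb <- wall_thickness(volb, probes, pitch_nm = 26)
  expect_lt(abs(as.numeric(wtb) - 3.617), 0.026)
  # zero contrast fails the measurement
  expect_error(wall_thickness(array(1, c(20, 20, 20)),
                              list(list(start = c(2, 10, 10),
                                        direction = c(1, 0, 0),
                                        length = 18)), pitch_nm = 26),
               "measurement-failed")
  # probes crossing two walls are excluded, the rest still measure
  two <- array(0, dim = c(n, 24, 24))
  two[abs(xs) <= 500 | abs(xs - 2000) <= 500, , ] <- 2.7e-6
  probes2 <- c(probes, list(list(start = c(5, 20, 20),
                                 direction = c(1, 0, 0), length = 190)))
  expect_error(wall_thickness(two, probes2, pitch_nm = 26),
               "measurement-failed")
})

test_that("ground-truth pit labels reproduce the printed dimensions", {
  v <- build_pit_pair_phantom()      # reference 256^3 phantom
  pm <- pit_metrics(v$labels == 0L, membrane_axis = 1, pitch_nm = 26,
                    centre = c(128, 128))
  # rasterization plus the end-voxel extent convention admits up to
  # one and a half voxels
  expect_lt(abs(pm$chamber_diameter_nm - 4230), 40)
  expect_lt(abs(pm$membrane_thickness_nm - 428), 26)
  expect_lt(abs(pm$canal_width_nm - 1053), 40)
})

test_that("pit metrics scale with the construction dimensions", {
  v1 <- tiny_pit_phantom()
  p1 <- pit_metrics(v1$labels == 0L, 1, 26, centre = c(48, 48))
  v2 <- build_pit_pair_phantom(tiny_pit_spec(2), grid_shape = rep(176, 3))
  p2 <- pit_metrics(v2$labels == 0L, 1, 26, centre = c(88, 88))
  for (f in c("chamber_diameter_nm", "membrane_thickness_nm",
              "canal_width_nm")) {
    expect_lt(abs(p2[[f]] - 2 * p1[[f]]), 2 * 26 + 1e-9)
  }
})

test_that("pit metrics reject masks without the pit topology", {
  n <- 48
  c0 <- (n + 1) / 2
  ball <- array(FALSE, dim = rep(n, 3))
  for (k in 1:n) {
    ball[, , k] <- outer((1:n - c0)^2, (1:n - c0)^2, "+") +
      (k - c0)^2 <= 12^2
  }
  expect_error(pit_metrics(ball, 1, 26), "topology-error")
  expect_error(pit_metrics(array(FALSE, rep(8, 3)), 1, 26),
               "topology-error")
})

test_that("morphometry report collects the five measurements", {
  rep <- morphometry_report(
    pit = list(chamber_diameter_nm = 4230, membrane_thickness_nm = 428,
               canal_width_nm = 1053),
    wall_um = 3.617,
    void = list(voxel_count = 1220270L, volume_um3 = 21.45))
  expect_s3_class(rep, "morphometry_report")
  expect_equal(rep$canal_width_um, 1.053)
  expect_match(attr(rep, "note"), "gallium")
  stem <- tempfile()
  write_morphometry_report(rep, stem)
  back <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(back$voxel_count, 1220270L)
})
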