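# Multi-distance phase retrieval (CTF + iterative projections) and
# destriping.

make_weak_case <- function(n = 128, delta = 8e-7, seed = NULL,
                           photons = NULL) {
  v <- weak_blob_phantom(n, delta)
  g <- near_geometry(n, n_projections = 2L)
  der <- geometry_derived(g)
  lam <- attr(der, "wavelength_nm")
  st <- simulate_hologram_stack(v, g, angles_deg = 0, seed = seed,
                                photons_per_pixel = photons)
  tm <- project_thickness(v, 0)
  phi <- -(2 * pi / lam) * v$materials[["1"]]$delta * tm[["1"]]
  list(holos = lapply(1:3, function(k) st$intensities[, , 1, k]),
       F_list = der$fresnel_number, phi = phi)
}

test_that("CTF inversion recovers a weak pure-phase object", {
  expect_equal(ctf_retrieve(list(matrix(1, 64, 64)), 1e-3),
               matrix(0, 64, 64), tolerance = 1e-10)
  cs <- make_weak_case()
  rng <- diff(range(cs$phi))
  phih <- ctf_retrieve(cs$holos, cs$F_list, alpha = 1e-4)
  expect_lt(sqrt(mean((phih - cs$phi)^2)) / rng, 0.05)
  # three distances beat the best single distance
  rmse3 <- sqrt(mean((phih - cs$phi)^2))
  rmse1 <- vapply(1:3, function(k) {
    sqrt(mean((ctf_retrieve(cs$holos[k], cs$F_list[k],
                            alpha = 1e-4) - cs$phi)^2))
  }, numeric(1))
  expect_lt(rmse3, min(rmse1))
  expect_warning(ctf_retrieve(cs$holos[1], cs$F_list[1], alpha = 0),
                 "ill-posed")
})

test_that("retrieval is equivariant under whole-pixel hologram shifts", {
  cs <- make_weak_case()
  sh <- function(m, s) {
    idx <- ((seq_len(nrow(m)) - 1 - s) %% nrow(m)) + 1
    m[idx, ]
  }
  p0 <- ctf_retrieve(cs$holos, cs$F_list, offset = "none", pad = FALSE)
  p5 <- ctf_retrieve(lapply(cs$holos, sh, s = 5), cs$F_list,
                     offset = "none", pad = FALSE)
  expect_equal(sh(p0, 5), p5, tolerance = 1e-6)
})

test_that("iterative retrieval keeps a noise-free truth fixed", {
  cs <- make_weak_case(n = 64, delta = 4e-6)
  r <- iterative_retrieve(cs$holos, cs$F_list, phi_init = cs$phi,
                          n_iter = 5, tol = 0, scheme = "aap")
  expect_lt(tail(r$misfit_trace, 1), r$misfit_trace[1] + 1e-12)
  expect_lt(sqrt(mean((r$phase - cs$phi)^2)), 1e-6)
  # negativity: the phase-range constraint is enforced exactly
  expect_lte(max(r$phase), 0)
})

test_that("iterative refinement improves on CTF for a strong object", {
  # strong-phase blob: |phi|max ~ 1 rad breaks the weak-object model
  cs <- make_weak_case(n = 128, delta = 1.2e-5)
  expect_gt(max(abs(cs$phi)), 0.8)
  rng <- diff(range(cs$phi))
  phi0 <- pmin(ctf_retrieve(cs$holos, cs$F_list), 0)
  e0 <- sqrt(mean((phi0 - cs$phi)^2))
  for (scheme in c("aap", "dm")) {
    r <- iterative_retrieve(cs$holos, cs$F_list, phi_init = phi0,
                            n_iter = 15, tol = 0, scheme = scheme)
    expect_lt(sqrt(mean((r$phase - cs$phi)^2)), e0)
  }
})

test_that("iterative misfit decreases from init on seeded noisy data", {
  for (seed in 1:10) {
    cs <- make_weak_case(n = 64, delta = 4e-6, seed = seed,
                         photons = 5000)
    phi0 <- pmin(ctf_retrieve(cs$holos, cs$F_list), 0)
    r <- iterative_retrieve(cs$holos, cs$F_list, phi_init = phi0,
                            n_iter = 8, tol = 0)
    expect_lt(tail(r$misfit_trace, 1), r$misfit_trace[1])
  }
})

test_that("iterative retrieval validates its inputs", {
  cs <- make_weak_case(n = 32, delta = 4e-6)
  expect_error(iterative_retrieve(cs$holos, cs$F_list,
                                  constraints = list()),
               "under-constrained")
  bad <- cs$holos; bad[[2]][5, 5] <- NaN
  expect_error(iterative_retrieve(bad, cs$F_list), "invalid-input")
  expect_error(iterative_retrieve(cs$holos, cs$F_list,
                                  phi_init = matrix(0, 8, 8)),
               "invalid-argument")
})

test_that("destriping removes horizontal stripes, preserves structure", {
  set.seed(3)
  n <- 256
  clean <- matrix(0, n, n)
  for (i in 1:10) {
    clean <- clean - runif(1, 0.3, 1) *
      outer(exp(-((1:n) - runif(1, 60, 200))^2 / 40),
            exp(-((1:n) - runif(1, 60, 200))^2 / 40))
  }
  # near-identity on stripe-free input
  out0 <- destripe(clean)
  expect_lt(sqrt(mean((out0 - clean)^2)) / sd(clean), 0.01)
  # injected ripple at 10% of the range: stripe-band energy drops >= 90%
  ripple <- 0.1 * diff(range(clean)) *
    matrix(sin(2 * pi * (1:n) / 32), n, n, byrow = TRUE)
  noisy <- clean + ripple
  out <- destripe(noisy)
  e_before <- stripe_band_energy(noisy - clean)
  e_after <- stripe_band_energy(out - clean)
  expect_lt(e_after, 0.1 * e_before)
  # and the frame gets closer to the clean reference
  expect_lt(sqrt(mean((out - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # phase-projection-set method touches every frame
  pps <- structure(list(phases = array(noisy, dim = c(n, n, 2)),
                        angles_deg = c(0, 90), pitch_nm = 26,
                        provenance = list()),
                   class = "phase_projection_set")
  dp <- destripe(pps)
  expect_equal(dp$phases[, , 1], out, tolerance = 1e-12)
  expect_true(dp$provenance$destriped)
})
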