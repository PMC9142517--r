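# Transport in the water sphere: source placement, electron/photon
# transport, tallies and sweeps. Simulation sizes are kept small; the
# acceptance suite runs the full-size checks.

small_cfg <- function(seed, n = 5000, ...) {
  transport_config(n_decays = n, seed = seed, ...)
}

test_that("source positions are uniform in the sphere", {
  w <- sphere_world(10)
  set.seed(201)
  p <- place_source(w, 1e5)
  r <- sqrt(rowSums(p^2))
  expect_true(all(r <= w$radius_cm))
  ks <- suppressWarnings(ks.test((r / w$radius_cm)^3, "punif"))
  expect_gt(ks$p.value, 0.01)
  # E|r| = 3R/4 for density prop. to r^2
  expect_lt(abs(mean(r) - 0.75 * w$radius_cm),
            3 * sd(r) / sqrt(length(r)))
})

test_that("sphere geometry is consistent", {
  w <- sphere_world(1.4e-5)
  expect_equal(4 / 3 * pi * w$radius_cm^3, 1.4e-5 * 1e-3, tolerance = 1e-9)
  expect_equal(w$radius_cm, 15e-4, tolerance = 0.01)   # 15 um cell
  expect_error(sphere_world(-1))
})

test_that("electron transport conserves energy exactly", {
  w <- sphere_world(1e-4)
  set.seed(202)
  pos <- place_source(w, 2000)
  ev <- sample_decay(default_scheme, pos, 2000)
  el <- ev$particles[ev$particles$species %in% c("electron", "positron"), ]
  tr <- transport_electrons(el, w, transport_config())
  expect_equal(tr$inside + tr$outside, el$energy_MeV, tolerance = 1e-9)
  expect_true(all(tr$inside >= 0 & tr$outside >= -1e-12))
})

test_that("a 2 keV electron is fully contained in a 15 um sphere", {
  w <- sphere_world(1.4e-5)
  p <- data.frame(event = 1L, energy_MeV = 2e-3, x = 0, y = 0, z = 0,
                  ux = 0, uy = 0, uz = 1)
  tr <- transport_electrons(p, w, transport_config())
  expect_equal(tr$inside, 2e-3, tolerance = 1e-9)
})

test_that("deposition along a truncated track matches the 1-D CSDA oracle", {
  # 0.573 MeV electron from the center of a 0.5 mm sphere: the energy left
  # inside equals the loss over the first 0.5 mm of its ~2.1 mm track
  R <- 0.05  # cm
  w <- sphere_world(4 / 3 * pi * R^3 * 1e3)
  p <- data.frame(event = 1L, energy_MeV = 0.573, x = 0, y = 0, z = 0,
                  ux = 0, uy = 0, uz = 1)
  tr <- transport_electrons(p, w, transport_config())
  E_exit <- oracle_energy_after_path(0.573, R)
  expect_equal(tr$inside, 0.573 - E_exit, tolerance = 0.02)
})

test_that("electron transport rejects energies above the table", {
  w <- sphere_world(1)
  p <- data.frame(event = 1L, energy_MeV = 2, x = 0, y = 0, z = 0,
                  ux = 0, uy = 0, uz = 1)
  expect_error(transport_electrons(p, w, transport_config()), "table bound")
})

test_that("photon escape follows the exponential chord law", {
  # from the center of a sphere of one attenuation length: P(escape) = 1/e
  lam <- attenuation_length(7.5)
  w <- sphere_world(4 / 3 * pi * lam^3 * 1e3)
  n <- 1e5
  set.seed(203)
  d <- matrix(c(rep(0, 2 * n), rep(1, n)), ncol = 3)
  p <- data.frame(event = 1L, energy_MeV = 7.5e-3, x = 0, y = 0, z = 0,
                  ux = d[, 1], uy = d[, 2], uz = d[, 3])
  tr <- transport_photons(p, w)
  esc <- mean(tr$inside == 0)
  expect_lt(abs(esc - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / n))
})

test_that("X-rays overwhelmingly escape a cell-sized sphere", {
  w <- sphere_world(1.4e-5)
  set.seed(204)
  pos <- place_source(w, 2e4)
  dirs <- cudosim:::isotropic_directions(2e4)
  p <- data.frame(event = 1L, energy_MeV = 7.48e-3,
                  x = pos[, 1], y = pos[, 2], z = pos[, 3],
                  ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3])
  tr <- transport_photons(p, w)
  expect_gt(mean(tr$inside == 0), 0.95)
})

test_that("a photon at the surface aimed outward always escapes", {
  w <- sphere_world(1)
  p <- data.frame(event = 1L, energy_MeV = 7.5e-3, x = 0, y = 0,
                  z = w$radius_cm, ux = 0, uy = 0, uz = 1)
  tr <- transport_photons(p, w)
  expect_identical(tr$inside, 0)
  # escape-only photons never deposit
  tr2 <- transport_photons(p, w, escape_only = TRUE)
  expect_identical(tr2$inside, 0)
})

test_that("tallies conserve energy per component and add up", {
  t1 <- simulate_sphere(1e-4, default_scheme, small_cfg(205))
  emitted <- t1$energy_inside_MeV + t1$energy_escaped_MeV
  # per-component emitted energy is positive and components sum to total
  expect_equal(sum(t1$dose_per_decay_Gy[t1$component != "total"]),
               t1$dose_per_decay_Gy[t1$component == "total"],
               tolerance = 1e-12)
  expect_equal(sum(emitted[t1$component %in% c("beta", "auger", "xray",
                                               "annihilation")]),
               emitted[t1$component == "total"], tolerance = 1e-12)
  expect_true(all(t1$energy_inside_MeV >= 0))
  # annihilation is escape-only
  expect_identical(t1$energy_inside_MeV[t1$component == "annihilation"], 0)
})

test_that("identical seeds give identical tallies", {
  a <- simulate_sphere(1e-5, default_scheme, small_cfg(206, n = 2000))
  b <- simulate_sphere(1e-5, default_scheme, small_cfg(206, n = 2000))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("component masking removes the masked component entirely", {
  t_no_auger <- simulate_sphere(1e-5, default_scheme,
                                small_cfg(207, n = 2000,
                                          components = c("beta", "xray")))
  expect_identical(t_no_auger$energy_inside_MeV[t_no_auger$component == "auger"], 0)
  expect_identical(t_no_auger$energy_escaped_MeV[t_no_auger$component == "auger"], 0)
})

test_that("containment fraction grows with volume for every component", {
  vols <- c(1e-7, 1e-5, 1e-3, 1e-1, 10)
  sw <- run_volume_sweep(vols, default_scheme, small_cfg(208, n = 4000))
  d <- as.data.frame(sw)
  for (cc in c("beta", "auger")) {
    di <- d[d$component == cc, ]
    frac <- di$energy_inside_MeV /
      (di$energy_inside_MeV + di$energy_escaped_MeV)
    expect_true(all(diff(frac) > -0.02))  # non-decreasing within MC noise
  }
  # dose (contained energy per decay) increases monotonically with volume
  tot <- d[d$component == "total", ]
  expect_true(all(diff(tot$dose_per_decay_Gy) > 0))
})

test_that("component_ratio propagates errors and handles edge cases", {
  t1 <- simulate_sphere(1e-5, default_scheme, small_cfg(209, n = 2000))
  r <- component_ratio(t1, "auger", "auger")
  expect_identical(unname(r["ratio"]), 1)
  rb <- component_ratio(t1, "beta", "auger")
  expect_gt(rb[["se"]], 0)
  expect_error(component_ratio(t1, "beta", "nope"), "unknown")
})

test_that("electron_track deposits sum to the initial energy", {
  tr <- electron_track(0.1)
  expect_equal(sum(tr$deposit_MeV), 0.1, tolerance = 1e-9)
  expect_true(all(diff(tr$s_cm) >= 0))
})
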