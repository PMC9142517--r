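# Cu-64 decay scheme sampling: channels, beta spectra, relaxation.

test_that("scheme validation enforces the published structure", {
  expect_error(cu64_decay_scheme(p_beta_minus = 0.5), "sum to 1")
  expect_error(cu64_decay_scheme(auger_energies_keV = c(5, 6),
                                 auger_weights = c(1, 1)), "Auger spectrum mean")
  expect_s3_class(cu64_decay_scheme(), "decay_scheme")
})

test_that("channel frequencies converge to the branching ratios", {
  set.seed(101)
  ch <- sample_channel(default_scheme, 1e6)
  f <- table(ch) / 1e6
  expect_equal(unname(f[["beta_minus"]]), 0.400, tolerance = 0.005)
  expect_equal(unname(f[["beta_plus"]]), 0.190, tolerance = 0.01)
  expect_equal(unname(f[["ec"]]), 0.410, tolerance = 0.005)
})

test_that("a degenerate scheme always picks its only channel", {
  sch <- cu64_decay_scheme(p_beta_minus = 0, p_beta_plus = 0, p_ec = 1)
  set.seed(1)
  expect_true(all(sample_channel(sch, 1000) == "ec"))
})

test_that("beta energies live strictly inside (0, endpoint)", {
  set.seed(102)
  E <- sample_beta_energy(2e4, 0.573, -1, 30)
  expect_true(all(E > 0 & E < 0.573))
})

test_that("sampled beta mean matches quadrature of the same density", {
  set.seed(103)
  n <- 2e5
  E <- sample_beta_energy(n, 0.573, -1, 30)
  mu <- oracle_beta_mean(0.573, -1, 30)
  expect_lt(abs(mean(E) - mu), 3 * sd(E) / sqrt(n))
  Ep <- sample_beta_energy(n, 0.656, +1, 28)
  mup <- oracle_beta_mean(0.656, +1, 28)
  expect_lt(abs(mean(Ep) - mup), 3 * sd(Ep) / sqrt(n))
})

test_that("Coulomb correction enhances beta- and suppresses beta+ at low energy", {
  lowE <- c(1e-4, 1e-3)
  dm <- beta_spectrum_density(lowE, 0.573, -1, 30)
  dp <- beta_spectrum_density(lowE, 0.656, +1, 28)
  expect_true(all(dm > 0))
  # positron density vanishes towards E = 0
  expect_lt(dp[1] / dp[2], 1e-3)
  expect_true(all(dp < dm))
})

test_that("Auger emission frequency matches the analytic factorization (~22%)", {
  set.seed(104)
  n <- 1e6
  ev <- sample_decay(default_scheme, n = n)
  has_auger <- tabulate(ev$particles$event[ev$particles$origin == "auger"],
                        nbins = n) > 0
  p_hat <- mean(has_auger)
  p_true <- auger_decay_fraction(default_scheme)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  expect_equal(p_hat, 0.22, tolerance = 0.05)
})

test_that("fluorescence yield 1 forbids Auger electrons", {
  sch <- cu64_decay_scheme(k_fluorescence_yield = 1)
  set.seed(105)
  rel <- sample_relaxation(sch, 1e4)
  expect_identical(nrow(rel$electrons), 0L)
})

test_that("X-ray line frequencies converge to the configured factorization", {
  set.seed(106)
  n <- 5e5
  ev <- sample_decay(default_scheme, n = n)
  xr <- ev$particles[ev$particles$origin == "xray", ]
  sch <- default_scheme
  kl <- sch$xray_lines[sch$xray_lines$label != "l", ]
  p_x <- sch$p_ec * sch$p_k_vacancy_given_ec * sch$k_fluorescence_yield
  ka1_true <- p_x * kl$fraction[kl$label == "ka1"] / sum(kl$fraction)
  ka1_hat <- sum(abs(xr$energy_MeV - 7.48e-3) < 1e-6) / n
  expect_lt(abs(ka1_hat - ka1_true), 3 * sqrt(ka1_true / n))
  # the model's analytic ka1 fraction sits within ~10% of the published 9.4%
  expect_equal(ka1_true, 0.094, tolerance = 0.10)
  # l line per-decay fraction matches its configured 0.5%
  l_hat <- sum(abs(xr$energy_MeV - 0.85e-3) < 1e-6) / n
  expect_lt(abs(l_hat - 0.005), 3 * sqrt(0.005 / n))
})

test_that("decay events honour the channel contracts", {
  set.seed(107)
  n <- 2e4
  ev <- sample_decay(default_scheme, n = n)
  p <- ev$particles
  for (i in which(ev$channel == "beta_minus")[1:50]) {
    pi <- p[p$event == i, ]
    expect_identical(sum(pi$origin == "beta_minus"), 1L)
    expect_false(any(pi$origin %in% c("auger", "xray")))
  }
  ec <- p$event %in% which(ev$channel == "ec")
  expect_true(all(p$origin[ec] %in% c("auger", "xray")))
  expect_true(all(p$energy_MeV > 0))
  # unit directions
  nrm <- with(p, ux^2 + uy^2 + uz^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
})

test_that("emission directions are isotropic", {
  set.seed(108)
  ev <- sample_decay(default_scheme, n = 3e4)
  ks <- suppressWarnings(ks.test(ev$particles$uz, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean emitted charged-particle energy matches the analytic expectation", {
  set.seed(109)
  n <- 1e5
  ev <- sample_decay(default_scheme, n = n)
  el <- ev$particles[ev$particles$species %in% c("electron", "positron"), ]
  per_decay <- numeric(n)
  agg <- rowsum(el$energy_MeV, el$event)
  per_decay[as.integer(rownames(agg))] <- agg
  me <- mean_emitted_energy(default_scheme)
  expect_lt(abs(mean(per_decay) - (me[["beta"]] + me[["auger"]])),
            3 * sd(per_decay) / sqrt(n))
})

test_that("identical seeds give identical event streams", {
  set.seed(42); a <- sample_decay(default_scheme, n = 500)
  set.seed(42); b <- sample_decay(default_scheme, n = 500)
  expect_identical(a, b)
})
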