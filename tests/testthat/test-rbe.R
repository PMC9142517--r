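# D10 / RBE arithmetic and survival-curve fitting.

test_that("decay counts follow the activity-time product", {
  expect_identical(decays_from_exposure(exposure_spec(1, 100)), 100)
  expect_equal(decays_from_exposure(exposure_spec(0.97, 5 * 3600)), 17460)
  # decay-corrected mode reduces to constant activity as half-life -> Inf
  long <- exposure_spec(2, 1000, half_life_s = 1e12)
  expect_equal(decays_from_exposure(long), 2000, tolerance = 1e-9)
  short <- exposure_spec(2, 1000, half_life_s = 500)
  expect_lt(decays_from_exposure(short), 2000)
})

test_that("dose from exposure is linear in activity", {
  s1 <- exposure_spec(0.5, 3600, dose_per_decay_Gy = 1e-9)
  s2 <- exposure_spec(1.0, 3600, dose_per_decay_Gy = 1e-9)
  expect_equal(dose_from_exposure(s2), 2 * dose_from_exposure(s1))
  expect_identical(dose_from_exposure(exposure_spec(0, 10,
                                                    dose_per_decay_Gy = 1)), 0)
  expect_error(dose_from_exposure(exposure_spec(1, 10)), "not set")
  # equal duration and dose/decay: dose ratio equals the activity ratio
  cho <- exposure_spec(0.97, 5 * 3600, dose_per_decay_Gy = 7.7e-10)
  xrs <- exposure_spec(0.40, 5 * 3600, dose_per_decay_Gy = 7.7e-10)
  expect_equal(dose_from_exposure(cho) / dose_from_exposure(xrs), 0.97 / 0.40)
})

test_that("D10 of a pure exponential is ln 10", {
  D <- seq(0.5, 4, by = 0.5)
  curve <- survival_curve(D, exp(-D))
  f <- d10_from_survival(curve, model = "loglinear")
  expect_equal(f$d10, log(10), tolerance = 1e-9)
  flq <- d10_from_survival(curve, model = "linear_quadratic")
  expect_equal(flq$d10, log(10), tolerance = 1e-6)
})

test_that("the LQ root reproduces 10% survival when substituted back", {
  alpha <- 0.2; beta <- 0.05
  D <- seq(0.5, 8, by = 0.5)
  curve <- survival_curve(D, exp(-alpha * D - beta * D^2))
  f <- d10_from_survival(curve)
  expect_equal(f$model, "linear_quadratic")
  expect_equal(exp(-f$alpha * f$d10 - f$beta * f$d10^2), 0.1,
               tolerance = 1e-9)
  expect_equal(f$alpha, alpha, tolerance = 1e-6)
  expect_equal(f$beta, beta, tolerance = 1e-6)
})

test_that("LQ with beta -> 0 converges to the log-linear closed form", {
  D <- seq(0.5, 6, by = 0.5)
  curve <- survival_curve(D, exp(-0.7 * D))
  f <- d10_from_survival(curve, model = "linear_quadratic")
  expect_equal(f$d10, log(10) / 0.7, tolerance = 1e-6)
})

test_that("a noisy synthetic curve recovers its true D10 within 5%", {
  curve <- gen_survival(generator_spec(401, noise_cv = 0.05))
  truth <- attr(curve, "truth")
  f <- d10_from_survival(curve)
  expect_equal(f$d10, truth$d10, tolerance = 0.05)
})

test_that("requesting D10 outside a shallow curve errors in loglinear mode", {
  curve <- survival_curve(c(1, 2, 3), c(0.9, 0.8, 0.7))
  expect_error(d10_from_survival(curve, model = "loglinear"), "outside")
})

test_that("rbe is the reference-to-test D10 ratio", {
  expect_equal(round(rbe(6.37, 5.31), 2), 1.20)
  expect_equal(round(rbe(6.37, 1.89), 2), 3.37)
  expect_identical(rbe(2.5, 2.5), 1)
  expect_error(rbe(-1, 2), "positive")
  # strictly decreasing in the test dose
  expect_gt(rbe(6, 1), rbe(6, 2))
})

test_that("the published D10 columns yield the published RBE columns", {
  cho <- build_rbe_table(data.frame(
    radiation = c("gamma", "proton", "carbon_13", "carbon_70", "iron"),
    d10 = c(6.37, 5.31, 3.79, 2.49, 1.89)))
  expect_equal(round_rbe_table(cho)$rbe, c(1, 1.20, 1.68, 2.56, 3.37))
  xrs <- build_rbe_table(data.frame(
    radiation = c("gamma", "proton", "carbon_13", "carbon_70", "iron"),
    d10 = c(1.18, 1.16, 0.91, 0.94, 1.00)))
  expect_equal(round_rbe_table(xrs)$rbe, c(1, 1.02, 1.30, 1.26, 1.18))
})

test_that("a single-row table gives RBE 1 and a missing reference errors", {
  one <- build_rbe_table(data.frame(radiation = "gamma", d10 = 6.37))
  expect_identical(one$rbe, 1)
  expect_error(build_rbe_table(data.frame(radiation = "x", d10 = 1)),
               "reference")
})

test_that("full chain: activity -> decays -> dose reproduces the D10 input", {
  # build a survival curve on the dose scale implied by a fixed dose chain,
  # then recover the D10-equivalent activity
  dpd <- 7.7e-10
  duration <- 5 * 3600
  act <- seq(0.2, 1.6, by = 0.2)
  doses <- vapply(act, function(a)
    dose_from_exposure(exposure_spec(a, duration, dose_per_decay_Gy = dpd)),
    numeric(1))
  true_d10 <- doses[5]  # define truth: 10% survival at the 5th dose
  sf <- pmin(exp(-log(10) * doses / true_d10), 1)
  f <- d10_from_survival(survival_curve(doses, sf))
  a10 <- f$d10 / (dpd * duration)
  expect_equal(a10, act[5], tolerance = 1e-6)
})
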