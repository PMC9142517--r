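# Synthetic-data generators with the statistical structure the analysis
# assumes: gamma calibration pairs (buffer vs copper chloride), Cu-64
# 7OH-C3CA volume series, and clonogenic survival curves. Every generated
# dataset carries its true parameters in a `truth` attribute so recovery
# tests compare estimates against embedded truth, never hard-coded numbers.

#' Generator settings
#'
#' @param seed Integer seed.
#' @param noise_cv Relative (coefficient-of-variation) measurement noise.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, noise_cv = 0.05) {
  stopifnot(noise_cv >= 0)
  structure(list(seed = as.integer(seed), noise_cv = noise_cv),
            class = "generator_spec")
}

mult_noise <- function(n, cv) {
  if (cv == 0) rep(1, n) else pmax(stats::rnorm(n, 1, cv), 1e-6)
}

#' Synthetic gamma calibration pair (buffer and copper chloride)
#'
#' Two linear 7OH-C3CA-versus-dose series: a phosphate-buffer series with
#' slope `slope_buffer` and a copper-chloride series with slope
#' `slope_buffer / slope_ratio` (default ratio 2.6), both with multiplicative
#' Gaussian noise. The dose grid uses the 6.2 Gy/min gamma dose rate preset
#' with one-minute steps.
#'
#' @param spec A `generator_spec`.
#' @param slope_buffer True buffer slope, mol/L per Gy.
#' @param slope_ratio True buffer/copper-chloride slope ratio.
#' @param doses_Gy Dose grid, Gy.
#' @return Data frame `label` (`gamma_buffer`/`gamma_cucl`), `dose_Gy`,
#'   `conc_7ohc3ca_M`; `truth` attribute holds the generating parameters.
#' @export
gen_gamma_calibration <- function(spec = generator_spec(),
                                  slope_buffer = 5e-8,
                                  slope_ratio = 2.6,
                                  doses_Gy = 6.2 * (1:6)) {
  stopifnot(all(doses_Gy > 0))
  set.seed(spec$seed)
  nb <- length(doses_Gy)
  out <- data.frame(
    label = rep(c("gamma_buffer", "gamma_cucl"), each = nb),
    dose_Gy = rep(doses_Gy, 2),
    conc_7ohc3ca_M = c(slope_buffer * doses_Gy,
                       slope_buffer / slope_ratio * doses_Gy) *
      mult_noise(2 * nb, spec$noise_cv)
  )
  attr(out, "truth") <- list(slope_buffer = slope_buffer,
                             slope_ratio = slope_ratio,
                             noise_cv = spec$noise_cv, seed = spec$seed)
  out
}

#' Synthetic Cu-64 7OH-C3CA volume series
#'
#' Emulates the volume-dependence experiment: C3CA solutions at 10--60 uL
#' final volume, exposed to dissolved Cu-64 at constant activity
#' concentration for 24 h. The per-decay 7OH-C3CA concentration at each
#' volume follows the supplied dose-per-decay model through the G-value /
#' conversion-efficiency chain, divided by the copper-chloride correction
#' factor (the generated series emulates the uncorrected measurement), with
#' multiplicative noise.
#'
#' @param spec A `generator_spec`.
#' @param dose_model Function mapping volume (uL) to dose per decay (Gy), or
#'   a `dose_sweep` covering the requested volumes (log-log interpolated).
#' @param volumes_uL Final solution volumes, uL.
#' @param constants `chemistry_constants`.
#' @param activity_MBq_per_uL Activity concentration of the added copper
#'   chloride solution, MBq per uL added (0.2 preset); with the 10% added
#'   fraction this fixes the decay count.
#' @param duration_s Exposure duration (24 h preset).
#' @return Data frame `label`, `volume_uL`, `duration_s`, `n_decays`,
#'   `conc_7ohc3ca_M`, `conc_per_decay`; `truth` attribute embeds the
#'   dose-per-decay curve and constants used.
#' @export
gen_cu64_volume_series <- function(spec = generator_spec(),
                                   dose_model,
                                   volumes_uL = c(10, 20, 30, 40, 50, 60),
                                   constants = chemistry_constants(),
                                   activity_MBq_per_uL = 0.2,
                                   duration_s = 24 * 3600) {
  f <- as_dose_model(dose_model)
  set.seed(spec$seed)
  dpd <- f(volumes_uL)
  # added copper-chloride volume is 10% of the final volume
  n_dec <- activity_MBq_per_uL * 1e6 * (volumes_uL / 10) * duration_s
  conc_pd <- dose_to_ohc3ca(dpd, mass_kg = volumes_uL * 1e-6,
                            volume_L = volumes_uL * 1e-6,
                            constants = constants) /
    constants$correction_factor
  noise <- mult_noise(length(volumes_uL), spec$noise_cv)
  out <- data.frame(label = "cu64", volume_uL = volumes_uL,
                    duration_s = duration_s, n_decays = n_dec,
                    conc_7ohc3ca_M = conc_pd * n_dec * noise,
                    conc_per_decay = conc_pd * noise)
  attr(out, "truth") <- list(dose_per_decay_Gy = dpd, volumes_uL = volumes_uL,
                             constants = constants, noise_cv = spec$noise_cv,
                             seed = spec$seed)
  out
}

# accept a function, a dose_sweep, or a (volume, dose) table
as_dose_model <- function(dose_model) {
  if (is.function(dose_model)) return(dose_model)
  if (inherits(dose_model, "dose_sweep")) {
    d <- as.data.frame(dose_model)
    d <- d[d$component == "total", ]
    dose_model <- d[, c("volume_uL", "dose_per_decay_Gy")]
  }
  stopifnot(is.data.frame(dose_model), ncol(dose_model) >= 2)
  v <- dose_model[[1]]; g <- dose_model[[2]]
  function(vol) {
    if (any(vol < min(v) | vol > max(v)))
      stop("dose model does not cover the requested volumes")
    exp(stats::approx(log(v), log(g), xout = log(vol))$y)
  }
}

#' Synthetic clonogenic survival curve
#'
#' `SF = exp(-alpha D - beta D^2)` with multiplicative lognormal noise,
#' clipped to (0, 1]. The truth attribute stores alpha, beta and the implied
#' D10.
#'
#' @param spec A `generator_spec`.
#' @param alpha,beta LQ parameters (/Gy, /Gy^2).
#' @param doses_Gy Dose grid, Gy.
#' @return A `survival_curve`; `truth` attribute holds `alpha`, `beta`,
#'   `d10`.
#' @export
gen_survival <- function(spec = generator_spec(), alpha = 0.3, beta = 0.05,
                         doses_Gy = seq(0.5, 6, by = 0.5)) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0)
  set.seed(spec$seed)
  sf <- exp(-alpha * doses_Gy - beta * doses_Gy^2) *
    exp(stats::rnorm(length(doses_Gy), 0, spec$noise_cv))
  sf <- pmin(pmax(sf, 1e-12), 1)
  curve <- survival_curve(doses_Gy, sf)
  ln10 <- log(10)
  d10 <- 2 * ln10 / (alpha + sqrt(alpha^2 + 4 * beta * ln10))
  attr(curve, "truth") <- list(alpha = alpha, beta = beta, d10 = d10,
                               noise_cv = spec$noise_cv, seed = spec$seed)
  curve
}
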