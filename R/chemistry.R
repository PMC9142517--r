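# C3CA chemical dosimetry: linear calibration fits, hydroxyl-radical yield,
# and G-value-based Co-60-equivalent dose reconstruction.
#
# Coumarin-3-carboxylic acid converts a fixed fraction (4.7 +/- 0.6%) of the
# hydroxyl radicals produced by water radiolysis into fluorescent 7OH-C3CA,
# independent of radiation quality. With the Co-60 gamma G-value for OH
# (2.7 per 100 eV) a measured 7OH-C3CA amount maps linearly to a
# Co-60-equivalent absorbed dose.

#' Chemical dosimetry constants
#'
#' @param conversion_efficiency Fraction of OH radicals converted to
#'   7OH-C3CA (default 0.047).
#' @param conversion_efficiency_se Its standard error (default 0.006).
#' @param g_oh_co60 G-value of OH for Co-60 gamma rays, per 100 eV.
#' @param c3ca_concentration C3CA molarity, mol/L.
#' @param correction_factor Copper-chloride correction factor (buffer slope /
#'   copper-chloride slope from the gamma calibration; default 2.6).
#' @return Object of class `chemistry_constants`.
#' @export
chemistry_constants <- function(conversion_efficiency = 0.047,
                                conversion_efficiency_se = 0.006,
                                g_oh_co60 = 2.7,
                                c3ca_concentration = 5e-4,
                                correction_factor = 2.6) {
  stopifnot(conversion_efficiency > 0, conversion_efficiency < 1,
            g_oh_co60 > 0, correction_factor > 0)
  structure(list(conversion_efficiency = conversion_efficiency,
                 conversion_efficiency_se = conversion_efficiency_se,
                 g_oh_co60 = g_oh_co60,
                 c3ca_concentration = c3ca_concentration,
                 correction_factor = correction_factor),
            class = "chemistry_constants")
}

#' Ordinary least-squares line over a restricted range
#'
#' Fits `y = a x + b` by OLS using only points with `x <= range_max`,
#' recording the fit range with the result.
#'
#' @param x,y Numeric vectors.
#' @param range_max Inclusive upper bound on x used for the fit (default:
#'   all points).
#' @return Object of class `calibration_fit`: fields `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `fit_range`, `n`, and the underlying `lm`.
#' @export
fit_linear <- function(x, y, range_max = Inf) {
  keep <- is.finite(x) & is.finite(y) & x <= range_max
  if (sum(keep) < 3)
    stop("fit_linear: fewer than 3 points within the fit range")
  fit <- stats::lm(y ~ x, data = data.frame(x = x[keep], y = y[keep]))
  # exact (noise-free) input is legitimate here; silence the perfect-fit note
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = cf["x", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 slope_se = cf["x", "Std. Error"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 fit_range = c(min(x[keep]), min(range_max, max(x[keep]))),
                 n = sum(keep),
                 lm = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Linear calibration fit (n = %d, x in [%.3g, %.3g])\n",
              x$n, x$fit_range[1], x$fit_range[2]))
  cat(sprintf("  slope     %.4g +/- %.3g\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.4g +/- %.3g\n", x$intercept, x$intercept_se))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Copper-chloride correction factor from two calibration fits
#'
#' Ratio of the phosphate-buffer slope to the copper-chloride slope of the
#' gamma calibration, with first-order error propagation.
#'
#' @param fit_buffer,fit_cucl `calibration_fit` objects.
#' @return Object of class `correction_factor`: `value`, `se`, `provenance`.
#' @export
correction_factor <- function(fit_buffer, fit_cucl) {
  if (fit_buffer$slope <= 0 || fit_cucl$slope <= 0)
    stop("correction_factor: calibration slopes must be positive")
  v <- fit_buffer$slope / fit_cucl$slope
  se <- v * sqrt((fit_buffer$slope_se / fit_buffer$slope)^2 +
                   (fit_cucl$slope_se / fit_cucl$slope)^2)
  structure(list(value = v, se = se,
                 provenance = "ratio of buffer to copper-chloride slopes"),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("Correction factor %.3g +/- %.2g (%s)\n",
              x$value, x$se, x$provenance))
  invisible(x)
}

#' Convert a 7OH-C3CA concentration to a hydroxyl-radical concentration
#'
#' Divides by the conversion efficiency (4.7% default); the efficiency's
#' uncertainty propagates to the result.
#'
#' @param conc_7ohc3ca 7OH-C3CA concentration (any linear unit), >= 0.
#' @param constants `chemistry_constants`.
#' @param conc_se Optional standard error of the measured concentration.
#' @return Named numeric: `value` (same unit as input) and `se`.
#' @export
ohc3ca_to_oh <- function(conc_7ohc3ca, constants = chemistry_constants(),
                         conc_se = 0) {
  stopifnot(all(conc_7ohc3ca >= 0))
  eff <- constants$conversion_efficiency
  v <- conc_7ohc3ca / eff
  rel <- sqrt((constants$conversion_efficiency_se / eff)^2 +
                ifelse(conc_7ohc3ca > 0, (conc_se / conc_7ohc3ca)^2, 0))
  list(value = v, se = v * rel)
}

#' Co-60-equivalent dose from a hydroxyl-radical amount
#'
#' `dose = N_OH * (100 eV / G) * 1.602e-19 J/eV / mass`, with G the Co-60
#' gamma G-value of OH.
#'
#' @param oh_mol Amount of OH radicals, mol.
#' @param mass_kg Irradiated mass, kg.
#' @param constants `chemistry_constants`.
#' @param n_decays Optional decay count; if given the dose is returned per
#'   decay.
#' @return Dose in Gy (or Gy/decay when `n_decays` is given).
#' @export
co60_equivalent_dose <- function(oh_mol, mass_kg,
                                 constants = chemistry_constants(),
                                 n_decays = NULL) {
  stopifnot(mass_kg > 0, all(oh_mol >= 0))
  dose <- oh_mol * AVOGADRO * (100 / constants$g_oh_co60) * EV_TO_J / mass_kg
  if (!is.null(n_decays)) dose <- dose / n_decays
  dose
}

#' Expected 7OH-C3CA concentration for a given dose
#'
#' Inverse of the reconstruction chain (dose -> OH via G -> 7OH-C3CA via the
#' conversion efficiency); used by the synthetic-data generators and by the
#' round-trip identity checks.
#'
#' @param dose_Gy Absorbed dose, Gy.
#' @param mass_kg Solution mass, kg.
#' @param volume_L Solution volume, L (for molarity).
#' @param constants `chemistry_constants`.
#' @return 7OH-C3CA concentration, mol/L.
#' @export
dose_to_ohc3ca <- function(dose_Gy, mass_kg, volume_L,
                           constants = chemistry_constants()) {
  oh_mol <- dose_Gy * mass_kg / EV_TO_J / (100 / constants$g_oh_co60) / AVOGADRO
  oh_mol * constants$conversion_efficiency / volume_L
}

#' Reconstruct per-decay dose from a Cu-64 7OH-C3CA volume series
#'
#' Applies the full chemical-dosimetry chain to a measured (or synthetic)
#' series of per-decay 7OH-C3CA concentrations versus solution volume:
#' linear fit below `fit_max_volume`, conversion to OH, then G-value dose at
#' the requested volume.
#'
#' @param volumes_uL Solution volumes, uL.
#' @param conc_per_decay 7OH-C3CA concentration per decay, mol/L/decay.
#' @param at_volume_uL Volume at which to evaluate the reconstructed dose.
#' @param constants `chemistry_constants`.
#' @param fit_max_volume Inclusive fit bound, uL (linear portion).
#' @param apply_correction Multiply concentrations by the copper-chloride
#'   correction factor (guard: an attribute marks corrected output so the
#'   factor cannot be applied twice).
#' @return List: `dose_per_decay_Gy`, `se`, `fit` (the `calibration_fit`).
#' @export
reconstruct_dose_per_decay <- function(volumes_uL, conc_per_decay,
                                       at_volume_uL = 30,
                                       constants = chemistry_constants(),
                                       fit_max_volume = 30,
                                       apply_correction = TRUE) {
  conc <- conc_per_decay
  if (apply_correction) {
    if (isTRUE(attr(conc, "cucl_corrected")))
      stop("reconstruct_dose_per_decay: correction factor already applied")
    conc <- conc * constants$correction_factor
    attr(conc, "cucl_corrected") <- TRUE
  }
  fit <- fit_linear(volumes_uL, as.numeric(conc), fit_max_volume)
  c_at <- fit$slope * at_volume_uL + fit$intercept
  c_se <- sqrt((fit$slope_se * at_volume_uL)^2 + fit$intercept_se^2)
  oh <- ohc3ca_to_oh(c_at, constants, conc_se = c_se)
  vol_L <- at_volume_uL * 1e-6
  mass_kg <- at_volume_uL * 1e-6  # 1 uL of water = 1e-6 kg
  dose <- co60_equivalent_dose(oh$value * vol_L, mass_kg, constants)
  list(dose_per_decay_Gy = dose,
       se = dose * ifelse(oh$value > 0, oh$se / oh$value, 0),
       fit = fit)
}
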