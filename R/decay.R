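# Cu-64 decay scheme and per-decay emission sampling.
#
# Cu-64 decays by beta-minus emission (endpoint 0.573 MeV, 40%), beta-plus
# emission (endpoint 0.656 MeV, 19%) and electron capture (41%). Electron
# capture leaves an inner-shell vacancy in the nickel daughter that relaxes
# either by K X-ray fluorescence or by Auger-electron emission.

MEC2 <- 0.5109989        # electron rest energy, MeV
FINE_STRUCTURE <- 1 / 137.035999

#' Cu-64 decay scheme
#'
#' Builds the default decay scheme used throughout the package. The K-vacancy
#' probability per electron capture (0.88) and the K fluorescence yield of the
#' nickel daughter (0.41) factorise the relaxation so that the fraction of all
#' decays emitting at least one Auger electron is
#' `p_ec * p_k_vacancy_given_ec * (1 - k_fluorescence_yield)` (about 0.21) and
#' the per-decay K X-ray fraction is about 0.15. The discrete Auger spectrum
#' stands in for the cascade-averaged line set; its mean is close to 2 keV.
#'
#' @param p_beta_minus,p_beta_plus,p_ec Channel probabilities; must sum to 1.
#' @param e_max_beta_minus,e_max_beta_plus Beta endpoint energies, MeV.
#' @param p_k_vacancy_given_ec Probability that an electron capture leaves a
#'   K-shell vacancy.
#' @param k_fluorescence_yield Probability that a K vacancy relaxes by X-ray
#'   fluorescence rather than Auger emission.
#' @param xray_lines Data frame with columns `label`, `energy_keV`,
#'   `fraction` (per-decay emission fraction, used for relative line weights).
#' @param auger_energies_keV,auger_weights Discrete Auger line energies (keV)
#'   and their sampling weights; the weighted mean must lie in [1.5, 2.5] keV.
#' @param n_auger_per_cascade Number of Auger electrons emitted per Auger
#'   relaxation.
#' @return An object of class `decay_scheme`.
#' @export
cu64_decay_scheme <- function(p_beta_minus = 0.40,
                              p_beta_plus = 0.19,
                              p_ec = 0.41,
                              e_max_beta_minus = 0.573,
                              e_max_beta_plus = 0.656,
                              p_k_vacancy_given_ec = 0.88,
                              k_fluorescence_yield = 0.41,
                              xray_lines = data.frame(
                                label = c("l", "ka1", "ka2", "kb1", "kb3"),
                                energy_keV = c(0.85, 7.48, 7.46, 8.27, 8.27),
                                fraction = c(0.005, 0.094, 0.048, 0.011, 0.0058)
                              ),
                              auger_energies_keV =
                                c(0.12, 0.52, 0.74, 0.84, 6.24, 6.83),
                              auger_weights =
                                c(0.15, 0.20, 0.20, 0.22, 0.12, 0.11),
                              n_auger_per_cascade = 1L) {
  scheme <- structure(list(
    p_beta_minus = p_beta_minus,
    p_beta_plus = p_beta_plus,
    p_ec = p_ec,
    e_max_beta_minus = e_max_beta_minus,
    e_max_beta_plus = e_max_beta_plus,
    daughter_z_beta_minus = 30,  # Zn-64
    daughter_z_beta_plus = 28,   # Ni-64
    p_k_vacancy_given_ec = p_k_vacancy_given_ec,
    k_fluorescence_yield = k_fluorescence_yield,
    xray_lines = xray_lines,
    auger_energies_keV = auger_energies_keV,
    auger_weights = auger_weights / sum(auger_weights),
    n_auger_per_cascade = as.integer(n_auger_per_cascade)
  ), class = "decay_scheme")
  validate_decay_scheme(scheme)
  scheme
}

validate_decay_scheme <- function(scheme) {
  p <- c(scheme$p_beta_minus, scheme$p_beta_plus, scheme$p_ec,
         scheme$p_k_vacancy_given_ec, scheme$k_fluorescence_yield)
  if (any(p < 0 | p > 1)) stop("decay_scheme: probabilities must lie in [0, 1]")
  if (abs(scheme$p_beta_minus + scheme$p_beta_plus + scheme$p_ec - 1) > 1e-9)
    stop("decay_scheme: channel probabilities must sum to 1")
  if (any(c(scheme$e_max_beta_minus, scheme$e_max_beta_plus,
            scheme$xray_lines$energy_keV, scheme$auger_energies_keV) <= 0))
    stop("decay_scheme: energies must be positive")
  m <- sum(scheme$auger_energies_keV * scheme$auger_weights)
  if (m < 1.5 || m > 2.5)
    stop(sprintf("decay_scheme: Auger spectrum mean %.2f keV outside [1.5, 2.5]", m))
  if (scheme$n_auger_per_cascade < 1L)
    stop("decay_scheme: n_auger_per_cascade must be >= 1")
  invisible(scheme)
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat("Cu-64-style decay scheme\n")
  cat(sprintf("  channels: beta- %.0f%% (endpoint %.3f MeV), beta+ %.0f%% (%.3f MeV), EC %.0f%%\n",
              100 * x$p_beta_minus, x$e_max_beta_minus,
              100 * x$p_beta_plus, x$e_max_beta_plus, 100 * x$p_ec))
  cat(sprintf("  K vacancy per EC %.2f, K fluorescence yield %.2f\n",
              x$p_k_vacancy_given_ec, x$k_fluorescence_yield))
  cat(sprintf("  Auger: mean line energy %.2f keV, %d electron(s) per cascade; P(>=1 Auger) = %.3f\n",
              sum(x$auger_energies_keV * x$auger_weights),
              x$n_auger_per_cascade, auger_decay_fraction(x)))
  cat(sprintf("  X-ray lines: %s\n",
              paste(sprintf("%s %.2f keV", x$xray_lines$label,
                            x$xray_lines$energy_keV), collapse = ", ")))
  invisible(x)
}

#' Analytic per-decay Auger emission probability
#'
#' @param scheme A `decay_scheme`.
#' @return Probability that a decay emits at least one Auger electron:
#'   `p_ec * p_k_vacancy_given_ec * (1 - k_fluorescence_yield)`.
#' @export
auger_decay_fraction <- function(scheme) {
  scheme$p_ec * scheme$p_k_vacancy_given_ec * (1 - scheme$k_fluorescence_yield)
}

#' Sample decay channels
#'
#' @param scheme A `decay_scheme`.
#' @param n Number of draws.
#' @return Character vector of `"beta_minus"`, `"beta_plus"`, `"ec"`.
#' @export
sample_channel <- function(scheme, n = 1L) {
  u <- stats::runif(n)
  ifelse(u < scheme$p_beta_minus, "beta_minus",
         ifelse(u < scheme$p_beta_minus + scheme$p_beta_plus,
                "beta_plus", "ec"))
}

#' Allowed beta spectrum density (unnormalised)
#'
#' Shape `p W (Q - E)^2 F(Z, W)` of an allowed transition, with the
#' nonrelativistic Coulomb (Fermi) factor
#' `F = 2 pi eta / (1 - exp(-2 pi eta))`, `eta = +/- Z alpha W / p` (positive
#' for electrons, negative for positrons). Electron spectra are enhanced at
#' low energy, positron spectra suppressed to zero.
#'
#' @param energy Kinetic energy, MeV (vectorised).
#' @param endpoint Endpoint energy Q, MeV.
#' @param charge_sign -1 for beta-minus, +1 for beta-plus.
#' @param daughter_z Atomic number of the daughter nucleus.
#' @return Unnormalised density values (0 outside (0, Q)).
#' @export
beta_spectrum_density <- function(energy, endpoint, charge_sign, daughter_z) {
  out <- numeric(length(energy))
  ok <- energy > 0 & energy < endpoint
  E <- energy[ok]
  W <- (E + MEC2) / MEC2               # total energy, units of mec2
  p <- sqrt(W^2 - 1)                   # momentum, units of mec
  eta <- -charge_sign * daughter_z * FINE_STRUCTURE * W / p
  x <- 2 * pi * eta
  fermi <- ifelse(abs(x) < 1e-12, 1, x / (1 - exp(-x)))
  out[ok] <- p * W * (endpoint - E)^2 * fermi
  out
}

# numerical mean of the implemented spectrum (trapezoid quadrature)
beta_spectrum_mean <- function(endpoint, charge_sign, daughter_z, n = 4096L) {
  E <- seq(0, endpoint, length.out = n + 2L)[-c(1L, n + 2L)]
  d <- beta_spectrum_density(E, endpoint, charge_sign, daughter_z)
  sum(E * d) / sum(d)
}

#' Sample beta kinetic energies from the allowed spectrum
#'
#' Rejection sampling under a uniform envelope over (0, endpoint).
#'
#' @param n Number of draws.
#' @inheritParams beta_spectrum_density
#' @return Kinetic energies in MeV, strictly inside (0, endpoint).
#' @export
sample_beta_energy <- function(n, endpoint, charge_sign, daughter_z) {
  stopifnot(endpoint > 0)
  grid <- seq(endpoint / 2000, endpoint * (1 - 1e-9), length.out = 2000L)
  dmax <- max(beta_spectrum_density(grid, endpoint, charge_sign, daughter_z)) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 256L)
    E <- stats::runif(m, 0, endpoint)
    keep <- stats::runif(m) * dmax <
      beta_spectrum_density(E, endpoint, charge_sign, daughter_z)
    out <- c(out, E[keep])
  }
  out[seq_len(n)]
}

#' Sample electron-capture relaxation products
#'
#' For each electron capture: with probability `p_k_vacancy_given_ec` a K
#' vacancy is created, which relaxes by fluorescence (one K X-ray drawn from
#' the K lines' relative weights) with probability `k_fluorescence_yield`,
#' otherwise by an Auger cascade (`n_auger_per_cascade` electrons drawn from
#' the discrete Auger spectrum). The low-energy l line is emitted as an
#' independent outer-shell fluorescence with per-EC probability equal to its
#' per-decay fraction divided by `p_ec`.
#'
#' @param scheme A `decay_scheme`.
#' @param n Number of electron-capture events to relax.
#' @return A list with data frames `electrons` (`event`, `energy_MeV`) and
#'   `photons` (`event`, `label`, `energy_MeV`).
#' @export
sample_relaxation <- function(scheme, n = 1L) {
  has_k <- stats::runif(n) < scheme$p_k_vacancy_given_ec
  fluor <- stats::runif(n) < scheme$k_fluorescence_yield
  # Auger cascades
  aev <- which(has_k & !fluor)
  na <- scheme$n_auger_per_cascade
  electrons <- data.frame(
    event = rep(aev, each = na),
    energy_MeV = sample(scheme$auger_energies_keV, length(aev) * na,
                        replace = TRUE, prob = scheme$auger_weights) * 1e-3
  )
  # K fluorescence
  kl <- scheme$xray_lines[scheme$xray_lines$label != "l", ]
  xev <- which(has_k & fluor)
  ki <- sample.int(nrow(kl), length(xev), replace = TRUE,
                   prob = kl$fraction / sum(kl$fraction))
  # independent l-line fluorescence
  ll <- scheme$xray_lines[scheme$xray_lines$label == "l", ]
  p_l <- if (nrow(ll) == 1L) ll$fraction / scheme$p_ec else 0
  lev <- which(stats::runif(n) < p_l)
  photons <- data.frame(
    event = c(xev, lev),
    label = c(kl$label[ki], rep("l", length(lev))),
    energy_MeV = c(kl$energy_keV[ki], rep(ll$energy_keV, length(lev))) * 1e-3
  )
  list(electrons = electrons, photons = photons)
}

# isotropic unit vectors, n x 3
isotropic_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Sample complete decay events
#'
#' Composes channel choice, beta-spectrum sampling and electron-capture
#' relaxation into a per-decay particle list with isotropic directions.
#'
#' @param scheme A `decay_scheme`.
#' @param positions n x 3 matrix of decay positions (cm); recycled if one row.
#' @param n Number of decays.
#' @return A list of class `decay_events`: `channel` (length n) and
#'   `particles`, a data frame with columns `event`, `species`
#'   (electron/positron/photon), `origin` (beta_minus/beta_plus/auger/xray),
#'   `energy_MeV`, `x`, `y`, `z`, `ux`, `uy`, `uz`.
#' @export
sample_decay <- function(scheme, positions = matrix(0, 1, 3), n = 1L) {
  if (nrow(positions) == 1L && n > 1L)
    positions <- positions[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(positions) == n)
  channel <- sample_channel(scheme, n)

  ev_bm <- which(channel == "beta_minus")
  ev_bp <- which(channel == "beta_plus")
  ev_ec <- which(channel == "ec")

  pieces <- list()
  if (length(ev_bm)) {
    pieces$bm <- data.frame(
      event = ev_bm, species = "electron", origin = "beta_minus",
      energy_MeV = sample_beta_energy(length(ev_bm), scheme$e_max_beta_minus,
                                      -1, scheme$daughter_z_beta_minus))
  }
  if (length(ev_bp)) {
    pieces$bp <- data.frame(
      event = ev_bp, species = "positron", origin = "beta_plus",
      energy_MeV = sample_beta_energy(length(ev_bp), scheme$e_max_beta_plus,
                                      +1, scheme$daughter_z_beta_plus))
  }
  if (length(ev_ec)) {
    rel <- sample_relaxation(scheme, length(ev_ec))
    if (nrow(rel$electrons)) {
      pieces$au <- data.frame(
        event = ev_ec[rel$electrons$event], species = "electron",
        origin = "auger", energy_MeV = rel$electrons$energy_MeV)
    }
    if (nrow(rel$photons)) {
      pieces$xr <- data.frame(
        event = ev_ec[rel$photons$event], species = "photon",
        origin = "xray", energy_MeV = rel$photons$energy_MeV)
    }
  }
  particles <- do.call(rbind, unname(pieces))
  if (is.null(particles)) {
    particles <- data.frame(event = integer(), species = character(),
                            origin = character(), energy_MeV = numeric())
  }
  np <- nrow(particles)
  dirs <- isotropic_directions(np)
  particles$x <- positions[particles$event, 1L]
  particles$y <- positions[particles$event, 2L]
  particles$z <- positions[particles$event, 3L]
  particles$ux <- dirs[, 1L]
  particles$uy <- dirs[, 2L]
  particles$uz <- dirs[, 3L]
  rownames(particles) <- NULL
  structure(list(channel = channel, particles = particles),
            class = "decay_events")
}

#' Analytic mean emitted electron + positron energy per decay
#'
#' Expectation of the total beta-particle and Auger-electron kinetic energy
#' emitted per decay, from the branching ratios, the quadrature means of the
#' implemented beta spectra, and the Auger cascade configuration. Used as the
#' full-absorption dose limit at large sphere volumes.
#'
#' @param scheme A `decay_scheme`.
#' @return Named numeric: `beta`, `auger`, `xray` mean emitted energy
#'   (MeV per decay).
#' @export
mean_emitted_energy <- function(scheme) {
  eb <- scheme$p_beta_minus *
    beta_spectrum_mean(scheme$e_max_beta_minus, -1, scheme$daughter_z_beta_minus) +
    scheme$p_beta_plus *
    beta_spectrum_mean(scheme$e_max_beta_plus, +1, scheme$daughter_z_beta_plus)
  ea <- auger_decay_fraction(scheme) * scheme$n_auger_per_cascade *
    sum(scheme$auger_energies_keV * scheme$auger_weights) * 1e-3
  kl <- scheme$xray_lines[scheme$xray_lines$label != "l", ]
  p_k_x <- scheme$p_ec * scheme$p_k_vacancy_given_ec * scheme$k_fluorescence_yield
  ll <- scheme$xray_lines[scheme$xray_lines$label == "l", ]
  ex <- p_k_x * sum(kl$energy_keV * kl$fraction) / sum(kl$fraction) * 1e-3 +
    (if (nrow(ll)) ll$fraction * ll$energy_keV * 1e-3 else 0)
  c(beta = eb, auger = ea, xray = ex)
}
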