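# Independent oracles used across the suite. These re-derive expected values
# from closed forms or brute-force quadrature, independently of the package's
# interpolation/stepping code paths.

# Berger-Seltzer electron collision mass stopping power for water, MeV cm^2/g
# (independent implementation; I = 75 eV, Z/A = 0.55509).
oracle_berger_seltzer <- function(E_MeV) {
  mc2 <- 0.5109989
  tau <- E_MeV / mc2
  gamma <- tau + 1
  beta2 <- 1 - 1 / gamma^2
  I <- 75e-6
  term_log <- log(tau^2 * (tau + 2) / (2 * (I / mc2)^2))
  Fminus <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  0.153536 / beta2 * 0.55509 * (term_log + Fminus)
}

# Remaining energy of an electron after travelling `path_cm` straight through
# water, by fine explicit integration of dE/ds = -S(E) (independent of the
# package's range-table stepping).
oracle_energy_after_path <- function(E0, path_cm, n = 20000L) {
  E <- E0
  ds <- path_cm / n
  for (i in seq_len(n)) {
    E <- E - cudosim::stopping_power(max(E, 7.4e-6)) * ds
    if (E <= 7.4e-6) return(0)
  }
  E
}

# Mean of the allowed beta spectrum by trapezoid quadrature of the same
# density the sampler draws from (checks the sampler, not the density).
oracle_beta_mean <- function(endpoint, charge_sign, daughter_z, n = 20000L) {
  E <- seq(endpoint / n, endpoint * (1 - 1e-9), length.out = n)
  d <- cudosim::beta_spectrum_density(E, endpoint, charge_sign, daughter_z)
  sum(E * d) / sum(d)
}

# Hand log-log interpolation between the two table rows bracketing x.
oracle_loglog_between_rows <- function(tab, x) {
  i <- findInterval(x, tab$energy)
  w <- (log(x) - log(tab$energy[i])) /
    (log(tab$energy[i + 1]) - log(tab$energy[i]))
  exp((1 - w) * log(tab$value[i]) + w * log(tab$value[i + 1]))
}

default_scheme <- cudosim::cu64_decay_scheme()
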