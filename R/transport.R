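# mass of the 1 uL reference volume behind the per-activity-concentration
# dose convention (1 Bq/uL): dose_per_decay = E_inside * 1.602e-13 / 1e-6 kg
REFERENCE_MASS_KG <- 1e-6

# Condensed-history transport of Cu-64 emissions in a water sphere.
#
# Electrons and positrons advance along straight CSDA tracks (optionally
# shortened by a detour factor) losing a fixed fraction of their energy per
# step; each step's loss is apportioned between inside and outside of the
# sphere exactly, by the overlap of the step segment with the chord to the
# surface. Photons interact at an exponentially sampled depth or escape.

#' Spherical simulation world
#'
#' @param volume_uL Sphere volume in microlitres (1 uL = 1e-3 cm^3). The
#'   supported sweep spans 1e-11 to 1e3 uL.
#' @param density Medium density, g/cm^3 (water).
#' @return Object of class `sphere_world` with fields `volume_uL`,
#'   `radius_cm`, `density`, `mass_kg`.
#' @export
sphere_world <- function(volume_uL, density = 1.0) {
  stopifnot(volume_uL > 0, density > 0)
  v_cm3 <- volume_uL * 1e-3
  structure(list(
    volume_uL = volume_uL,
    radius_cm = (3 * v_cm3 / (4 * pi))^(1 / 3),
    density = density,
    mass_kg = v_cm3 * density * 1e-3
  ), class = "sphere_world")
}

#' Transport configuration
#'
#' @param electron_cutoff Tracking cutoff, MeV; electrons below it deposit
#'   their remaining energy locally (default 7.4 eV).
#' @param step_fraction Maximum fractional energy loss per condensed step,
#'   in (0, 0.2].
#' @param detour_factor Ratio of straight-line penetration to CSDA path
#'   length, in (0, 1]; 1 means straight full-length tracks.
#' @param n_decays Decays simulated per volume point.
#' @param seed Master seed; each volume point derives its own stream.
#' @param activity_concentration Bq/uL, carried as metadata only (dose is
#'   normalised per simulated decay).
#' @param components Emission components to simulate; any subset of
#'   `c("beta", "auger", "xray")`. Masking Auger reproduces the
#'   "without Auger electrons" simulation variant.
#' @return Object of class `transport_config`.
#' @export
transport_config <- function(electron_cutoff = ELECTRON_CUTOFF_MEV,
                             step_fraction = 0.05,
                             detour_factor = 1.0,
                             n_decays = 1e5,
                             seed = 1L,
                             activity_concentration = 1,
                             components = c("beta", "auger", "xray")) {
  stopifnot(step_fraction > 0, step_fraction <= 0.2,
            electron_cutoff >= ELECTRON_CUTOFF_MEV,
            detour_factor > 0, detour_factor <= 1,
            n_decays >= 1,
            all(components %in% c("beta", "auger", "xray")))
  structure(list(electron_cutoff = electron_cutoff,
                 step_fraction = step_fraction,
                 detour_factor = detour_factor,
                 n_decays = as.integer(n_decays),
                 seed = as.integer(seed),
                 activity_concentration = activity_concentration,
                 components = components),
            class = "transport_config")
}

#' Uniform source positions inside a sphere
#'
#' @param world A `sphere_world`.
#' @param n Number of positions.
#' @return n x 3 matrix of positions (cm), uniform over the sphere volume.
#' @export
place_source <- function(world, n = 1L) {
  r <- world$radius_cm * stats::runif(n)^(1 / 3)
  isotropic_directions(n) * r
}

# distance along (ux,uy,uz) from an interior point to the sphere surface
chord_to_surface <- function(x, y, z, ux, uy, uz, radius) {
  b <- x * ux + y * uy + z * uz
  c0 <- x^2 + y^2 + z^2 - radius^2
  -b + sqrt(pmax(b^2 - c0, 0))
}

#' Transport electrons and positrons
#'
#' Vectorised condensed-history transport. Each particle advances along its
#' emission direction; per energy step of fractional loss `step_fraction` the
#' geometric step length is the CSDA path difference scaled by
#' `detour_factor`, and the step's energy loss is split between inside and
#' outside by the exact overlap of the step segment with the chord to the
#' sphere surface. Remaining energy below the cutoff deposits locally.
#' Deposited inside + outside equals the initial energy exactly.
#'
#' @param particles Data frame with columns `event`, `energy_MeV`, `x`, `y`,
#'   `z`, `ux`, `uy`, `uz` (positions in cm, unit directions).
#' @param world A `sphere_world`.
#' @param config A `transport_config`.
#' @param chunk_rows Approximate flattened rows per processing chunk
#'   (memory/speed trade-off).
#' @return List: `inside`, `outside` (per-particle energies, MeV),
#'   `end_x/y/z` (track end points, cm).
#' @export
transport_electrons <- function(particles, world, config = transport_config(),
                                chunk_rows = 2e6) {
  np <- nrow(particles)
  inside <- numeric(np)
  end_x <- numeric(np); end_y <- numeric(np); end_z <- numeric(np)
  if (np == 0L)
    return(list(inside = inside, outside = numeric(0),
                end_x = end_x, end_y = end_y, end_z = end_z))
  tabmax <- water_stopping_table()$energy[nrow(water_stopping_table())]
  if (any(particles$energy_MeV > tabmax))
    stop(sprintf("transport_electrons: energy above table bound %g MeV", tabmax))

  f <- config$step_fraction
  cutoff <- config$electron_cutoff
  det <- config$detour_factor
  Rs <- world$radius_cm

  E0 <- particles$energy_MeV
  # below-cutoff particles deposit everything at the emission point
  sub <- E0 <= cutoff
  inside[sub] <- E0[sub]   # emission points are always inside the sphere
  end_x[sub] <- particles$x[sub]
  end_y[sub] <- particles$y[sub]
  end_z[sub] <- particles$z[sub]

  act <- which(!sub)
  if (length(act)) {
    m <- pmax(ceiling(log(cutoff / E0[act]) / log1p(-f)), 1L)
    tplus <- chord_to_surface(particles$x[act], particles$y[act],
                              particles$z[act], particles$ux[act],
                              particles$uy[act], particles$uz[act], Rs)
    R0 <- csda_range(E0[act])
    send <- det * R0
    end_x[act] <- particles$x[act] + particles$ux[act] * send
    end_y[act] <- particles$y[act] + particles$uy[act] * send
    end_z[act] <- particles$z[act] + particles$uz[act] * send

    rows_per <- m + 1L
    avg <- mean(rows_per)
    chunk_np <- max(64L, as.integer(chunk_rows / avg))
    for (start in seq(1L, length(act), by = chunk_np)) {
      ii <- start:min(start + chunk_np - 1L, length(act))
      mi <- m[ii]
      idx <- rep(seq_along(ii), mi + 1L)
      j <- sequence(mi + 1L) - 1L
      Ej <- E0[act][ii][idx] * (1 - f)^j
      final <- j == mi[idx]
      # path consumed at the start/end of each step
      Rj <- ifelse(Ej > cutoff, csda_range(pmin(Ej, tabmax)), 0)
      Enext <- Ej * (1 - f)
      Rnext <- ifelse(final | Enext <= cutoff, 0, csda_range(Enext))
      s0 <- det * (R0[ii][idx] - Rj)
      s1 <- ifelse(final, s0, det * (R0[ii][idx] - Rnext))
      dep <- ifelse(final, Ej, Ej * f)
      tp <- tplus[ii][idx]
      # fraction of the segment [s0, s1] inside the sphere
      len <- s1 - s0
      frac <- ifelse(len > 0,
                     pmin(pmax((pmin(s1, tp) - s0) / len, 0), 1),
                     as.numeric(s0 <= tp))
      di <- dep * frac
      inside[act[ii]] <- inside[act[ii]] +
        as.numeric(rowsum(di, idx, reorder = TRUE))
    }
  }
  list(inside = inside, outside = particles$energy_MeV - inside,
       end_x = end_x, end_y = end_y, end_z = end_z)
}

#' Transport photons
#'
#' Characteristic X-rays (0.5--10 keV) interact at an exponentially sampled
#' depth with the table attenuation length: if the sampled depth exceeds the
#' chord to the sphere surface the photon escapes with all its energy,
#' otherwise all energy deposits at the interaction point (the photoelectron
#' range is negligible against the sphere radii where X-rays matter).
#' Photons flagged `escape_only` (511 keV annihilation quanta, mean free
#' path ~10 cm) always escape.
#'
#' @param particles Data frame with columns `energy_MeV`, `x`, `y`, `z`,
#'   `ux`, `uy`, `uz`.
#' @param world A `sphere_world`.
#' @param escape_only Logical vector (recycled) flagging photons that never
#'   interact.
#' @return List: `inside`, `outside` per-photon energies (MeV).
#' @export
transport_photons <- function(particles, world, escape_only = FALSE) {
  np <- nrow(particles)
  if (np == 0L) return(list(inside = numeric(0), outside = numeric(0)))
  esc <- rep_len(escape_only, np)
  inside <- numeric(np)
  act <- which(!esc)
  if (length(act)) {
    lambda <- attenuation_length(particles$energy_MeV[act] * 1e3)
    d <- stats::rexp(length(act)) * lambda
    tp <- chord_to_surface(particles$x[act], particles$y[act],
                           particles$z[act], particles$ux[act],
                           particles$uy[act], particles$uz[act],
                           world$radius_cm)
    inside[act] <- ifelse(d <= tp, particles$energy_MeV[act], 0)
  }
  list(inside = inside, outside = particles$energy_MeV - inside)
}

#' Simulate decays in one sphere and tally dose per decay
#'
#' Samples `n_decays` decays uniformly in the sphere, transports the emitted
#' particles and accumulates per-component energy inside/escaped and absorbed
#' dose per decay. Components follow the emission origin: `beta` (beta-minus
#' plus beta-plus), `auger`, `xray`; annihilation photons from positron track
#' ends are tallied as an escape-only `annihilation` component.
#'
#' @param world A `sphere_world` (or volume in uL).
#' @param scheme A `decay_scheme`.
#' @param config A `transport_config`; its `seed` is set before sampling.
#' @return Object of class `dose_tally`: data frame with one row per
#'   component plus `total`, columns `component`, `energy_inside_MeV`,
#'   `energy_escaped_MeV`, `dose_per_decay_Gy` (contained energy per decay
#'   over the fixed 1 uL reference mass of the 1 Bq/uL activity convention,
#'   the normalisation under which dose grows with volume and saturates),
#'   `dose_sphere_Gy` (over the sphere's own mass), `mc_error_Gy` (for the
#'   reference-mass dose); attributes `volume_uL`, `radius_cm`, `n_decays`,
#'   `seed`, `config`.
#' @export
simulate_sphere <- function(world, scheme = cu64_decay_scheme(),
                            config = transport_config()) {
  if (is.numeric(world)) world <- sphere_world(world)
  set.seed(config$seed)
  n <- config$n_decays
  pos <- place_source(world, n)
  ev <- sample_decay(scheme, pos, n)
  p <- ev$particles
  comp_of <- c(beta_minus = "beta", beta_plus = "beta",
               auger = "auger", xray = "xray")
  p$component <- comp_of[p$origin]
  p <- p[p$component %in% config$components, , drop = FALSE]

  comps <- c("beta", "auger", "xray", "annihilation")
  e_in <- stats::setNames(numeric(4), comps)
  e_out <- stats::setNames(numeric(4), comps)
  per_decay_in <- numeric(n)
  per_comp_sq <- stats::setNames(numeric(4), comps)
  per_comp_decay <- matrix(0, n, 2,
                           dimnames = list(NULL, c("beta", "auger")))

  el <- p[p$species %in% c("electron", "positron"), , drop = FALSE]
  if (nrow(el)) {
    tr <- transport_electrons(el, world, config)
    for (cc in c("beta", "auger")) {
      sel <- el$component == cc
      e_in[cc] <- sum(tr$inside[sel])
      e_out[cc] <- sum(tr$outside[sel])
      if (any(sel)) {
        agg <- rowsum(tr$inside[sel], el$event[sel])
        per_comp_decay[as.integer(rownames(agg)), cc] <- agg
      }
    }
    per_decay_in <- per_comp_decay[, "beta"] + per_comp_decay[, "auger"]
    # annihilation photons at positron track ends (escape-only)
    npos <- sum(el$species == "positron")
    e_out["annihilation"] <- npos * 2 * 0.511
  }
  xr_decay <- numeric(n)
  ph <- p[p$species == "photon", , drop = FALSE]
  if (nrow(ph)) {
    trp <- transport_photons(ph, world)
    e_in["xray"] <- sum(trp$inside)
    e_out["xray"] <- sum(trp$outside)
    agg <- rowsum(trp$inside, ph$event)
    xr_decay[as.integer(rownames(agg))] <- agg
    per_decay_in <- per_decay_in + xr_decay
  }

  # Dose normalization: `dose_per_decay_Gy` divides the contained energy by a
  # fixed 1 uL reference mass -- the dose rate to the medium per unit activity
  # concentration (1 Bq/uL), the convention under which dose per decay grows
  # monotonically with volume and saturates once all ranges are contained.
  # `dose_sphere_Gy` divides by the sphere's own mass (dose to the source
  # sphere itself).
  to_gy <- MEV_TO_J / REFERENCE_MASS_KG
  dose <- e_in * to_gy / n
  se_of <- function(v) stats::sd(v) / sqrt(n) * to_gy
  mc <- c(beta = se_of(per_comp_decay[, "beta"]),
          auger = se_of(per_comp_decay[, "auger"]),
          xray = se_of(xr_decay),
          annihilation = 0)
  tally <- data.frame(
    component = c(comps, "total"),
    energy_inside_MeV = c(e_in, sum(e_in)),
    energy_escaped_MeV = c(e_out, sum(e_out)),
    dose_per_decay_Gy = c(dose, sum(dose)),
    dose_sphere_Gy = c(e_in, sum(e_in)) * MEV_TO_J / world$mass_kg / n,
    mc_error_Gy = c(mc, se_of(per_decay_in)),
    row.names = NULL
  )
  structure(tally, class = c("dose_tally", "data.frame"),
            volume_uL = world$volume_uL, radius_cm = world$radius_cm,
            n_decays = n, seed = config$seed, config = config)
}

#' @export
print.dose_tally <- function(x, ...) {
  cat(sprintf("Dose tally: %.3g uL sphere (radius %.3g cm), %d decays, seed %d\n",
              attr(x, "volume_uL"), attr(x, "radius_cm"),
              attr(x, "n_decays"), attr(x, "seed")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# deterministic per-volume sub-seed from the master seed (documented scheme)
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 7919 * i) %% 2147483647)
}

#' Sweep absorbed dose per decay over sphere volumes
#'
#' Runs `simulate_sphere` at each volume with an independent RNG stream
#' derived from the master seed (`seed + 7919 * index`, mod 2^31 - 1).
#'
#' @param volumes_uL Vector of sphere volumes, uL.
#' @param scheme A `decay_scheme`.
#' @param config A `transport_config` (its seed acts as the master seed).
#' @return Object of class `dose_sweep`: list of `dose_tally` with a
#'   `summary` data frame (one row per volume x component).
#' @export
run_volume_sweep <- function(volumes_uL, scheme = cu64_decay_scheme(),
                             config = transport_config()) {
  tallies <- vector("list", length(volumes_uL))
  for (i in seq_along(volumes_uL)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    tallies[[i]] <- simulate_sphere(sphere_world(volumes_uL[i]), scheme, cfg)
  }
  structure(list(tallies = tallies, volumes_uL = volumes_uL,
                 master_seed = config$seed),
            class = "dose_sweep")
}

#' @export
as.data.frame.dose_sweep <- function(x, ...) {
  do.call(rbind, lapply(x$tallies, function(t) {
    cbind(volume_uL = attr(t, "volume_uL"), radius_cm = attr(t, "radius_cm"),
          as.data.frame(t), n_decays = attr(t, "n_decays"))
  }))
}

#' @export
print.dose_sweep <- function(x, ...) {
  cat(sprintf("Volume sweep over %d spheres (master seed %d)\n",
              length(x$tallies), x$master_seed))
  d <- as.data.frame(x)
  print(d[d$component == "total",
          c("volume_uL", "radius_cm", "dose_per_decay_Gy", "mc_error_Gy")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dose_sweep <- function(x, components = c("total", "beta", "auger"), ...) {
  d <- as.data.frame(x)
  d <- d[d$component %in% components & d$dose_per_decay_Gy > 0, ]
  plot(NA, xlim = range(d$volume_uL), ylim = range(d$dose_per_decay_Gy),
       log = "xy", xlab = "sphere volume (uL)",
       ylab = "absorbed dose per decay (Gy)", ...)
  for (i in seq_along(components)) {
    di <- d[d$component == components[i], ]
    graphics::lines(di$volume_uL, di$dose_per_decay_Gy, type = "b",
                    pch = i, col = i)
  }
  graphics::legend("topleft", legend = components, pch = seq_along(components),
                   col = seq_along(components), bty = "n")
  invisible(x)
}

#' Ratio of two component doses in a tally
#'
#' @param tally A `dose_tally`.
#' @param a,b Component names (`beta`, `auger`, `xray`, `total`).
#' @return Named numeric: `ratio` = dose(a)/dose(b) and `se`, the
#'   first-order propagated Monte Carlo error (components treated as
#'   independent).
#' @export
component_ratio <- function(tally, a, b) {
  da <- tally$dose_per_decay_Gy[tally$component == a]
  db <- tally$dose_per_decay_Gy[tally$component == b]
  if (!length(da) || !length(db))
    stop("component_ratio: unknown component")
  if (db == 0) stop("component_ratio: zero denominator dose")
  if (a == b) return(c(ratio = 1, se = 0))
  sa <- tally$mc_error_Gy[tally$component == a]
  sb <- tally$mc_error_Gy[tally$component == b]
  r <- da / db
  c(ratio = r, se = abs(r) * sqrt((sa / da)^2 + (sb / db)^2))
}

#' Deposition points along a single electron track
#'
#' Convenience helper for trajectory-style plots: returns the condensed-step
#' deposition positions and energies of one electron.
#'
#' @param energy_MeV Initial kinetic energy.
#' @param position Length-3 origin, cm.
#' @param direction Length-3 unit direction.
#' @param config A `transport_config`.
#' @return Data frame `s_cm`, `x`, `y`, `z`, `deposit_MeV`.
#' @export
electron_track <- function(energy_MeV, position = c(0, 0, 0),
                           direction = c(0, 0, 1),
                           config = transport_config()) {
  f <- config$step_fraction
  cutoff <- config$electron_cutoff
  if (energy_MeV <= cutoff)
    return(data.frame(s_cm = 0, x = position[1], y = position[2],
                      z = position[3], deposit_MeV = energy_MeV))
  m <- max(ceiling(log(cutoff / energy_MeV) / log1p(-f)), 1L)
  Ej <- energy_MeV * (1 - f)^(0:m)
  R0 <- csda_range(energy_MeV)
  Rj <- ifelse(Ej > cutoff, csda_range(Ej), 0)
  s <- config$detour_factor * (R0 - Rj)
  smid <- c((s[-(m + 1L)] + s[-1L]) / 2, s[m + 1L])
  dep <- c(Ej[-(m + 1L)] * f, Ej[m + 1L])
  data.frame(s_cm = smid,
             x = position[1] + direction[1] * smid,
             y = position[2] + direction[2] * smid,
             z = position[3] + direction[3] * smid,
             deposit_MeV = dep)
}
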