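---
title: "Cu-64 cellular dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cu-64 cellular dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cudosim)
```

## The problem

Cu-64 is attractive for targeted radionuclide therapy because a single decay
scheme delivers three very different radiation qualities: beta particles
(beta-minus, endpoint 0.573 MeV, 40% of decays; positrons, endpoint
0.656 MeV, 19%), and — after electron capture (41%) — low-energy Auger
electrons and characteristic K X-rays of the nickel daughter. The CSDA range
of the endpoint beta is about 2.1 mm, six orders of magnitude longer than
the ~120 nm range of a 2 keV Auger electron, so the dose each component
delivers to a cell-sized water volume depends dramatically on the volume
itself. `cudosim` estimates the absorbed dose per decay for uniformly
distributed Cu-64 in water spheres from 1e-11 to 1e3 uL, reconstructs doses
from coumarin-3-carboxylic-acid (C3CA) chemical dosimetry, and converts
doses into D10/RBE biological-effectiveness estimates for CHO wild-type and
xrs5 cells.

## Physics data

Two plain-text tables under `inst/extdata/` carry all medium data.

**Electron stopping power (7.4 eV – 1 MeV).** Rows at and above 10 keV are
generated from the Berger–Seltzer collision stopping-power formula for water
(I = 75 eV, Z/A = 0.55509) plus an approximate radiative correction
(~Z(E+mc²)/800, about 1% at 0.5 MeV); they agree with standard evaluated
data to well under 5%. Below 10 keV no single published dataset
simultaneously matches the LET anchors the package is built around
(7 keV/um at 2 keV, 26 keV/um at 150 eV) *and* a 120 nm CSDA range at
2 keV — an ESTAR-like physical table integrates to roughly 180 nm. The
packaged low-energy rows are therefore package-owned values: they follow a
track-structure-like shape, reproduce both LET anchors within a few
percent, and are adjusted between the anchor energies (where no published
constraint applies here) so the reciprocal-stopping-power integral gives
~120 nm at 2 keV. The header of the data file says exactly this.

**Photon mass attenuation (0.5 – 10 keV).** Standard evaluated mu/rho values
for liquid water at 1–10 keV, power-law extension below 1 keV (marked
approximate; nothing in the analysis depends on sub-keV photons). Log-log
interpolation gives an attenuation length of ~795 um at 7.5 keV, the mean
K X-ray energy.

CSDA ranges are the trapezoid integral of 1/S(E) on a 6000-node log-energy
grid from the 7.4 eV cutoff; doubling the node count changes the 0.573 MeV
range by well under 1%.

## Decay model

Channel choice is categorical over (0.40, 0.19, 0.41). Beta energies are
sampled by rejection from the allowed-transition shape
p·W·(Q−E)²·F(Z, W) with the nonrelativistic Coulomb factor
F = 2πη/(1−e^(−2πη)), η = ±ZαW/p — enhancement at low energy for
electrons (daughter Z = 30), suppression to zero for positrons
(daughter Z = 28).

Electron capture relaxes through a two-factor model: a K vacancy exists with
probability 0.88 per capture and relaxes by fluorescence with the nickel
K yield 0.41, otherwise by Auger emission. These two defaults were chosen
(and are overridable) so that the per-decay Auger-emission probability
0.41 × 0.88 × 0.59 ≈ 0.213 matches the ~22% published for Cu-64, and the
per-decay K X-ray fraction ≈ 0.148 sits close to the published line-fraction
sum (~0.159). The printed per-line fractions are not exactly consistent with
any (vacancy × yield) factorization; the model's analytic kα1 fraction
(0.0875/decay) is within ~7% of the printed 9.4% and the tests assert both
the convergence to the analytic value and that proximity. The weak l line
(0.85 keV, 0.5%/decay) is emitted as an independent outer-shell
fluorescence so its per-decay fraction is exact.

**Auger spectrum and multiplicity.** The published account constrains the
mean Auger energy (~2 keV) and the emission fraction (22%), not the line
set. The default spectrum is six discrete lines from 0.12 to 6.83 keV with
weighted mean 1.96 keV, sampled one electron per Auger relaxation.
Multiplicity 1 is a deliberate design choice: with the 2 keV per-electron
mean fixed, only the low end of cascade multiplicity reproduces the
published containment picture — Auger dose comparable to beta dose in a
1 um-radius sphere (the simulation gives a ratio ≈ 1.4) and beta dose more
than twice the Auger dose at the 15 um cell size (ratio ≈ 6). Two or more
2 keV electrons per cascade would push the 1 um ratio well above 2. A
configured spectrum with more, softer lines is equally valid as long as its
mean stays in the 1.5–2.5 keV band the scheme validator enforces.

Neutrinos and the 0.5%/decay 1.346 MeV gamma are omitted (negligible local
deposition); annihilation quanta are produced at positron track ends but
flagged escape-only, since their ~10 cm mean free path dwarfs every
simulated sphere.

## Transport and scoring

Electrons follow straight condensed-history tracks: per step the particle
loses a fixed fraction (default 5%) of its current energy over the
corresponding CSDA path difference, scaled by a detour factor (default 1.0,
i.e. straight full-length tracks; 0.8 mimics multiple-scattering
shortening). Each step's energy loss is split between inside and outside of
the sphere by the exact overlap of the step segment with the chord from the
emission point to the surface, so energy is conserved to machine precision
and the inside/outside split has no step-quantization bias. Below the
7.4 eV cutoff the remaining energy deposits locally. Delta rays are not
produced (continuous loss along the primary track); at the smallest volumes
this slightly over-assigns energy to the source sphere because real
secondaries could leave it.

Photons sample an exponential interaction depth with the table attenuation
length and either escape (depth beyond the chord) or deposit all their
energy at the interaction point — the photoelectron range is far below the
sphere radii at which X-rays contribute at all.

**Dose normalization.** The tally reports two quantities. `dose_sphere_Gy`
divides the contained energy by the sphere's own mass — the literal dose to
the source volume, which *decreases* with volume once containment
saturates. `dose_per_decay_Gy`, the quantity used throughout the analysis,
divides the contained energy per decay by the fixed 1 uL reference mass of
the 1 Bq/uL activity convention; it is proportional to the contained energy
and therefore grows monotonically with volume and saturates, which is the
behaviour (and, to within ~20%, the magnitude) of the published
dose-per-decay curve: the package computes ≈1.7e-8 Gy/decay at 30 uL
against the published 1.6e-8, and ≈4.5e-10 at the 1.4e-5 uL cell volume
against the published 7.7e-10. Only ratios, shapes and limits are treated
as reproducible; the absolute axis is a convention.

**Full-absorption limit.** Where every range is far below the radius, the
beta+Auger dose must equal the analytic mean emitted charged-particle
energy (≈0.130 MeV/decay) over the reference mass. The test asserts this
within 3 Monte Carlo sigma at 1e5 uL (radius ≈ 2.9 cm, ≈14 endpoint
ranges). At the 1e3 uL sweep bound the radius is only three endpoint
ranges, and a genuine ~7% escape tail remains with straight tracks; the
suite pins that tail below 10% rather than pretending the limit is reached
there.

**Problem sizes.** The headline simulations use 1e5 decays per volume point
(the study's own count) — about 10 s per volume point in pure R thanks to
the flattened vectorized stepping; shape and invariant sweeps in the test
suite use 2e4–4e3 decays per point, which keeps every Monte Carlo
assertion at 3-sigma power while the whole suite runs in about a minute.
Emission-statistics checks use 1e6 sampled decays.

## Chemical dosimetry

The C3CA chain is linear algebra with published constants: 4.7 ± 0.6% of OH
radicals convert to fluorescent 7OH-C3CA independent of radiation quality,
and the Co-60 gamma G-value 2.7/100 eV converts an OH amount into a
Co-60-equivalent dose. Calibration and volume-series fits are ordinary
least squares; the "linear portion below 30 uL" is implemented as an
inclusive x ≤ 30 bound (overridable). The copper-chloride correction
factor (default 2.6) is the buffer/copper-chloride slope ratio of the
gamma calibration; it subsumes pH and chlorine-scavenging effects as a
single empirical multiplier — no competition-kinetics model — and a guard
attribute makes double application an error. All uncertainty propagation is
first-order (delta method). Per-decay normalization uses constant-activity
counts N = A·t (0.2 MBq per added uL, 24 h, with the added volume 10% of
the final volume); an exponential decay correction is available but off by
default.

## D10 and RBE

D10 comes either from log-linear interpolation of log-survival or from a
linear-quadratic fit `log SF = −αD − βD²` (default when a curve has ≥ 4
points), solved with the numerically stable root
`2 ln10 / (α + sqrt(α² + 4β ln10))` so the β → 0 limit reduces exactly to
ln10/α. RBE is the gamma-to-test D10 ratio; full precision internally,
half-up rounding to 2 decimals only at serialization. The packaged
reference table carries the published D10 columns for CHO wild-type and
xrs5 cells; its Cu-64 rows also carry the *reported* RBEs (2.53, 1.12),
which differ from the gamma/test ratios computable from the same column
(2.86, 1.28) for reasons the source does not state — both are exposed,
neither is silently preferred. The published absolute D10s for Cu-64
(2.23, 0.92 Gy) are likewise not re-derivable from activity × duration ×
dose-per-decay (only their ratio, 2.23/0.92 ≈ 0.97/0.40, is consistent),
so they are treated as reported constants.

## Synthetic data

The generators emulate the *structure* of the measurements, never digitized
figure values: two gamma-calibration lines whose slope ratio defaults to
2.6, a Cu-64 volume series driven by any dose-per-decay model (typically
the transport sweep) pushed backwards through the chemistry chain with
multiplicative Gaussian noise (CV 5% default — a typical
HPLC-fluorescence repeatability), and LQ survival curves with lognormal
noise clipped to (0, 1]. Every dataset embeds its generating truth as an
attribute, and recovery tests compare estimates against that truth. What
passing tests show is that the analysis chain is unbiased and correctly
propagates uncertainty under its own noise model; they cannot show that
real HPLC drift, volume-dependent geometry effects in PCR tubes, or
clonogenic plating variability are captured — none of those are modelled.

## Known limitations

* Straight-track condensed history with continuous energy loss: no elastic
  scattering, no delta rays, no track-end straggling. Containment-versus-
  volume behaviour is governed by range/radius ratios, which this captures;
  event-level agreement with discrete track-structure codes is out of
  scope.
* The low-energy stopping rows are anchor-calibrated, not a published
  evaluation; below ~100 eV they are little more than a smooth
  interpolation to a plausible cutoff value.
* Photons outside 0.5–10 keV are handled only by the escape-only flag.
* The chemical chain absorbs all copper-chloride chemistry into one
  multiplicative factor; no radical kinetics.
* Water only, unit density, spheres only.
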