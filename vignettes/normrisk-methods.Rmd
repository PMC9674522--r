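---
title: "Methods: radiological risk assessment for NORM surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiological risk assessment for NORM surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normrisk)
library(dplyr)
```

# The problem

Mining redistributes subsurface material enriched in the primordial
radionuclides K-40, U-238 and Th-232. People living around a mine are
exposed externally, through gamma radiation from soil, and internally,
through drinking water and food crops that take the nuclides up from the
rooting zone. `normrisk` implements the standard assessment chain for such
a survey: gamma-spectrometric activity concentrations, UNSCEAR-style dose
and risk indices, soil-to-plant transfer factors, and a probabilistic
(Monte Carlo) treatment of the excess lifetime cancer risk. The packaged
reference profiles describe two surveyed mining fields in Kwara, Nigeria
(a beryllium mine and a gold mine), with n = 24 soil and grain samples and
n = 12 water samples per site.

# Spectrometry

A NaI(Tl) multichannel spectrum is calibrated with point sources through an
ordinary least-squares line `energy = slope * channel + intercept`
(`fit_energy_calibration()`); NaI systems are linear over the terrestrial
range, and the packaged three-source calibration predicts the 1173 keV
Co-60 line to within 1 keV.

The full-energy peak efficiency is
$\varepsilon = C_{net} / (A\,P_\gamma\,T)$ and the activity concentration
of a sample of mass $M_s$ is

$$A = \frac{C_{net}}{\gamma\,\varepsilon(E_\gamma)\,T\,M_s}.$$

Two conventions deserve note. First, $C_{net}$ is *net counts* (gross minus
background), not a count rate: dividing by the live time $T$ once is what
produces becquerels, and treating it as a rate would double-count $T$.
Second, water aliquots are reported per litre by passing the aliquot
volume (0.5 L by default in the survey protocol) in place of the mass, with
the unit tag carried through the tables.

U-238 and Th-232 are quantified under secular equilibrium through progeny
lines (Pb-214 295.2/351.9 keV, Bi-214 609.3/1764.5 keV; Ac-228 911.2 keV,
Tl-208 2614.7 keV). Multi-line activities are combined as an unweighted
mean by default; an inverse-variance weighted mean (Poisson counting
variances) is available via `nuclide_activities(method =
"inverse_variance")`. Negative net counts after background subtraction are
clamped at zero with a warning. The detection limit uses the Currie
formula $MDA = (2.71 + 4.65\sqrt{B}) / (\gamma \varepsilon T M_s)$ — an
explicit modelling choice, since counting protocols rarely publish their
exact MDA convention.

# Hazard indices

For soil with mean activities $C_K, C_U, C_{Th}$ (Bq/kg):

* absorbed dose rate in air at 1 m,
  $D = 0.0417\,C_K + 0.462\,C_U + 0.623\,C_{Th}$ nGy/h;
* external annual effective dose,
  $AED = D \times 8760\,\mathrm{h} \times 0.7\,\mathrm{Sv/Gy} \times 0.2
  \times 10^{-6}$ mSv/y (0.2 outdoor occupancy; exactly
  $1.2264\times10^{-3}$ mSv/y per nGy/h at the defaults);
* representative level index,
  $RLI = C_U/150 + C_{Th}/100 + C_K/1500$, flagged when above 1;
* for ingestion, $AED = 365\sum_i I_i D_i$ with daily intakes $I_i$ from
  2 L/d of water or 24.8 kg/y of guinea corn, and dose coefficients
  $6.2\times10^{-9}$, $4.5\times10^{-8}$, $2.3\times10^{-7}$ Sv/Bq for
  K-40, U-238 and the Th-232 chain;
* excess lifetime cancer risk, $ELCR = AED \times DL \times RF$ with a
  70-year lifetime and the ICRP stochastic risk factor 0.05/Sv.

All indices are linear and homogeneous of degree one in the activity
vector, so the index of a site mean equals the mean of per-sample indices;
the tests exploit this as an invariant. ELCR is stored as a pure
probability and rendered in the conventional $\times 10^{-3}$ units in
reports. Only outdoor external exposure is evaluated (the surveys under
study report no indoor scenario); the indoor ELCR benchmark is retained in
`reference_limits()` for context. Every constant is overridable — e.g. the
water intake, because published water rows in this genre of survey are
sometimes only consistent with 1 L/d rather than the stated 2 L/d, and both
scenarios should be reproducible.

```{r hazard-example}
site_means() |>
  filter(medium == "soil", basis == "in_situ") |>
  rli() |>
  aed_external() |>
  elcr() |>
  select(site, rli, aed_external_mSv_y, elcr_external)
```

# Transfer factors

$TF = C_{plant}/C_{soil}$ on a dry-weight basis, computed by default from
site *mean* activities (the convention of survey reports), with a paired
per-sample mode for matched rooting-zone sampling. TF below 1 is
classified "absorbed", above 1 "accumulated", and each value is reported
next to the IAEA cereal-grain references (K 0.74, U 0.0062, Th 0.0021).
TF is scale-invariant and reciprocal ($TF_{p/s} \times TF_{s/p} = 1$),
which the property tests check. A zero soil activity leaves that nuclide's
TF undefined (`NA` with a warning) rather than infinite.

# Descriptive statistics

`site_summary()` reports min, max, mean, sample SD (n−1), CV in percent,
adjusted Fisher–Pearson skewness and *excess* kurtosis — the conventions
that make published survey tables (kurtosis values near zero or negative)
internally consistent. The estimators are configurable through the
underlying e1071 types; n below 3 (skewness) or 4 (kurtosis) yields `NA`,
and a zero mean leaves the CV undefined.

# Monte Carlo cancer risk

A point estimate of ELCR hides the spread of the inputs, so `run_mcs()`
propagates distributions through the deterministic chain (activities →
dose rate → AED → ELCR for soil; activities → intake → AED → ELCR for
water/grain), with 10 000 trials by default and linear-interpolation
P5/mean/P95 summaries (the percentile convention is stated because
commercial risk packages do not document theirs).

Default input model: activity concentrations are normal, truncated to
remain non-negative, at the observed site mean/SD; exposure factors
(occupancy, lifetime, risk factor, intake) are point values, optionally
triangular at ±10% of nominal to emulate their intrinsic uncertainty. The
*symmetric* truncated normal (`dist_truncnorm_symmetric()`) truncates at
`mean ± min(mean, 3·sd)`: bounds symmetric about the mean preserve the
expectation exactly, so with symmetric inputs the Monte Carlo mean
converges on the deterministic ELCR — the consistency check the test
suite enforces within three Monte Carlo standard errors. Plain
zero-truncation is also available, but at the coefficients of variation
seen in these surveys (up to ~85%) it shifts the mean upward by several
percent, which is a modelling statement rather than a numerical error, and
is therefore opt-in. All randomness flows through a single seeded
generator; the seed is recorded in every result, and identical
configuration plus seed reproduces results bit-for-bit.

# Synthetic data

The generator exists so every stage is testable without field data.

**Site activities** (`generate_site()`): each nuclide is drawn from a
skew-normal matched to the profile's mean, SD and skewness (closed-form
moment inversion, with the skewness capped inside the family's attainable
range of about ±0.995), truncated at zero, and then *re-matched*: location
and scale are numerically adjusted so the truncated distribution itself
hits the target mean/SD. Draws use stratified uniforms through a numeric
quantile map (Latin-hypercube style), so sample moments track the targets
closely even at n = 12–24; across the packaged profiles the realised means
sit within a few percent of target. A lognormal family is available as an
alternative.

The published summary rows for the laboratory-measured media are
internally impossible as strict distributions — their printed SDs exceed
the largest SD any distribution confined to the printed min–max range can
attain (the half-range), and one row's mean equals its maximum. The
generator therefore treats the printed range endpoints as descriptive
targets rather than truncation bounds (`bounds = "physical"`, truncation
at zero only). `bounds = "strict"` truncates to `[min, max]` after a
feasibility check (mean inside the range, SD at most the half-range) and
aborts with a diagnostic otherwise. Similarly, where a strongly *negative*
printed skew collides with the zero bound, matching mean and SD takes
precedence and the realised skew may flip sign; the sign is reproduced
where the truncation leaves it attainable.

**Spectra** (`generate_spectrum()`): 1024 channels under the packaged
calibration; Gaussian photopeaks at the indicator lines with FWHM 7% of
662 keV scaling as $\sqrt{E}$; expected net areas
$A\,\gamma\,\varepsilon\,T\,M_s$ with a power-law efficiency model
anchored at 5% at 662 keV; a smooth exponential continuum; independent
Poisson noise per channel; and a paired continuum-only background spectrum
at the same 18 000 s live time, mirroring the empty-container protocol.
What the simulator deliberately omits: escape and summing peaks,
self-absorption, decay-chain disequilibrium, and channel-to-channel gain
drift. Passing round-trip tests therefore demonstrate the correctness of
the reduction arithmetic and its statistical calibration, not robustness
to real detector pathology.

**Reduction** (`reduce_spectrum()`) integrates sample and background
counts in ±1.5σ windows around each line and divides by the Gaussian
coverage. The window width is a bias/variance compromise fixed a priori:
at ±2σ the 295/352 keV Pb-214 doublet leaks ~3% of each peak into its
neighbour's window, while at ±1.5σ the cross-talk falls below ~1%, small
against the Poisson standard error at realistic peak areas. Recovered
activities land within three Poisson standard errors of truth in ≥95% of
seeded trials (99% typical).

# Problem sizes and numerical choices

The test suite and the acceptance script use the survey's own scale: 200
synthetic spectra of 1024 channels for the round trip, full 24/12-sample
site generations, 10 000 Monte Carlo trials, 20 replicates for the
end-to-end pipeline identity (generated sites reproduce the profile-mean
hazard indices within 15%). The skew-normal re-match runs a Nelder–Mead
optimisation over location and log-scale on a 2001-point grid; quantiles
interpolate the gridded CDF. Degenerate inputs are defined, not special
cased ad hoc: zero SD or `min == max` produce constant samples, a
zero-activity truth produces a background-only spectrum, and a
single-trial simulation returns a one-draw summary.

# Known limitations

* Nuclide activities are generated independently; real sites correlate
  them through shared mineralogy, so simulated index spreads are, if
  anything, slightly narrow.
* No radium-equivalent activity or H_ex/H_in indices; the assessed
  surveys do not use them.
* The spectrometry module reduces spectra at known line positions; it is
  not a general peak-search tool.
* Soil-chemistry covariates of transfer (pH, texture, solubility) are out
  of scope; TF is a ratio, not a mechanistic uptake model.
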