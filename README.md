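# normrisk

Radiological risk assessment for NORM (naturally occurring radioactive
material) surveys: from gamma-spectrometric activity concentrations of
K-40, U-238 and Th-232 in soil, water and food crops to dose and cancer
risk indices, soil-to-plant transfer factors, and probabilistic risk via
Monte Carlo simulation.

The package is aimed at environmental health physicists assessing sites —
mining fields, processing plants, agricultural land — where primordial
radionuclides may be enhanced. It ships reference activity profiles for
two surveyed mining fields in Kwara, Nigeria (beryllium and gold mining),
and a synthetic-data generator (site sample sets and NaI(Tl) spectra) so
the whole pipeline runs and is tested without any external data.

## The models

For soil activities $C_K, C_U, C_{Th}$ (Bq/kg):

* **Absorbed dose rate in air** (1 m above ground):
  $D = 0.0417\,C_K + 0.462\,C_U + 0.623\,C_{Th}$ (nGy/h)
* **External annual effective dose**:
  $AED = D \times 8760 \times 0.7 \times 0.2 \times 10^{-6}$ (mSv/y)
* **Representative level index**:
  $RLI = C_U/150 + C_{Th}/100 + C_K/1500$ (unity ≈ 1 mSv/y)
* **Ingestion dose** from water (2 L/d) or grain (24.8 kg/y):
  $AED = 365 \sum_i I_i D_i$ with ICRP dose coefficients
* **Excess lifetime cancer risk**: $ELCR = AED \times DL \times RF$
  (70-y lifetime, risk factor 0.05/Sv), reported in units of $10^{-3}$
* **Transfer factor**: $TF = C_{grain}/C_{soil}$ (dry weight), classified
  against the IAEA cereal references
* **Monte Carlo ELCR**: input distributions propagated through the chain
  (10 000 trials), summarised as P5 / mean / P95

Activity concentrations themselves come from
$A = C_{net} / (\gamma\,\varepsilon\,T\,M_s)$ with a least-squares energy
calibration and Currie detection limits.

## Worked example

```r
library(normrisk)
library(dplyr)

# deterministic indices from the packaged site mean activities
site_means() |>
  filter(medium == "soil") |>
  rli() |> aed_external() |> elcr() |>
  mutate(elcr_x1e3 = 1e3 * elcr_external) |>
  select(site, basis, dose_rate_nGy_h, aed_external_mSv_y, rli, elcr_x1e3)
#>   site      basis   dose_rate_nGy_h aed_external_mSv_y   rli elcr_x1e3
#> 1 Beryllium in_situ            39.2             0.0481 0.614     0.168
#> 2 Gold      in_situ            75.5             0.0926 1.18      0.324
#> 3 Beryllium lab                37.5             0.0460 0.592     0.161
#> 4 Gold      lab                29.8             0.0366 0.469     0.128
```

Only the gold site's in-situ measurements push the screening index above
unity (RLI 1.18) — outdoor external doses there exceed the 1 mSv/y
benchmark while every laboratory-based row stays below it.

```r
transfer_factors(site_means()) |> select(site, nuclide, tf, classification)
#>   site      nuclide    tf classification
#> 1 Beryllium K40     0.208 absorbed
#> 2 Beryllium U238    0.171 absorbed
#> 3 Beryllium Th232   0.314 absorbed
#> 4 Gold      K40     0.484 absorbed
#> 5 Gold      U238    0.187 absorbed
#> 6 Gold      Th232   0.284 absorbed
```

All transfer factors sit below 1 (absorption without accumulation), below
the IAEA cereal reference for K-40 (0.74) but far above the U-238/Th-232
references (0.0062 / 0.0021).

```r
cfg <- mcs_config(
  activities = list(
    K40  = dist_truncnorm_symmetric(29.86, 5.29),
    U238 = dist_truncnorm_symmetric(1.00, 0.19),
    Th232 = dist_truncnorm_symmetric(1.30, 0.23)
  ),
  n_trials = 10000, seed = 1
)
run_mcs(cfg, "ingestion_water")
#> Monte Carlo ELCR (ingestion_water, 10000 trials, seed 1)
#>   P5    0.00109
#>   mean  0.00135
#>   P95   0.001613
#>   deterministic 0.001352
```

The simulated mean risk from gold-site drinking water, 1.35 × 10⁻³, sits
below the 3.75 × 10⁻³ internal-exposure benchmark, with a 90% band of
(1.09–1.61) × 10⁻³. `tidy()`, `glance()` and `autoplot()` methods expose
every result as tibbles and ggplots, and `run_pipeline()` +
`write_report()` run all stages over a samples table and write
CSV/JSON report bundles.

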