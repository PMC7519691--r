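# dustspec

Estimating foliar dust retention from leaf hyperspectral reflectance.

Urban greening vegetation traps airborne particulate matter on its leaves,
and the deposited layer leaves a measurable fingerprint in the leaf's
reflectance spectrum: the bright near-infrared plateau darkens roughly in
proportion to dust coverage, the red-edge rise flattens, and narrow-band
indices shift monotonically with the deposited mass. `dustspec` is an R
package for analysts who turn laboratory deposition-series spectra
(350–2500 nm, one spectrum per leaf per dust increment, with weighed loads
in g m⁻²) into a calibrated prediction model of leaf dust load — and for
anyone who needs a fully reproducible synthetic test bed for that workflow.

## What it computes

From each spectrum `R(λ)` on a uniform 1 nm grid and its first derivative
`D(λ)` (forward differences by default):

| feature | definition |
|---|---|
| LWI | `R970 / R900` |
| REI | `Σ D(λ)·Δλ` over the red edge 680–750 nm (= `R750 − R680` exactly on the forward path) |
| NDI | `(R750 − R705) / (R750 + R705 + 2·R445)` |
| SRI | `R706 / R809` |
| PRI | `(R570 − R531) / (R570 + R531)` |
| REP, RES | position and value of `max D` over 680–750 nm |
| BEP, BES | position and value of `max D` over 490–530 nm |
| YEP, YES | position and value of the `D` extremum over 560–640 nm (minimum by default) |

These eleven features are screened against measured loads with per-band and
per-feature Pearson correlations, calibrated by univariate OLS
(`load = slope·x + intercept`), ranked by training R², and validated per
dust type on held-out samples (Pearson r, RMSE, and accuracy defined as
100 − MAPE on positive loads).

The package also ships a seeded simulator of dusted-leaf spectra: a
closed-form leaf endmember with the six canonical reflection maxima
(557, 780, 1000, 1282, 1660, 2215 nm), coal/cement/soil dust endmembers,
and an exponential-saturation deposition law
`f = 1 − exp(−k·load)`, `R_mix = (1−f)·R_leaf + f·R_dust`.

## Worked example

```r
library(dustspec)

cfg <- run_config(simulate = synthetic_config(seed = 20200925),
                  seed = 20200925)
res <- run_pipeline(cfg, "out/")
#> [dustspec] simulate: seed 20200925, 30 leaves
#> [dustspec] input: 210 samples x 2151 bands
#> [dustspec] features: 210 rows (0 with errors)
#> [dustspec] split: 120 train / 50 corr / 90 validation
#> [dustspec] correlate: 50 samples, 2151 bands
#> [dustspec] calibrate: best predictor REI (R2 = 0.8752)
#> [dustspec] validate: 3 dust types

head(models_table(res$models), 4)
#>   predictor  slope intercept     r2    rmse   n
#> 1       REI -2.578    1.0287 0.8752 0.03824 120
#> 2       NDI -2.831    1.0520 0.4838 0.07778 120
#> 3       SRI  1.738   -0.5866 0.2575 0.09329 120
#> 4       LWI  1.956   -1.5879 0.1310 0.10092 120
```

Reading: on this simulated deposition series the red edge index is the
strongest single predictor — one REI unit (a change of `R750 − R680`) maps
to −2.58 g m⁻² of dust, and the model explains 87.5 % of the training
variance with an RMSE of 0.038 g m⁻² over loads spanning 0–0.35 g m⁻².
The held-out validation (`res$validation`) reports r = 0.91–0.94 and
accuracies of 81–84 % per dust type. The report bundle written to `out/`
(`features.csv`, `correlations.csv`, `parameter_correlations.csv`,
`models.csv`, `validation.csv`, `best_model.txt`, `summary.txt`,
`config_echo.yaml`) is byte-identical on re-run with the same seed, and
`read_run_config("out/config_echo.yaml")` reproduces the run.

To analyse measured data instead, point the config at files:

```r
cfg <- run_config(spectra_path = "spectra.csv",  # wavelength_nm,<id1>,<id2>,...
                  dust_path = "dust.csv",        # sample_id,dust_type,dust_g_per_m2
                  seed = 1)
```

A thin command-line wrapper with `simulate` / `features` / `correlate` /
`calibrate` / `validate` / `run` subcommands is installed at
`inst/cli/dustspec.R`.

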