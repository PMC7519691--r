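---
title: "Methods: estimating foliar dust retention from leaf reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating foliar dust retention from leaf reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustspec)
```

## The problem

Particulate dust deposited on leaf surfaces changes how leaves reflect
light. In the near infrared (NIR), where healthy leaf tissue is bright and
mineral or combustion particles are dark, a dust layer darkens the spectrum
roughly in proportion to how much of the leaf it covers; around the red edge
(the steep reflectance rise between chlorophyll absorption and the NIR
plateau, ~680–750 nm) it flattens the rise and shrinks derivative features.
`dustspec` turns these effects into a calibration: scalar spectral features
are screened against measured dust loads (g m⁻²) and the best univariate
linear model is used to predict load from reflectance alone.

The intended measurement design is a laboratory deposition series: each leaf
is measured clean, then repeatedly dusted (coal, cement or soil dust),
weighed and re-measured, giving per-sample (spectrum, dust type, load)
triples on a 350–2500 nm field-spectrometer grid.

## Features

All features are computed from a spectrum $R(\lambda)$ on a uniform 1 nm
grid and its first-derivative spectrum $D(\lambda)$:

* **LWI** $= R_{970}/R_{900}$ — leaf water content index;
* **REI** $= \sum_{\lambda \in [680,750)} D(\lambda)\,\Delta\lambda$ — red
  edge index (amplitude of the red-edge rise);
* **NDI** $= (R_{750}-R_{705})/(R_{750}+R_{705}+2R_{445})$;
* **SRI** $= R_{706}/R_{809}$ — kept exactly as defined in the parameter
  table this package implements, although it is inverted relative to the
  common NIR/red simple ratio; nothing downstream depends on the
  orientation, only on monotonicity;
* **PRI** $= (R_{570}-R_{531})/(R_{570}+R_{531})$;
* trilateral parameters: red edge position/slope (REP, RES) = arg-max and
  max of $D$ over 680–750 nm; blue edge (BEP, BES) likewise over
  490–530 nm; yellow edge (YEP, YES) = the window *minimum* of $D$ over
  560–640 nm by default, since the yellow-edge derivative of green
  vegetation is negative. Two window conventions for the yellow edge
  circulate (560–640 nm with a maximum, 550–582 nm with a minimum); we use
  the 560–640 nm window with the minimum, and expose
  `yellow_edge_mode = "max"` for the alternative reading.

### Numerical conventions

* **Grid.** The canonical analysis grid is the integer 1 nm grid
  350–2500 nm; instrument-native sampling (~1.4 nm) is handled by linear
  interpolation at load time (`resample()`). This makes every band lookup
  such as $R_{970}$ unambiguous.
* **Derivative.** Forward differences attributed to the left node are the
  default. The reason is arithmetic, not cosmetic: with forward differences
  the REI node sum telescopes *exactly* to $R(750)-R(680)$, which gives the
  feature a closed-form meaning and the test suite a machine-precision
  oracle. Central differences are available for sensitivity analysis (REI is
  then the plain node sum over [680, 750]).
* **Smoothing** is off by default — the exact identities above must hold on
  the default path. When requested, Savitzky–Golay smoothing is used
  (endpoints handled by the asymmetric least-squares fits of the SG
  projection matrix, so constants and straight lines are reproduced
  exactly).
* **Ties** in any arg-extremum are broken toward the shortest wavelength,
  making edge positions deterministic.
* **Degenerate inputs.** Zero denominators in an index give `NA` for that
  index only; constant vectors give `NA` correlations; a constant target in
  OLS gives `r2 = NA` (SST = 0 is undefined, not perfect). Non-uniform
  grids are rejected by the derivative rather than silently regridded.

## Calibration and validation

Per-band and per-feature screening uses Pearson correlation with two-sided
t-distribution p-values; stars follow the universal convention (`**` for
p < 0.01, `*` for p < 0.05). No multiplicity correction is applied across
the ~2000 bands or 11 features — the screening is exploratory and the band
correlogram is flagged as such in its output file.

Calibration is univariate ordinary least squares, `load = slope · x +
intercept`, ranked by training $R^2$ (ties by smaller RMSE, then fixed
feature order). RMSE uses divisor $n$; $n$ is stored in every model file so
the $n-2$ convention is recomputable. Validation is always on held-out
samples, grouped by dust type, reporting the Pearson r between predicted and
measured loads, RMSE, and a prediction accuracy defined as
$100\,(1 - \mathrm{MAPE})$ over samples with positive measured load —
"prediction accuracy" has no universal definition, so the formula is fixed
here and zero-load samples are excluded and flagged.

The data split mirrors the laboratory design the package targets: 120
samples for model fitting, 50 of those for correlation screening, the
remainder for validation, drawn with a mandatory seed (`split_samples()`).

## The synthetic-data generator

Because measured deposition-series spectra are rarely shareable, the
simulator produces datasets with the statistical structure the analysis
assumes, and its defaults *are* the study conditions the package is tested
under.

* **Leaf endmember.** A closed-form curve: visible baseline (0.08) plus a
  Gaussian green peak at 557 nm, minus a chlorophyll well near 675 nm,
  joined to the NIR plateau (0.48) by a logistic rise centred at 715 nm
  (width 12 nm), minus Gaussian water bands (970, 1200, 1450, 1940 nm) and
  a smooth dry-matter depression shaping the SWIR maxima. The shape
  constants are set so the six local reflectance maxima fall within
  ±10 nm of 557, 780, 1000, 1282, 1660 and 2215 nm — the canonical peak
  positions of a green broadleaf — and the curve stays inside (0, 1).
  Parameters that would leave (0, 1) by more than 0.02 pre-clip are an
  error, not a silent clip.
* **Dust endmembers.** Smooth level + tilt spectra with optional absorption
  features. Coal is dark (0.08); cement (0.25) and soil (0.28) are brighter
  and carry a broad blue-green absorption, giving them the rising visible
  slope of mineral dusts. All three sit strictly below the default leaf
  across 760–1400 nm, which is what forces the NIR darkening law and the
  deposition-drop ordering coal > cement > soil. A reported visible-band
  brightness ordering with coal *above* the mineral dusts is physically
  surprising for dark combustion particles and is deliberately not built
  into the defaults; users can parameterise it if wanted.
* **Deposition.** Coverage $f = 1 - e^{-k\,\mathrm{load}}$ with $k = 1$
  m² g⁻¹, and linear area mixing $R_{mix} = (1-f)R_{leaf} + f R_{dust}$.
  This is the simplest law that is the identity at zero load, saturates at
  the dust endmember, and makes $R_{mix}$ strictly monotone in load
  wherever the dust is darker than the leaf. At the default load range
  (0.03–0.35 g m⁻²) coverage reaches ~30%.
* **Stochastic structure.** Leaf-to-leaf variability: unit-mean lognormal
  multipliers (CV 0.05) on the green peak, chlorophyll depth, water-depth
  scale and plateau contrast. Realized loads are jittered around the
  nominal six-step series per dust type (lognormal, CV 0.03) and recorded
  as truth. Noise is additive Gaussian (sd 0.005 absolute reflectance),
  independent across wavelengths, applied after mixing, floored at a small
  positive reflectance. Everything is drawn in a fixed order from one seed,
  so datasets are bitwise reproducible.
* **What it does not emulate.** Wavelength-correlated instrument noise,
  BRDF/geometry effects, particle-size optics, radiative-transfer leaf
  structure (PROSPECT-class), and fine spectral structure of real dusts
  (e.g. sharp carbonate features). Passing tests therefore demonstrate the
  *pipeline's* correctness and the qualitative response laws under a linear
  mixing world — not quantitative transfer to any particular instrument or
  species. In particular, which feature wins the model ranking depends on
  the mixing geometry: on the default simulation the red edge index is the
  strongest single predictor, whereas measured studies have reported the
  water-band ratio LWI on top; both orderings are consistent with the sign
  structure the simulator reproduces.

## What the default simulation provably reproduces

On the noiseless deterministic limit of the default configuration the test
suite verifies, per dust type: mean 760–1400 nm reflectance strictly
decreasing over the six load steps; red edge slope strictly decreasing and
red edge position non-increasing with load; and the sign pattern of the
feature–load correlations — LWI (+), SRI (+), PRI (+), REI (−), NDI (−).

## Problem sizes

The test suite and the acceptance script run at desk scale by design: the
default simulated dataset is 30 leaves × (1 clean + 6 load steps) = 210
spectra on the 2151-point grid; identity properties use 100–1000 randomized
replicates; the noisy slope-recovery check uses 50 replicates at n = 120.
These sizes keep every statistical check well inside its Monte-Carlo
tolerance while completing in seconds.

## Known limitations

* Univariate linear models only; no PLS, no nonlinear calibration forms.
* No multiple-testing control in the screening stage (by design, flagged).
* Band lookups interpolate linearly; no spline or Gaussian red-edge
  fitting — edge positions are grid-node arg-extrema with 1 nm resolution.
* The simulator's dust endmembers are smooth; it does not reproduce
  reported fine structure such as twin reflection peaks near 535–550 nm
  under cement dust, whose mechanism is unclear.
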