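---
title: "Modelling vertical SPAD distribution in maize canopies and inverting it from multispectral reflectance"
author: "canopyspad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canopyspad methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyspad)
```

## The problem

Leaf chlorophyll content in a maize canopy is not vertically uniform: SPAD
readings (a unitless transmittance-based proxy for chlorophyll) rise from
the lowest leaves to a mid-canopy maximum and fall again towards the top —
a bell-shaped vertical profile whose shape shifts with growth stage and
nitrogen supply. Canopy-scale remote sensing (e.g. UAV multispectral
imagery) sees a reflectance signal dominated by particular leaf layers, so
a model that treats the canopy as uniform misattributes that signal. This
package implements the full analysis chain for working with that vertical
structure:

1. a parametric model of the vertical SPAD profile,
2. plot-level vegetation indices (VIs) from 5-band reflectance,
3. a screen for the leaf position whose SPAD is most tightly coupled to a
   chosen VI ("sensitive leaf"), and
4. simple linear inversion models for SPAD from a VI, fitted either to the
   sensitive-leaf SPAD or to the canopy mean, and compared.

Because no field data ship with the package, a synthetic campaign
generator with fully known ground truth stands in for the field campaign;
every downstream stage is exercised against it.

## The vertical profile model

The vertical profile is modelled by the Lorentz peak distribution
function,

$$\mathrm{SPAD}(n) \;=\; \frac{\mathrm{SPAD}_m}{1 + \left(\frac{n - n_m}{b}\right)^2},$$

with three interpretable parameters: $\mathrm{SPAD}_m$, the peak SPAD
value; $n_m$, the leaf position (counted from the bottom) at which the
peak occurs; and $b > 0$, a width/slope coefficient in leaf-position
units — the curve falls to half its peak at $n = n_m \pm b$. The model is
even in $b$, so the fitter always reports the positive representative.

`fit_lorentz()` estimates the three parameters by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`). Numerical choices, all data-driven so
that a noiseless profile is recovered deterministically:

* start values: $\mathrm{SPAD}_m \leftarrow \max(\mathrm{SPAD})$,
  $n_m \leftarrow$ the position of that maximum, $b \leftarrow$ half the
  observed position range;
* box constraints: $\mathrm{SPAD}_m \in (0, 2\max]$,
  $n_m \in [\min - 2, \max + 2]$ positions, $b \in [0.1, 3\,\mathrm{range}]$;
* convergence tolerances `ftol = ptol = 1e-15`, at most 2000 function
  evaluations;
* at least 3 distinct leaf positions and a non-constant profile are
  required (otherwise an error); optimizer failure is reported through the
  `converged` flag rather than an exception.

The test suite verifies that the fitter's objective never exceeds the best
triple on a dense $50^3$ parameter grid (a brute-force oracle) and that
all 28 built-in reference triples are recovered from noiseless profiles to
better than $10^{-6}$ relative error.

### Group fits and cross-season validation

`fit_campaign()` produces the per-(treatment × stage) parameter table.
The default aggregation fits the *position-wise mean profile* of each
group: per-position means across plots are computed first and one curve is
fitted through them, which corresponds to the usual presentation of a
single fitted curve through mean points with error bars. Whether such
published tables are produced from mean profiles or from pooled
observations is generally ambiguous, so pooled fitting
(`aggregation = "pooled"`) is provided as well; for symmetric
perturbations both agree. `n_m` is reported both raw (continuous) and
rounded to the nearest integer leaf position — a continuous optimizer
cannot be forced onto the integer grid without changing the model, and the
rounded column is what a printed table of integer peak positions
corresponds to.

`validate_fit()` applies a fitted parameter table to an independent
profile set (typically another season), pooling predicted vs observed
SPAD per stage into $R^2$ and RMSE on the 1:1 line.

## Evaluation metrics

`r_squared()`, `rmse()`, `nrmse()` and `pearson_r()` implement the
explicit formulas

$$R^2 = 1 - \frac{\sum_i (y_i - P_i)^2}{\sum_i (y_i - \bar y)^2},\qquad
\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i (y_i - P_i)^2},\qquad
\mathrm{nRMSE} = \frac{\mathrm{RMSE}}{y_{max} - y_{min}},$$

and the product-moment correlation $r$. $R^2$ is computed against the 1:1
line (not re-fitted), may be negative, and is not clamped. The p-value for
$r$ uses the exact t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$
degrees of freedom — the standard test for a Pearson correlation.
Screening is at raw $p < 0.05$ per leaf position / per index, with **no
multiple-testing correction**, matching the screening convention of the
sensitivity analysis this package implements; the returned p-values can be
passed to `stats::p.adjust()` (e.g. Holm) when family-wise control is
preferred.

## Vegetation indices

`compute_vi()` implements 17 chlorophyll-related broadband indices on
fractional 5-band reflectance (band centres 475 / 560 / 668 / 717 /
842 nm). The formulas are applied exactly as published for broadband use;
in particular the triangular and absorption indices (TVI, mTVI, TCARI,
MCARI, EVI, DVI) are computed on *fractional* reflectance with no percent
rescaling, so their numeric ranges differ from papers that use percent
reflectance. Two indices deserve notes:

* **mNDblue** is implemented as $(R_{blue} - R_{re})/(R_{blue} +
  R_{nir})$ — the red-edge variant with an NIR denominator. Other
  definitions circulate; because the denominator pairs blue with NIR
  rather than with the red edge, this form is *not* bounded in $[-1, 1]$.
* **CCCI** is the min–max rescaling of NDRE over a normalization
  population, $(\mathrm{NDRE} - \mathrm{NDRE}_{min}) /
  (\mathrm{NDRE}_{max} - \mathrm{NDRE}_{min})$. The population is all
  plot ROIs of one flight date/stage — the only scope consistent with
  computing CCCI per stage — so CCCI is a *campaign-relative* quantity:
  values from different dates are each in $[0,1]$ but not directly
  comparable. `build_vi_table()` therefore normalizes CCCI within the
  stage it is given and refuses mixed-stage input.

Division by zero yields `NA`, which is propagated (never dropped
silently) and counted per index in the `"n_missing"` attribute.

## Sensitivity screening and inversion

`stage_dataset()` aligns, per stage, the plot-level canopy-mean SPAD
(mean over all measured leaf positions), the per-position SPAD matrix and
the VI table. Leaf positions missing in some plots (senesced lower leaves
at R1/R2) are handled by pairwise-complete correlation per position, with
the per-position $n$ reported.

`find_sensitive_leaf()` correlates the chosen VI with SPAD at every leaf
position and returns the position with the **maximum signed r**, ties to
the lower position. Signed rather than absolute maximization is the
default because canopy reflectance contrast increases with chlorophyll and
all expected sensitivity profiles are positive; `use_abs = TRUE` switches
to $|r|$ for applications where negatively coupled layers matter.

`fit_inversion()` fits $\mathrm{SPAD} = \beta_0 + \beta_1 \cdot
\mathrm{VI}$ by OLS on an explicit training set of plot ids, evaluating on
a disjoint test set (or flagging resubstitution when none is given). An
explicit id split is required because which season plays which role in a
two-season train/test protocol is a user decision, not a package default.
`compare_models()` reports the relative improvement of the sensitive-leaf
model over the canopy-mean model as
$100\,(R^2_{sens} - R^2_{canopy})/R^2_{canopy}$, rounded to the nearest
integer percent — e.g. test $R^2$ of 0.59 vs 0.44 is a 34 % improvement.

## The synthetic campaign generator

`campaign_config()` + `ground_truth()` + `generate_profiles()` +
`generate_reflectance()` emulate a two-factor split-plot nitrogen trial:

* **Layout**: 7 nitrogen levels (N0–N6, 0–400 kg N ha⁻¹) × 10 varieties ×
  3 replicates by default; four growth stages V6 / V9 / R1 / R2 with leaf
  ranges 1–6, 1–9, 6–20 and 6–19 (bottom leaves senesced and counting
  truncated at the reproductive stages).
* **Profiles**: each plot × stage draws its SPAD profile from the
  Lorentz curve of the built-in per-(treatment × stage) parameter table
  (`default_lorentz_params()`, 28 triples), plus additive Gaussian noise
  truncated below at zero. Truncation rather than resampling keeps the
  generator simple; at the default noise level the induced bias is
  negligible because profile values sit far above zero.
* **Noise defaults**: SPAD noise sd 1.5 SPAD units — a realistic
  repeatability figure for plot-averaged handheld SPAD readings (five
  plants × five leaf segments averaged); the within-plot variance of real
  campaigns is rarely published, so this is a package choice, exposed in
  the configuration. Reflectance (latent contrast) noise sd 0.02 NDRE
  units.
* **Reflectance**: generated through NDRE rather than a radiative-transfer
  model. A latent contrast $c = a_0 + a_1\,\mathrm{SPAD}(n_{sens})$ (with
  Gaussian noise, clamped to $(0.01, 0.99)$; defaults $a_0 = -0.10$,
  $a_1 = 0.012$ place NDRE in ≈0.2–0.6 for SPAD 25–60) is realized
  exactly as NDRE by fixing NIR at 0.45 and solving for the red edge,
  $R_{re} = R_{nir}(1 - c)/(1 + c)$. Blue/green/red are nuisance draws
  from fixed plausible ranges (0.03–0.06, 0.06–0.12, 0.04–0.10),
  independent of SPAD. This is the minimal structure that makes the whole
  downstream chain exercisable: NDRE-family indices (NDRE, CCCI) carry the
  designed signal, the designated sensitive positions (V6: 6, V9: 4,
  R1: 12, R2: 12) are recoverable, and everything else behaves as noise.
* **Determinism**: one global integer seed; every plot × stage consumes
  its own RNG stream derived by counter offset, so identical seeds give
  bit-identical campaigns and appending plots leaves earlier draws
  unchanged.

What the generator deliberately does **not** emulate: radiative transfer
(leaf angle, soil background, shadowing), spatial autocorrelation between
neighbouring plots, variety-specific profile shapes (varieties differ only
through noise), senescence dynamics within a stage, or any coupling of the
visible bands to chlorophyll. Passing tests on synthetic campaigns
therefore demonstrate the *correctness of the machinery* — parameter
recovery, index arithmetic, screening logic, model comparison — not the
field-scale accuracy of SPAD inversion, which can only be established on
real campaigns.

## Imagery

`extract_roi_means()` reproduces the plot-reflectance extraction step:
per-band arithmetic means over rectangular regions of interest (by
convention 100 × 100 pixels per plot) in a co-registered 5-band
reflectance mosaic. Coordinates are 0-based, row-major, top-left origin,
with half-open extents, which makes "100 × 100 pixels" unambiguous.
Nodata pixels are excluded from the mean; an ROI entirely nodata in a band
flags the plot. On disk, scenes are 32-bit float multi-directory TIFFs in
fixed band order with an optional sixth validity-mask directory shared
across bands (the float TIFF writer stores only $[0,1]$, so an in-band
sentinel cannot represent nodata). Upstream photogrammetry — stitching,
radiometric calibration, multi-date registration — is out of scope; ROIs
are assumed co-registered. No shadow or soil masking is applied beyond
nodata.

`make_fixture_raster()` inverts the extraction for testing: it tiles
constant (optionally pixel-noisy) blocks with known means and emits
matching ROI specs, so extraction is checked as an exact round trip and,
under noise, against the CLT ($3\,\sigma/\sqrt{hw}$).

## Problem sizes used by the test suite

The suite works at desk scale, chosen to keep the full run under a minute
while leaving comfortable statistical margins: 28 noiseless round-trip
fits; 1000 random vectors for metric and index oracle equivalence; 50
random profiles against a $50^3$ brute-force grid; 100 seeded 70-plot
single-stage campaigns for the end-to-end sensitivity property (recovery
of the designated leaf in ≥95/100 and a sensitive-leaf test-$R^2$
advantage in ≥90/100); and 50 replicates of 315-point pooled validation
for RMSE concentration under known noise.

## Known limitations

* The linear SPAD–NDRE link in the generator is a modelling convenience;
  real canopies saturate at high leaf area index and the link varies by
  stage.
* `fit_lorentz()` constrains $b \ge 0.1$ leaf positions; profiles
  narrower than that (not biologically plausible for maize) would hit the
  bound.
* CCCI depends on the normalization population; comparing CCCI-based
  models across campaigns requires a shared normalization or a
  campaign-invariant index.
* Only the five broadband channels are supported; no hyperspectral or
  narrow-band variants.
* No quantitative model links $(\mathrm{SPAD}_m, b)$ to nitrogen rate or
  thermal time; the parameter table is descriptive.
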