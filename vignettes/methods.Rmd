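---
title: "Models and methods behind metalrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metalrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
library(dplyr)
```

metalrisk assesses heavy-metal contamination of surface waters from flat
tables of monitoring records — one row per station, season and replicate,
with concentrations of Cd, Cu, Fe, Pb and Zn in mg/L and a below-detection
flag per metal. This vignette explains the models, the defaults and the
numerical choices, and states what the synthetic generator does and does
not emulate.

## The weighted pollution index

Each metal $m$ receives a relative weight $R_{w,m} = 1/L_m$, the
reciprocal of its permissible limit $L_m$ (mg/L), and a normalized
parameter weight $W_{p,m} = R_{w,m} / \sum_k R_{w,k}$, so
$\sum_m W_{p,m} = 1$. The contamination status is the limit-normalized
concentration $S_{c,m} = C_m / L_m$ and the index total is

$$\mathrm{HPI} = \sum_m W_{p,m}\, S_{c,m}.$$

Two consequences anchor the scale. A sample sitting exactly at all limits
scores 1, and the index is linear in the concentration vector, so doubling
every concentration doubles the index. The classification uses five bands:
0–0.25 negligible (excellent water), 0.25–0.5 very low (good), 0.5–0.75
low (poor), 0.75–1 moderate (very poor), and above 1 high pollution, not
fit for drinking. A value sitting exactly on an edge is assigned to the
lower band, so 0.25 classifies as negligible. (Index values well above 1
are meaningful — the bands are an open-ended drinking-water scale, not a
0–1 normalization, and Cd-dominated river samples land between 2 and 3.)

Default limits are the WHO drinking-water guideline values — Cd 0.003,
Cu 2, Fe 0.3, Pb 0.01, Zn 3 mg/L — overridable through a YAML standards
table. Cadmium's strict limit gives it weight $W_{p,\mathrm{cd}} \approx
0.762$; lead follows with $\approx 0.229$; the remaining three metals
together carry under 1% of the weight. That is why the *exclusion*
analysis matters: `hpi(..., exclude = "cd")` drops the cadmium sub-index
**without renormalizing** the remaining weights. This is the "what if
cadmium were absent" counterfactual: a spring sample at 0.009 mg/L across
all metals falls from 2.49 (unfit) to 0.206 (excellent). Renormalizing
instead would redistribute cadmium's 76% weight onto lead and keep the
sample out of the excellent band; both operations are defensible, but the
counterfactual reading is the one the package implements because it is the
question practitioners ask of a single dominant pollutant.

By default the index is computed on replicate means per station and
season; `by_replicate = TRUE` keeps replicates separate. Censored values
enter at their stored substitution value and flag the result row.

## The exposure and health-risk chain

The drinking-water dose is the average daily intake

$$\mathrm{ADI} = \frac{C \times IR \times EF \times ED}{BW \times AT}
\quad \left[\mathrm{mg\,kg^{-1}\,day^{-1}}\right],$$

with defaults body weight $BW = 70$ kg, intake rate $IR = 2$ L/day,
exposure frequency $EF = 365$ days/yr, exposure duration $ED = 70$ yr and
averaging time $AT = ED \times EF$ days. Under that averaging-time
convention $ED$ and $EF$ cancel and the dose reduces to $C \cdot IR / BW$;
the package asserts this identity in its tests, and `exposure_profile()`
offers presets for shorter durations (30, 65 yr) and a 1.5 L/day intake.

Non-carcinogenic risk is the hazard quotient $HQ = \mathrm{ADI}/RfD$ per
metal and the hazard index $HI = \sum_m HQ_m$; $HI \le 1$ means no
adverse effect is expected. Default oral reference doses (mg/kg/day) are
Cd 0.0005, Cu 0.04, Fe 0.7, Pb 0.0035, Zn 0.3 — standard oral RfD values,
shipped as an overridable table rather than hard-wired.

Carcinogenic risk is $CR = \mathrm{ADI} \times CSF$ and the carcinogenic
index $CI = \sum CR$ over metals with a slope factor, judged against the
conventional acceptable band of $10^{-6}$ to $10^{-4}$ lifetime excess
risk. Slope factors are **not** defaulted silently: published values vary
by agency and route, so the shipped example table (Cd 6.1, Pb 0.0085
(mg/kg/day)$^{-1}$, others absent) is only used when the caller explicitly
passes `with_csf = TRUE` with the default standards; a user-supplied
standards table must carry its own factors or the carcinogenic chain
errors.

```{r risk-example}
fx <- station_fixture(variants = "as_printed")
health_risk(fx, with_csf = TRUE) |>
  select(sample_id, river, season, hi, ci, ci_class) |>
  head(4)
```

## The model-comparison harness

Each metal is predicted from the remaining four concentrations, a season
indicator and the station coordinates — the layout that supports spatial
prediction maps. Three regressors are compared, with tuned
hyperparameters held fixed:

* **random forest** — 15 trees (`randomForest`), raw features;
* **support vector regression** — RBF kernel, $\gamma = 1.2$,
  $\varepsilon = 0.015$, $C = 200$ (`e1071`), z-scored features;
* **neural network** — one hidden layer of 9 sigmoid neurons, linear
  output, up to 1000 epochs, z-scored features.

Feature standardization statistics are always estimated on the training
data only. The neural network's default optimizer is a hand-implemented
Levenberg–Marquardt loop: damped Gauss–Newton steps
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = J^\top r$ with an
analytic Jacobian, $\lambda$ starting at the configured learning rate
(0.01), divided by 10 on accepted steps and multiplied by 10 on rejected
ones. Output weights start at zero and the output bias at the training
mean, so the initial model is the mean predictor — which also makes a
constant target an exact fixed point. A BFGS alternative
(`optimizer = "quasi_newton"`, via `nnet`) is selectable. If the epoch
budget runs out before the gradient tolerance is met, a warning is raised
and the best weights seen are returned.

One SVR degeneracy is handled explicitly: when the target's whole range
fits inside the $2\varepsilon$ tube, the SVR optimum has zero support
vectors ($w = 0$) and any feasible constant is optimal; libsvm reports an
empty model there, so the package returns the midrange constant — the
exact solution. With $\varepsilon = 0.015$ on mg/L-scale targets this
happens routinely for the low-range metals, and it is a faithful
consequence of the stated hyperparameters rather than a defect.

Scoring uses MAE, RMSE, MAPE and $R^2$. Note the MAPE convention: the
denominator is the **predicted** value,
$\mathrm{MAPE} = \frac{100}{n}\sum |a_i - \hat a_i| / |\hat a_i|$, and
elements with $\hat a_i = 0$ (possible under zero-substitution censoring)
are excluded with a warning and counted. MAPE is reported in percent.
Validation is a seeded 70/30 hold-out split plus k-fold cross-validation
with $k = 5$ by default ($k$ is a free choice; 5 balances bias and cost
at these sample sizes). Records are canonically ordered by sample
identifiers before the seeded shuffle, so splits and fold assignments do
not depend on incoming row order.

## Interpolated surfaces

Station values (concentrations, index values, risk indices) become
continuous surfaces by inverse-distance weighting with power 2: each cell
is $\sum w_i v_i / \sum w_i$ with $w_i = d_i^{-2}$. Coordinates pass
through an equirectangular local projection before distance computation —
over a coastal study extent of a few tenths of a degree, planar geometry
is accurate to well under a percent, and IDW is the minimal defensible
interpolant when nothing is known about the spatial covariance (kriging
would require a variogram the data cannot support at 10 stations). Cells
within $10^{-9}$ degrees of a station take the station value exactly;
consequently the surface is exact at stations and bounded by the station
value range. Banding a surface reuses the five-band classification and
reports cell counts per band. Rasters export as plain-text ESRI ASCII
grids, banded cells as GeoJSON polygons, quick-looks as PNG.

## The synthetic generator

`generate_samples()` emulates a two-season, ten-station campaign across
three rivers and a coastal lagoon with three replicates per station. Its
defaults are fixed as the study design the package targets:

* marginal ranges (mg/L): Cd and Cu 0.005–0.01, Fe 0.007–0.34,
  Pb 0.007–0.22, Zn 0.009–0.3;
* winter correlations 0.727 (Cd–Cu) and 0.607 (Cd–Zn, Cu–Zn), spring
  correlations near 1 among Cd/Fe/Zn (0.999), Cd–Pb 0.998 and 0.85
  between Cu and the rest;
* spring below-detection censoring at the two upstream border-river
  stations;
* detection limits Cd/Cu 0.004, Fe/Pb 0.006, Zn 0.008 mg/L — chosen once
  as plausible flame-AAS limits of quantification, since only the fact of
  censoring, not the instrument limit, is recorded in the source survey.

Only ranges and correlations are known, not distribution families, so
concentrations are drawn through a **Gaussian copula with uniform
marginals**: a latent multivariate normal is mapped through the normal
CDF onto each metal's range. Two numerical details matter. First, the
latent correlation is pre-adjusted as $\rho = 2\sin(\pi r/6)$ so the
*Pearson* correlation of the uniform marginals matches the target $r$
(the standard copula correction). Second, latent draws use exact
second-moment matching (`MASS::mvrnorm(empirical = TRUE)`; plain Cholesky
colouring below 11 draws), so the sample correlation equals the target up
to the copula transform instead of wandering with $O(n^{-1/2})$ sampling
noise — at 1000 stations the empirical matrices sit within 0.05 of the
targets everywhere and within 0.01 for the near-unity pairs. User-supplied
correlation matrices are validated (symmetry, unit diagonal) and repaired
to positive semidefiniteness by clipping negative eigenvalues at
$10^{-10}$ and rescaling the diagonal; a repair that moves the matrix by
more than 0.1 in Frobenius norm errors instead, since such an input is a
mistake, not noise.

Censoring substitutes LOD/2 by default — the common convention in
environmental statistics — with `zero` and `drop` selectable. Seeds flow
from one root generator with an independent sub-stream per season, so a
single season can be regenerated identically.

What the generator does **not** emulate: spatial autocorrelation along
river courses (coordinates are uniform in the bounding box, rivers
assigned by longitude band), inter-season dependence at a station,
instrument error structure, or real pollutant sources. Tests that pass on
synthetic data therefore validate the *statistical machinery* — index
arithmetic, exposure algebra, estimator behaviour under known correlation
— not claims about any real river system.

## Problem sizes and reproducibility

The bundled checks run the index and risk chains on the 17-row station
fixture, correlation-recovery checks at 1000 stations, and model fits at
30–120 records — sizes chosen so the full suite completes in well under a
minute while still exercising every code path. `run_pipeline()` writes a
deterministic bundle (identical files for identical configuration and
seed) and a YAML manifest with the seed and a configuration hash.

Known limitations: point-estimate risk only (no Monte-Carlo uncertainty),
ingestion route only (no dermal/inhalation), no kriging or hydrological
transport, and the source survey's own published error tables cannot be
recomputed because its full measured dataset and dose constants are not
public — the package instead verifies the machinery on data with known
structure.
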