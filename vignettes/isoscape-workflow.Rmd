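---
title: "Building delta-13C isoscapes for insect origin tracing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building delta-13C isoscapes for insect origin tracing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isokrig)
options(isokrig.log_level = "off")
```

`isokrig` turns a sparse table of sampling sites — site-mean δ¹³C of insect
tissue plus bioclimatic covariates — into a classified isoscape and assigns
unknown samples to origin regions. This vignette is the package's account of
the statistical machinery: the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic generator emulates, and
where the method's limits are.

## 1. Data model and units

The analysis unit is the *site*: within-site specimen replicates enter as a
mean, a standard deviation, and a count (`d13c_mean`, `d13c_sd`, `n`), and
the spatial model interpolates site means. δ¹³C is in ‰ vs PDB (plausible
C3-food-web values are around −35…−15‰; values outside warn but do not
error). Coordinates are geographic degrees; inter-site distances use the
haversine formula on a 6371.0 km sphere, with a planar-Euclidean option for
data already in projected km. Published site lists sometimes print the
coordinate columns swapped; the reader validates ranges and offers an
explicit `auto_swap` policy — applied only when swapping fixes *every* row,
and logged — rather than guessing silently.

## 2. Covariate screening

Bioclimatic covariates come in two internally collinear blocks (temperature
Bio1–Bio11, precipitation Bio12–Bio19). Within a block we compute all
pairwise Pearson correlations with two-sided p-values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. A variable *passes* the screen when it has
no significant correlation with any other block member; the block's
*representative* is the variable with the most significant correlations
(ties by mean |r|, then name order, logged). Because published narratives
also speak of the "least correlated" variable in a block even when it has
some significant partners, the least-collinear variable is reported
alongside. The screened set plus CO₂ and solar radiation goes through a VIF
check ($\mathrm{VIF}_j = 1/(1-R_j^2)$, OLS with intercept; VIF ≤ 10 read as
no collinearity, exact collinearity reported as `Inf`). Finally each
candidate is correlated with δ¹³C; the auxiliary shortlist is ranked by |r|
among significant variables. Adjusted $R^2$ (not plain $R^2$) accompanies r
because at these sample sizes it can legitimately go negative, which is
informative about useless covariates. The significance level α is a
parameter, default 0.05; with ~10 sites the distinction between α = 0.05
and α = 0.01 can change which variable "wins" a block, so both the counts
and the full r/p matrices are returned for audit.

## 3. Spatial dependence

Moran's *I* with inverse-distance row-standardized weights (k-nearest and
user-matrix weights available) and a two-sided permutation test,
$p = (\#\{|I_\pi - E[I]| \ge |I_{obs} - E[I]|\} + 1)/(n_{perm}+1)$ with
$E[I] = -1/(n-1)$ and 999 permutations by default, checks that the site
means are spatially structured before any kriging is attempted.

Empirical semivariograms use the Matheron moment estimator on binned pair
distances, by default 12 equal-width bins up to half the maximum inter-site
distance; bin "centers" are the mean pair distance per bin. The cross
form $\hat\gamma_{12}(h) = \sum (z_{1i}-z_{1j})(z_{2i}-z_{2j})/2N(h)$
justifies an auxiliary: visible cross-structure means co-kriging has
something to exploit. Collocated duplicate coordinates are an error by
default (an averaging option exists, logged), since they make the kriging
matrix singular.

## 4. The model catalog

Eleven families are parameterized as $\gamma(h) = c_0 + c\,g(h/a)$, with
$\gamma(0)=0$ by convention, under the *effective-range* convention:
families that approach their sill asymptotically (exponential, Gaussian,
stable, rational quadratic, K-Bessel, J-Bessel) are scaled so
$g(1) = 0.95$ — hence the familiar factor 3 in $1-e^{-3u}$ and the 19 in
$19u^2/(1+19u^2)$. The polynomial families (circular, spherical,
tetraspherical, pentaspherical) reach the sill exactly at $h=a$; the
tetraspherical uses the 4-dimensional ball-overlap correlation, evaluated
through the regularized incomplete beta function (the same identity
reproduces the circular, spherical and pentaspherical closed forms, which
is exploited in the tests). K-Bessel is the Matérn model
$1-(2^{1-s}/\Gamma(s))t^sK_s(t)$ (shape default 0.5) and J-Bessel is
$1-\Gamma(s{+}1)(2/t)^sJ_s(t)$ (shape default 1); both get their lag
scaling $t=\kappa u$ calibrated at construction so the 95%-sill point lands
at $h=a$ — for J-Bessel the calibration root is taken before the first zero
of $J_s$, and like the hole effect the model then oscillates about its sill,
which is the feature that lets it track quasi-periodic spatial patterns.
Parameter domains are validated at construction, not at evaluation.

**Fitting** minimizes $\sum_k w_k(\hat\gamma_k - \gamma(h_k))^2$ over
non-empty lags with $w_k = N(h_k)$ (Cressie weights $N/\gamma^2$ by flag),
using bounded L-BFGS-B from a moment-based start plus Latin-hypercube
starts (8 total, seed default 20240457), then a Nelder-Mead and a tight
L-BFGS-B polish. On noise-free curves the generating parameters are
recovered to ~1e-6, and the fit is invariant to lag order and rescales
correctly with distance units. The `stable` shape is fitted as a fourth
parameter when not fixed; the Bessel shapes are fixed (fitting smoothness
from ~10 sites is hopeless).

**Coregionalization.** The two-variable LMC shares one structure:
$\gamma_{kl}(h) = B_0[k,l]\,1(h>0) + B_1[k,l]\,g(h/a)$. The shared range is
profiled by one-dimensional minimization (each component's nugget/sill is
then a linear weighted-least-squares solve, non-negative for the direct
components, each component's SSE normalized by its scale so the covariate's
units do not dominate). Cross coefficients are clipped into the positive
semi-definite cone; the clip lands *strictly inside* the boundary (factor
$1-10^{-6}$), because $b_{12}^2 = b_{11}b_{22}$ exactly means perfectly
correlated components and a singular co-kriging system. Every projection is
logged. With 10 fixture sites the clip is active for most families — the
printed metric table makes that auditable rather than hiding it.

## 5. Kriging

Ordinary kriging and ordinary co-kriging are solved in semivariance form
(so unbounded or oscillating models remain usable), with constraints
$\sum\lambda=1$, $\sum\mu=0$; prediction variance is
$\sum\lambda_i\gamma(h_{i0}) + \sum\mu_j\gamma_{12}(h_{j0}) + m$. All sites
enter every prediction (global neighbourhood): site counts here are tens of
points, and search-ellipse heuristics would only add unreported degrees of
freedom. Negative variances from round-off are clipped to zero and counted
in the log. Grid prediction shares one factorization across cells and is
bit-identical to per-cell point kriging; cells beyond a configurable
`max_dist` from the nearest site become nodata. The secondary variable is
used at the data sites only — no collocated-covariate variant at the
prediction point — keeping the predictor strictly within what the site
table supports.

## 6. Cross-validation and model choice

Leave-one-out CV predicts each site from the other $n-1$. By default the
(co)variogram is *fixed* from the full data and only the kriging system is
re-solved per fold, matching standard GIS cross-validation; `per_fold`
refitting exists for sensitivity analysis. For co-kriging the auxiliary
value at the held-out site is kept by default: the auxiliaries are climate
covariates, known everywhere (including at any future unknown sample's
hypothesized origin), so dropping them would understate exactly the
benefit co-kriging is there to deliver. A strict `drop_aux` mode removes
the whole site instead.

The metric quartet is RMSE, mean standardized error
($\mathrm{mean}(e_i/\sigma_i)$), RMSSE
($\sqrt{\mathrm{mean}((e_i/\sigma_i)^2)}$), and average standard error.
RMSSE > 1 flags *underestimated* prediction variability, < 1
*overestimated*. Ranking is lexicographic — lowest RMSE, then |RMSSE−1|,
then |MeanSE|, then |ASE−RMSE|, residual ties by name order, logged — and
the full score table is always returned so a user who weighs RMSSE over
RMSE can defend the alternative choice. ESDA products (least-squares line
of predicted on observed; normal Q-Q pairs of sorted standardized errors at
plotting positions $(k-0.5)/n$) support the same judgement graphically.

## 7. Classification and assignment

Fisher–Jenks natural breaks minimize the within-class sum of squared
deviations exactly, by dynamic programming over the *distinct* values with
multiplicity weights (ties can never be split). Interval boundaries are
reported as the data extremes at the ends and midpoints between adjacent
class extremes inside: unlike class-maximum breaks, these are strictly
increasing even when a class is a single repeated value, and the
lower-open/upper-closed membership rule (lowest interval closed at both
ends) then reproduces the DP classes exactly. A cell exactly on an interior
break belongs to the lower interval. Default k = 3 with labels
low/medium/high *by numeric δ¹³C order* — labels are configurable because
the domain literature is not consistent about which end of the δ¹³C scale
it calls "high", and the numeric intervals are the ground truth.

Assignment reports the sample's class, the fraction of mapped (non-nodata)
cells sharing it (`compatible_fraction`; an optional ±tolerance mode in ‰
counts near-boundary cells instead, since samples near a class boundary are
exactly the hard cases), and, given a hypothesized coordinate, the
consistency z-score $(z_{obs}-\hat z)/\sigma$. Values outside the grid's
prediction range are flagged out-of-range with compatibility 0.

## 8. The synthetic generator: what it emulates, and what not

`synthetic_field_spec()` encodes the study conditions the tests run under:
a jointly Gaussian pair of fields (δ¹³C + one covariate) with a shared
exponential structure, simulated by dense Cholesky factorization of the
joint covariance (exact, capped at ~10⁴ joint dimensions; a degenerate
all-zero covariance returns the mean surfaces directly). Defaults, chosen
once from the anchors the application domain provides: effective range
comparable to the sampled domain (strong spatial autocorrelation is the
regime in which isoscape tracing is attempted at all), a 1‰ west-to-east
gradient in the mean surface with total field variance 0.09‰² on top —
giving an overall between-site spread of about 1‰ — cross-correlation 0.6
with the covariate (matching the ~0.5–0.6 target correlations the screening
is designed to find), and 5 replicates per site with 0.1‰ replicate noise
(published within-site sds run ~0.05–0.21‰). Replicate noise is stored as
the *sample* sd of the simulated replicates, so the stored values carry the
usual small-sample bias (c₄ ≈ 0.94 at n = 5) exactly as real tables do.
Covariate layers are unit-scaled internally and affine-transformed into a
realistic range (default precipitation-seasonality-like, 70 ± 9) when
written into a site table; the remaining covariate columns are filled with
independent noise purely to keep the table read-compatible.

What the generator does *not* emulate: non-Gaussian tails, host-plant
effects (species-specific δ¹³C baselines), measurement drift between
campaigns, anisotropy, and non-stationary variance. Green synthetic
benchmarks therefore certify the *estimators and solvers*, not the field
realism of any particular published map.

Problem sizes used by the test suite were picked to keep a full run at
desk scale: solver oracles at n ≤ 8 sites (200 random configurations),
recovery and calibration studies at 60–200 sites on 100–120 km domains
with 30–50 seeded replicates, permutation-uniformity at 500 replicates of
199 permutations, and the fixture pipeline on a 0.25° grid (~3200 cells).

## 9. Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; fitting, simulation and
  permutation tests restore the caller's RNG state.
* Kriging systems are solved densely; a singular system is an error naming
  the likely cause (duplicate sites, degenerate model), and in LOOCV a
  singular fold is skipped and counted rather than aborting the study.
* Zero-variance variables, empty blocks, under-determined fits (fewer
  usable lags than parameters), k exceeding the number of distinct values,
  and grids too large for dense simulation are all named errors.
* Empty variogram bins are reported with N = 0 and excluded from fitting.
* The ESRI ASCII round trip preserves values to 1e-6 (10 significant
  digits written), geometry exactly, and the nodata mask; all layers of
  one grid share one sentinel (−9999 by default).

## 10. Known limitations

With ~10 real sites the empirical variogram has a handful of usable lags;
model ranking discriminates weakly and several families fit
near-identically — the package surfaces this (clip logs, full metric
table) instead of smoothing it over. Range parameters estimated from a
single realization carry irreducible sampling error even for an efficient
estimator; uncertainty in the fitted variogram is *not* propagated into
the kriging standard errors (the classical plug-in caveat). Assignment is
deterministic by class, not probabilistic: a likelihood-surface assignment
would need a defensible error model for between-laboratory offsets, which
single-isotope data do not constrain.
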