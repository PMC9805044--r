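---
title: "Partitioning uncertainty in climate projections of species distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning uncertainty in climate projections of species distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Species distribution models (SDMs) fitted to historical observations are
routinely projected decades ahead under climate forcing, yet we rarely
know how trustworthy those projections are, because validation data for
2050 do not exist.  `sdmuq` sidesteps that problem with a virtual-species
simulation: the "true" distribution of each species is generated from
known environment–suitability rules, so every projection can be scored
against truth, and the total spread of an ensemble of projections can be
attributed to its sources — divergent earth-system-model (ESM) forcing,
the choice of SDM family, and the choice of covariate parameterization.

The experiment runs on a California Current-like domain (30–48°N, coast
to 134°W) over 1985–2100, with a 1985–2010 fitting period and a
2011–2100 projection period, for three archetypes of commercially
important marine finfish: a highly migratory species (HMS,
albacore-like), a coastal pelagic species (CPS, anchovy-like) and a
groundfish (GFS, sablefish-like).

## The forcing emulator

Real applications use dynamically downscaled ESM projections.  Here
three *pseudo-ESMs* emulate the statistical structure of such an
ensemble.  Each variable (SST, bottom temperature BT, bottom oxygen BO,
mixed-layer depth MLD, chlorophyll CHL, and zooplankton integrated over
50 m and 200 m) is generated as

> base(cell) + trend · (year − 1985) · nearshore(cell) + decadal
> sinusoid + AR(1) spatially correlated noise,

clipped to physical bounds (BO, CHL, ZOO ≥ 0; MLD > 0).  Design choices:

* **Trends** warm SST/BT and decrease MLD/BO/ZOO, at per-decade rates
  that differ among the three styles (the strongly forced end member
  loses zooplankton about twice as fast as the mildest).  Rates were
  chosen once so that late-century fields are strongly displaced from
  the historical envelope without collapsing any field to its physical
  bound domain-wide.
* **Decadal variability** (30-year sinusoid, style-specific phase) is
  applied to MLD and zooplankton only, emulating low-frequency climate
  variability in mixed layer and productivity; different phases make the
  pseudo-ESMs disagree even before the trends separate.
* **Noise** is an AR(1) process in time (φ = 0.5) built from
  spatially smoothed Gaussian fields (range 2 cells), a pragmatic stand-in
  for mesoscale-aggregated interannual variability.
* **Nearshore amplification** multiplies trends by up to 1.5× at the
  coastal boundary, decaying offshore, so inter-ESM divergence is
  largest nearshore.
* **Chlorophyll** is generated as a noisy proportional proxy of ZOO50
  (CHL = 0.35·ZOO50 + noise).  The estimation models are only allowed to
  see CHL, never the zooplankton truth drivers — the deliberate
  proxy-covariate handicap of the design.
* Bathymetry is a deterministic shelf–slope–abyssal profile (~90 m at
  the coast to a ~4 km plateau); the "coastline" is the eastern grid
  boundary.  Real shoreline geometry is irrelevant to the statistical
  questions asked here.

The default grid is 0.5° (36 × 36 cells).  The 0.1° resolution of real
downscaled products is supported through `gridSpec()` but is about 25×
more expensive and changes nothing qualitative.  An ingest path
(`readForcing()`) accepts long-format CSV tables, annual or monthly
(monthly tables are reduced to March–May spring means); forcing written
by `writeForcing()` round-trips exactly.

## Operating models

Truth generation follows the virtual-species two-step.  Per-variable
suitabilities come from response curves (gaussian, logistic, or ramp);
their product is rescaled by the field maximum so the best cell-year
scores 1.  Suitability is converted to presence with a sharp logistic
function p = 1/(1 + exp((s − β)/α)) with β = 0.3 and α = −0.05;
cells of zero suitability (including everything outside the archetype's
domain) are strict absences.  Where present, biomass is drawn from a
lognormal (meanlog 2, sdlog 0.3), multiplied by the cell's suitability
("habitat-informed biomass") and by an annual population multiplier:

* HMS: none (distribution responds to environment only); drivers SST
  (gaussian, optimum 16 °C), MLD (gaussian, optimum 24 m), ZOO200
  (logistic); full domain.
* CPS: boom–bust two-state Markov regime (stay probabilities 0.8,
  high 2.0, low 0.25, lognormal jitter 0.2); drivers SST, ZOO50,
  bathymetry (shallow-preferring ramp); inshore domain.
* GFS: 20-year low/high recruitment phases (0.5 / 1.5, 2-year ramps);
  drivers BT (gaussian, optimum 7 °C), BO (logistic), bathymetry
  (shelf-break gaussian); inshore domain.

The inshore domain is bathymetry ≤ 1200 m — a single testable threshold
standing in for shelf/slope habitat.  Curve parameters are package
defaults (the reference study keeps its exact values in supplementary
data); they were chosen once so that historical suitability has strong
spatial structure and end-of-century forcing pushes a substantial
minority of cells outside the historical niche.  The multiplier scales
the biomass draw, not the presence probability, and is spatially
uniform within a year.

On the default 0.5° grid the inshore domain holds 252 cells, fewer than
the 500-per-year observation design, so inshore archetypes are censused
annually (with a warning) rather than subsampled; the HMS domain (1296
cells) is genuinely subsampled.  This is the intended degradation of
the design at desk scale.

## The estimation ensemble

All SDMs are hurdle (delta) models: a binary occurrence submodel fitted
to presence/absence on all training rows, and a lognormal
positive-biomass submodel fitted to log(biomass) on presence rows.
Projected biomass is p̂ · exp(m̂ + s²/2), with s² the training residual
variance of the log-scale submodel (the lognormal mean correction).
Covariates are never clipped to the training range — models extrapolate
natively, and extrapolation is *measured*, not prevented.

Four families are implemented, each in two flavors (binomial /
gaussian):

* **GAM** — penalized regression splines (`mgcv::bam`, k = 6 per
  covariate), a 2-D thin-plate smooth in (lon, lat) for S, a year
  smooth for T.
* **GLMM surrogate** — linear + quadratic fixed effects per
  environmental covariate (quadratic terms capture unimodal niches), a
  low-rank Gaussian radial-basis spatial surface (5 × 5 quantile knots,
  bandwidth 1.5× knot spacing) standing in for spatial random effects,
  and a strictly linear year term.  Keeping the year term linear is
  deliberate: a quadratic time trend extrapolates explosively over a
  90-year horizon and would dominate the ensemble variance with an
  artifact.
* **BRT** — stochastic gradient-boosted trees (`xgboost`: depth 3,
  500 rounds, learning rate 0.05, 75 % subsampling).
* **MLP** — one hidden layer of 16 units on standardized inputs
  (`nnet`, weight decay 0.01).

Parameterizations combine environmental covariates (E), spatial
coordinates (S), and a year term (T); "Temp" is the single-covariate
temperature model (SST for HMS/CPS, BT for GFS).  The default roster
has 15 types — GAM(E, S, ES, EST), GLMM(E, ES, ST, EST),
BRT(E, ES, ST, EST), MLP(E, ES, EST) — of which three are excluded from
the retained ensemble for poor projection behavior: the spatial-only
GAM, the spatiotemporal GAM (its unconstrained year smooth extrapolates
linearly without bound), and the spatiotemporal GLMM.  The composition
is configuration, not a constant: the reference study names the
exclusions but not the full roster, so the package treats the roster as
an open design choice and documents this one.  The retained 12 members
are all environmental except BRT_ST, whose tree-based year effect
freezes outside the training range rather than extrapolating.

The observation design draws 500 random cells per year without
replacement (13,000 training rows over 1985–2010; 45,000 test rows over
2011–2100), independently across years.  The same test draw is shared
by all members of one (archetype, ESM), so model comparisons are
paired.  Whether the reference study re-drew test cells per SDM is not
stated; sharing isolates model effects in the variance partitioning.

## Scoring, novelty, and variance partitioning

Projection skill is the annual Spearman correlation between simulated
and predicted biomass over the year's test cells (pooled within year —
the study's wording is ambiguous between pooling and per-cell averaging;
pooling is used and stated here).  Occurrence skill is the Mann–Whitney
AUC with half-credit ties.  Reported series are smoothed with an
11-year centered running mean (edges shrink).  Regions split at 34.5°
and 40°N, both boundaries assigned to the central region.

Environmental novelty uses the ExDet pair: NT1 sums the fractional
range exceedance of each covariate relative to the 1985–2010 reference
(negative when outside), and NT2 is the Mahalanobis distance to the
reference mean divided by the most extreme reference distance, computed
only for NT1 = 0 points; NT1 < 0 or NT2 > 1 marks a novel cell.  The
reference is built from *all* domain grid cells over the reference
years, not the 500-cell samples; covariance is ridge-regularized with
1e-8 × trace.  The NT2 > 1 novelty threshold is the standard ExDet
convention.  Covariate spaces per archetype are the SDM-facing sets:
{SST, MLD} for HMS, {SST, CHL, bathymetry} for CPS, {BT, BO,
bathymetry} for GFS.

Uncertainty partitioning fits, for every (year, region), a linear model
of the per-member regional biomass aggregates on three factor groups —
ESM (3 levels), family (4 levels), parameterization (up to 6 levels:
E, S, ES, ST, EST, Temp; absent levels are dropped, never imputed) —
and assigns each group its **general dominance weight**: the average
incremental R² the group adds over all subsets of the other groups,
enumerated exhaustively (2³ subsets).  Weights sum to the full-model R²
by construction; shares are the weights renormalized over the three
groups, so residual variance is excluded — matching the three-component
stacked presentation of the reference study, and noted as an
interpretive choice.  Per-year cross-sections (rather than one pooled
model with a year covariate) follow the annual "relative uncertainty"
curves; the alternative is a one-line change in `dominanceShares()`.
Conditional and complete dominance are computed and returned, but only
general dominance feeds the shares.

The temperature-only experiment refits the same retained roster with
the environmental covariate set collapsed to the archetype's single
temperature variable (so its "E" members are exactly the Temp configs),
keeping the structural parameterization labels for the dominance
factors.

## Numerical choices and degenerate inputs

* Seeds: one master seed; every stage derives child seeds via a fixed
  FNV-1a hash of (module, ESM, member) keys, so adding an ensemble
  member never perturbs another's random stream.
* Stage memoization: with a cache directory, completed stages are
  stored keyed by a content hash of the configuration and loaded on
  re-run.
* Zero-range reference covariates in NT1 are in-range only at equality,
  otherwise an error; a constant response in the dominance analysis
  returns zero weights with a warning; single-class years yield NA AUC
  and constant years NA correlation, and both are excluded from window
  means.
* Sharp presence conversions can separate the training classes; the
  occurrence GLMs are fitted with warnings suppressed and evaluated as
  probability rankings (AUC), never thresholded.

## What the defaults do and do not show

The default experiment (0.5° grid, 500 samples/year, 12 + 12 member
fits per archetype × ESM, master seed fixed) reproduces the qualitative
findings the package is built around: near-ceiling training fits,
progressive projection-skill decay, monotone growth of environmental
novelty with a negative novelty–skill coupling, ESM-dominated
uncertainty in the first projection decades with SDM-structure
uncertainty overtaking it late in the century, and a further shift
toward SDM uncertainty when models are starved down to temperature
only.  Problem sizes for tests were chosen as the smallest that leave
these signals unambiguous.

Passing tests on this synthetic world do **not** establish realism of
any single projection: the operating models omit density dependence,
species interactions, movement, age structure and observation error;
the forcing emulator has no mesoscale dynamics, no real coastline, and
exactly linear forced trends.  Conclusions are about the *relative*
behavior of estimation models under controlled, divergent forcing.
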