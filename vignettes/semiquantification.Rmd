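---
title: "Semi-quantification of PFASs from QSAR-predicted ionization efficiencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantification of PFASs from QSAR-predicted ionization efficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Electrospray response is, over a working calibration range, linear in
analyte concentration, so the slope of the peak-area vs mass-concentration
line is an operational ionization efficiency (IE). Absolute slopes depend
on source geometry, mobile phase and tuning, which is why `ieqsar` works
exclusively with *relative* efficiencies against an anchor compound
(default FHUEA): for compound $i$ with slope $S_i$ (area per ng/mL) and
molecular weight $M_i$ (g/mol),

$$\log \mathrm{IE}_i \;=\; \log_{10}\!\left(
   \frac{S_i}{S_\mathrm{anchor}} \cdot
   \frac{M_\mathrm{anchor}}{M_i}\right),$$

the molecular-weight ratio converting mass-based slopes to a molar
response ratio. The anchor's own value is identically 0. Inverting for an
unknown with measured area $A$ and model-predicted $\widehat{\log\mathrm{IE}}$,

$$C_\mathrm{pred} \;=\;
  \frac{A \, M_\mathrm{anchor}}
       {10^{\widehat{\log\mathrm{IE}}}\, S_\mathrm{anchor}\, M}.$$

Two modelling commitments follow from this pair of equations:

* **Slope-only inversion.** Calibration intercepts are estimated and
  reported (they are useful diagnostics) but never used in the inversion.
  A consequence — visible in the synthetic benchmarks — is a bias at
  concentrations comparable to `intercept/slope`, i.e. at the lowest
  calibration levels. This is a property of the method, not a bug.
* **Unweighted OLS.** Calibration lines are fitted by ordinary least
  squares with a free intercept. No 1/x weighting and no forcing through
  the origin; with only six calibration points and areas spanning two
  orders of magnitude, weighting choices change slopes by less than the
  run-to-run area noise, and the free intercept keeps the intercept-bias
  diagnostic available.

Fold-space error metrics complete the framework: the symmetric IE fold
error $\max(p/a,\, a/p) \ge 1$, the directional concentration error $p/a$,
and a log-space RMS fold factor $10^{\sqrt{\overline{\log_{10}^2 e}}}$.
The latter is deliberately *not* the arithmetic RMS of the fold errors: an
arithmetic RMS of values that are all $\ge 1$ can never sit below their
mean, so a dispersion summary reported alongside a median of ~1.04 and a
mean of ~1.10 is only coherent in log space. `summarize_errors()` computes
both (`rms_fold` and plain `rms`); the geometric form is the headline.

## Feature cleaning and selection

A PaDEL-style 2D descriptor export has ~1 400 columns; a calibration study
has a few dozen compounds. The cascade reduces the space in three
deterministic stages before any supervised selection:

1. **Missing/non-finite columns are deleted**, not imputed. With 50 rows
   there is no basis for imputing a descriptor; deletion is the only
   defensible policy at this scale.
2. **Near-zero-variance filter**: a column is dropped when its most
   frequent value outnumbers the runner-up by more than `freq_ratio = 19`
   (i.e. 95/5) *and* fewer than `unique_pct = 10` % of its values are
   distinct. These are the long-standing defaults of the R modelling
   ecosystem (caret), and `ieqsar` calls `caret::nearZeroVar()` directly.
3. **Correlation filter** at $|r| > 0.8$ via `caret::findCorrelation()`
   (exact mode): repeatedly remove, from the worst remaining pair, the
   member with the larger mean absolute correlation. Greedy, order-stable,
   and auditable — after the stage an exhaustive pairwise scan of the
   survivors finds no $|r| > 0.8$, and the test suite performs exactly that
   scan. The absolute value is used; a strongly negatively correlated pair
   is just as redundant as a positive one.

Recursive feature elimination then ranks the survivors by random-forest
permutation importance and scores candidate subset sizes (default
`{5, 10, 18, 30, 60}`) by repeated cross-validation (5 folds x 5 repeats).
The selected size minimises mean CV RMSE with ties broken toward the
smaller size; `tol_se` optionally switches to a one-standard-error-style
rule (smallest size within `tol_se` SE of the minimum), which is the
natural choice when the response is expected to be mostly noise.
Permutation importance (unscaled) rather than impurity importance is used
for ranking because impurity measures inflate under correlated
descriptors, which this feature space has by construction. All resampling
is derived from a single seed, so an identical call reproduces the
`selection_report` bit for bit.

Selection runs on all compounds by default, matching the workflow order of
the original study design (preprocessing precedes the train/test split);
`rfe_on = "train"` in `run_synthetic_pipeline()` (or `exclude_ids` in
`cmd_select()`) gives the stricter leakage-free variant for users who want
selection blind to the held-out compounds.

## The three model families

* **Elastic net** (`glmnet`): mixing parameter over `{0.1, ..., 1.0}`,
  penalty over glmnet's internal path, tuned by cross-validated RMSE with
  shared fold assignments. Features are standardized inside the glmnet
  path only — tree models see raw descriptor values.
* **Random forest** (`randomForest`): 500 trees; `mtry` over
  `{p/3, sqrt(p), p/2}`.
* **Gradient-boosted trees** (`xgboost`): depth `{2, 3, 4}` x learning
  rate `{0.05, 0.1, 0.3}`, number of rounds chosen by early-stopped CV
  (cap 500, patience 25), single-threaded for reproducibility.

The grids are deliberately small: with ~40 training compounds, wide grids
select noise. Tuning, fold assignment and final refit all derive from one
seed, so `train -> evaluate` twice with the same seed is bit-identical
(the suite asserts this). A zero-variance response short-circuits to a
constant model flagged `degenerate`, with $R^2$ reported as 0 rather than
`NaN`.

Feature importances are normalized to sum to one and sorted with
alphabetical tie-breaks: absolute standardized coefficients for the
elastic net, non-negative permutation importance for the forest, split
gain for boosting.

## What the synthetic generator emulates

`generator_config()` encodes the study conditions the package is
benchmarked under: 50 compounds, six calibration levels at 0.2/0.5/1/2/5/10
ng/mL, a 200-column descriptor table (standing in for a full PaDEL export
at desk scale), 18 informative descriptors, a 42/8 train/test split.

Structure of the generated data, and why:

* **Informative descriptors as redundant proxies.** The 18 informative
  columns are noisy proxies (within-group $r = 0.6$, safely under the 0.8
  cleaning cutoff) of two latent molecular factors, in equal groups of
  nine. This mirrors how real 2D descriptors behave: dozens of
  size/connectivity descriptors track fluorinated chain length, and a
  second cluster tracks head-group character — the two axes along which
  PFAS ionization chiefly varies. It also makes the selection problem
  honest: every informative column genuinely carries signal, yet no small
  subset is sufficient, so cross-validated RFE has a real optimum near the
  full informative set.
* **The latent IE surface** is a smooth monotone function of the primary
  factor with a saturating component, plus a weaker secondary term and a
  mild interaction, rescaled so the anchor-relative values span 2 log10
  units — a 100-fold IE range, consistent with relative efficiencies
  observed for PFAS panels (lowest relative IEs below 0.1). `ie_mode =
  "linear"` drops the nonlinear pieces (elastic-net sanity checks);
  `ie_mode = "step"` produces threshold-and-interaction-dominated
  structure, the regime in which tree ensembles must beat linear models
  and which the algorithm-ordering benchmark uses.
* **Calibration realism**: areas are
  $\mathrm{intercept} + S\,c\,(1 + \varepsilon)$ with multiplicative noise
  $\varepsilon \sim N(0, 0.02)$ (a few percent area CV, typical of
  replicate LC-HRMS peak areas) and half-normal intercepts scaled to 5 %
  of the slope, which reproduces the observed degradation of low-level
  predictions. IE measurement noise is 0.03 log10 units, consistent with
  the residual scatter a well-behaved panel shows. Setting all three noise
  parameters to zero makes the whole pipeline exact: fitted slopes equal
  true slopes and the concentration inversion returns every nominal level
  to machine precision — the basis of the round-trip tests.
* **Planted defects**: 10 % of columns are made near-constant, 5 % get
  missing cells, and part of the noise columns form correlated blocks
  (block $r$ configurable, 0.9 by default) — one planted target for each
  cleaning stage, so the cascade can be audited column by column.

All randomness flows from one master seed through a drawn set of per-stage
sub-seeds, so each generator stage is independently reproducible.

What the generator does **not** emulate: chromatography, matrix effects,
ion suppression by co-eluting compounds, adduct chemistry, detector
saturation, or any relationship between a real molecular structure and its
descriptors. Passing the synthetic benchmarks therefore demonstrates that
the *pipeline machinery* is correct and that the method behaves as
designed under its own assumptions — not that any particular accuracy will
be achieved on a new instrument or compound class.

## Problem sizes and known limits

The packaged benchmarks run the default study conditions (50 x 200, RFE
over five subset sizes with 5x5 resampling) and a 200-compound variant for
the algorithm comparison; these sizes keep the full suite in the
low-minutes range on a single core while preserving the statistical
character of the full-scale problem.

Two desk-scale limits are worth stating plainly, because they are
properties of the statistics rather than of the implementation:

* With 42 training compounds, tree-ensemble test RMSE on the synthetic IE
  surface sits around 0.15-0.25 log10 units. The *median* fold error over
  a 50-compound panel is dominated by the training compounds and lands
  near 1.0, but the *worst-case* held-out compound regularly exceeds
  2-fold — a small-sample reality that also bounds what any 50-compound
  QSAR-IE study can promise for its worst prediction.
* The choice between 10 and 18 retained descriptors is worth only ~0.01-
  0.02 CV RMSE, which is close to the resampling noise at this scale;
  the selected size is therefore reproducible only under a fixed seed.

Other limitations: the anchor must have a positive, well-determined slope
(everything is conditioned on it); results transfer across instruments
only if the anchor-relative formulation actually removes the instrument
effect, which for strongly tuning-dependent analytes it may not; and
descriptor computation itself (PaDEL or otherwise) is outside the package
— descriptor tables are consumed as files.
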