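---
title: "Backcasting songbird occurrence from repeat photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backcasting songbird occurrence from repeat photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Repeat oblique photography gives a land cover record that predates bird
surveys by decades: a historical survey photograph and its modern repeat,
both classified into a common set of land cover categories, measure the
landscape at two times from the same viewpoint. `photobackcast` combines
that record with species distribution models (SDMs) fitted on
contemporary surveys to *backcast* bird occurrence: if a model describes
how the probability of occurrence of a species depends on the land cover
composition around a site, and the composition of a photographed
landscape is known for both epochs, the model predicts occurrence at both
epochs, and the paired difference across photo stations estimates a
century of change.

The SDM is a binomial generalized linear model with a logit link. At each
survey site, songbirds are sampled at $k = 9$ sampling units and each
unit is treated as a Bernoulli trial, so the response is a detection
count $y \in [0, 9]$. Non-detections are treated as temporary emigration
from the range of detection — genuine zeros, not false absences; the
probability-of-false-absence summary $\mathrm{PFA} = (1 - p)^k$
(`pfa()`) quantifies why that is defensible when per-occasion
detectability $p$ is high ($\mathrm{PFA} < 0.15$ is flagged reliable).
The linear predictor is

$$\operatorname{logit} P \;=\; \beta_0 + \sum_j \beta_j x_j,$$

where $x_j$ is the **percent** (0–100) of category $j$ within a circular
buffer around the site. The percent convention matters: published
coefficient magnitudes of, say, 0.04 per unit conifer only make sense per
percentage point, and every module in the package shares the convention.

Three model-selection devices are layered on the GLM:

- **VIF screening** (`vif_screen()`): covariates are retained only while
  all variance inflation factors $1/(1 - R_j^2)$ are below 3, dropping
  the worst offender iteratively. Because compositions are closed (the
  categories sum to 100%), the full category set is always exactly
  collinear with the intercept; the screen removes one category
  automatically, which is the standard resolution for compositional
  covariates.
- **Bidirectional stepwise AIC** (`stepwise_aic()`): starting from the
  full screened model, all single-term deletions and additions are
  scored and the lowest-AIC move taken until no move lowers AIC. AIC
  (not AICc) is used, matching the convention of the stepwise tools this
  emulates; AICc can be obtained by post-hoc correction if desired.
- **Characteristic-scale selection** (`select_scale()`): the screen and
  the stepwise search are run independently at every radius of the
  250–4500 m grid (250-m steps), and the radius whose selected model
  attains the lowest AIC is the species' characteristic scale of
  selection. The paper trail of per-radius AICs is kept on the fit.

Backcasting (`predict_occurrence()`, `backcast_pairs()`) is the logistic
back-transform of the fitted model applied to the historical and modern
composition of each photo pair. Change is then assessed per species with
a paired two-sided Wilcoxon signed-rank test and a bootstrap percentile
CI on the mean change; a species is classified *increased* or *declined*
only when the CI excludes zero. Uncertainty in the coefficients is
propagated by re-running the whole backcast with every coefficient
(including the intercept) shifted simultaneously to $\beta - SE$ and
$\beta + SE$ (`sensitivity_analysis()`); a result is direction-consistent
when the sign of the mean change agrees across the three scenarios.

## Photo alignment

Historical and repeat photographs are registered from manually selected
tie points on unchanging features. `estimate_affine()` solves the
least-squares 6-parameter affine mapping historical pixel coordinates to
repeat coordinates (exactly interpolating three non-collinear points);
a 4-parameter similarity (rotation, isotropic scale, translation) is
offered because alignment tools described as "translation, rotation and
scaling" may estimate only that subfamily — the default is the full
affine, and the choice is recorded in the transform metadata. Pixel
coordinates are 0-based with x = column, y = row, origin top-left.

Labels are categorical, so `apply_transform()` resamples strictly by
nearest neighbour; interpolating between category ids is never
meaningful. The historical image is warped onto the repeat image's grid
(the repeat photograph is the higher-quality frame and keeps native
geometry); output pixels whose source falls outside the input become
invalid, and validity masks travel with the labels. Registration quality
is summarized as RMS tie-point residual; pairs above 3 px (the "few
pixels" working standard) are flagged but retained — exclusion is an
analysis-level choice that stays visible in the run log.

## Land cover accounting

`composition()` counts label proportions over *valid* pixels only
(foreground and uncertain areas are masked out of both images), reporting
every scheme category, absent ones at 0%. Landscape diversity is
Shannon's index in natural log units (`shannon_index()`), the default of
the vegan package and the index most sensitive to the rare categories
(alpine meadows, wetlands) whose fate is of interest; other bases are a
parameter.

`wilcoxon_signed_rank()` is implemented from first principles because the
exact small-sample distribution is central here: zero differences are
dropped, midranks handle ties, and for $n \le 25$ untied differences the
two-sided p-value is exact, computed from the full distribution of the
rank-sum over all $2^n$ sign assignments (generating-polynomial
recursion; counts are exact in double precision at these n). Otherwise a
normal approximation with tie correction and continuity correction is
used. With 46 photo pairs the test therefore uses the approximation, as
any standard implementation would; both branches are cross-checked
against enumeration and against the reference implementation in the test
suite.

"Percent change" for a category is the change in percentage points
(after − before), matching how such results are reported (e.g. "from
40.1% to 52.5%"); relative change is available behind an option. CIs are
10,000-resample bootstrap percentiles over photo pairs with an explicit
seed; no multiple-testing correction is applied by default (none is
conventional here), with Holm adjustment behind a flag.

## The synthetic world

The generator exists so every stage has a ground-truth recovery test
without any field data download.

- `generate_landscape()` emulates a Landsat-like thematic map: white
  noise is boxcar-smoothed (separable, circular boundaries) with
  half-width `autocorr_length` cells and sliced at composition-matching
  quantiles, so categories occupy contiguous level sets and realized
  pixel fractions match the target to within one cell. Defaults used in
  the recovery experiments: 200 × 200 cells of 250 m (a 50-km park-scale
  extent in which 4500-m buffers fit), smoothing half-width 6 cells
  (≈1.5 km vegetation-belt patchiness, which makes buffer composition
  genuinely scale-dependent across the radius grid), and a
  conifer-dominated five-category composition (40% conifer, 15% shrubs,
  20% herbaceous, 10% wetland, 15% barren).
- `simulate_surveys()` draws detection counts as $k$ Bernoulli trials
  with success probability given by the logistic truth evaluated on the
  site's buffer composition at the truth's characteristic radius. The
  default truth in the experiments mirrors a conifer/shrub associate:
  intercept −4.41, +0.04 per % conifer, +0.06 per % shrub at 1250 m.
  An optional `detection_p < 1` thins detections to exercise the PFA
  computation; the default of 1 encodes the temporary-emigration
  interpretation of zeros.
- `generate_photo_pair()` produces a modern mask by independent
  per-pixel category transitions at specified rates (so expected
  compositional change is known), a historical mask warped by a known
  affine, and noisy tie points — making alignment, accounting and
  backcast classifications all checkable against truth.

What the generator does *not* emulate: photographic rendering (haze,
exposure), classification error, the oblique pixel-footprint geometry of
real photographs, spatially structured detection error, and species
interactions. Passing recovery tests therefore demonstrates the
statistical machinery is correct and unbiased under the stated model —
not that field classifications are accurate.

## Numerical choices and degenerate inputs

- The GLM is fitted by iteratively reweighted least squares with a
  relative coefficient-change tolerance of $10^{-10}$ (cap 100
  iterations); standard errors come from the inverse Fisher information.
  Fitted probabilities are clamped away from 0/1 at $10^{-12}$ for
  numerical stability. Quasi-separation is flagged when any coefficient
  exceeds 50 in magnitude or any site's linear predictor exceeds 20 —
  with percent-scale covariates the latter catches separation long
  before the former.
- `validate_model()` requires convergence, no separation, dispersion
  (residual deviance / residual df) within [0.3, 3], and a non-constant
  design column for every term; failures carry reasons. Constant columns
  get NA coefficients rather than an error so the failure is visible in
  diagnostics.
- Stepwise ties are broken deterministically: deletion before addition,
  then alphabetical term order. Scale ties go to the smaller radius.
  The VIF screen drops the first-indexed covariate among equally worst
  (infinite) VIFs.
- Buffers are edge-truncated (cells beyond the raster leave the
  denominator) rather than dropping edge sites; the truncated fraction
  is reported per row so users can filter.
- All randomness flows through explicit seed arguments; no function
  touches the global RNG state without restoring it.

## Decisions where the design was genuinely open

- **Link function.** Descriptions of this analysis mix "log link" and a
  logit back-transform; the worked occurrence equation is logistic. The
  package implements the logit link — the only choice under which
  published coefficient magnitudes and the worked equation cohere — and
  rejects other links explicitly in the pipeline config.
- **PFA formula.** The compact notation "1 − p k" is read as
  $(1-p)^k$, the standard probability that a present species is missed
  on all $k$ occasions; the alternative reading $1 - p^k$ is not a
  false-absence probability. The benchmark threshold 0.15 mirrors a
  worst-case detectability near 0.147.
- **Stepwise loop order.** Scale and covariates are described as chosen
  jointly by stepwise AIC; the package runs the stepwise search within
  each radius and compares radii by AIC afterwards — the standard
  pseudo-optimization loop — and records the whole profile.
- **Community diversity.** Shannon diversity of bird occurrence has no
  unique construction from occurrence probabilities. Two defensible
  summaries are emitted: Shannon of renormalized probabilities
  $q_s = P_s / \sum_s P_s$ (relative occurrence as proportional
  abundance) and expected species richness $\sum_s P_s$. Neither is
  claimed to be canonical.
- **CI construction.** Published per-species intervals do not state
  their method; the package uses bootstrap percentile intervals over
  photo pairs (10,000 resamples, seeded). A normal-approximation CI on
  the mean change is the logged alternative.
- **Classification rule.** "No substantial change" is operationalized as
  the bootstrap CI containing zero.
- **Intercept rounding.** Coefficient tables sometimes print an
  intercept (−4.41) that differs in the last digit from a worked
  equation (−4.42); the loader accepts either, treating the difference
  as rounding.

## Problem sizes in the verification suite

The package's own verification (tests and `scripts/acceptance.R`) uses
sizes chosen to make Monte-Carlo bands tight while keeping a full run in
minutes on a laptop: 200 exact-Wilcoxon instances at $n \le 12$ against
full enumeration; 20 GLM instances against an independent BFGS likelihood
maximizer; 1000 random compositions for Shannon; 100 random affines plus
noise-scaling checks; 200 survey replicates of 500 sites for coefficient
(3-SE coverage) and scale recovery on the full 18-radius grid; and a
20-pair end-to-end transition scenario for sign recovery with the exact
zero-change control.

## Limitations

Backcasting assumes temporal stationarity of habitat association over
the century — reasonable relative to eco-evolutionary time scales, but
untestable from these data alone. Models omit landscape configuration,
interspecific interactions, and any covariate not expressible as buffer
composition. Only species with enough detections to fit a validated
model are represented, which biases community-level summaries toward
common species. And the deposited-data reproduction tier requires the
original study archive; it is not redistributed with the package.
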