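---
title: "Scan-quality control by propensity matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-quality control by propensity matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical groups move more in the MRI scanner than controls. Motion blurs
tissue boundaries, worsens partial voluming, and systematically lowers
apparent gray-matter volume (GMV), most strongly along the gray/white
boundary. Because motion also degrades automated image-quality metrics, scan
quality becomes a group-correlated confound: a voxel-based morphometry (VBM)
comparison can "detect" anatomy that is really noise. The two standard
responses both have costs. Including everyone leaves the confound in place;
excluding scans below a quality threshold (conventionally a 70% overall
image quality rating) preferentially removes the most clinically affected
participants and shrinks the sample.

`qcmatch` implements a third protocol: balance scan quality *between*
groups by 1:1 propensity-score matching on automated quality metrics, so
that low-quality scans stay in the analysis but no longer differ
systematically by group. The package provides the full comparison pipeline —
simulation, propensity estimation, exact optimal matching, balance
diagnostics, quality-control protocols, site harmonization, and VBM with
permutation familywise-error (FWE) control — so the three protocols can be
compared end to end on data with known ground truth.

## Quality metrics

Three automated metrics drive matching, following common automated
quality-assessment practice:

* `iqr_pct` — overall image quality rating, a percent grade averaging
  resolution, noise, and bias grades; higher is better.
* `euler` — mean surface Euler number from surface reconstruction; tracks
  topological complexity of the gray/white boundary and is highly sensitive
  to noise; higher is worse.
* `defect_pct` — percent of the cortical surface affected by topological
  defects; higher is worse.

## Propensity model and matching

The propensity score is the modeled probability of treated-group membership
given the quality covariates, estimated by maximum-likelihood logistic
regression (iteratively reweighted least squares with internally
standardized covariates; coefficients are reported on the original scale).
Zero-variance covariates are dropped; collinear designs and complete or
quasi-complete separation raise errors rather than silently returning
divergent coefficients, since a separated fit produces degenerate distances.

Matching minimizes the total absolute distance between paired scores. The
distance defaults to the *logit* (linear-predictor) scale — the standard
recommendation, since logit differences are stable where probabilities
saturate — with the probability scale available by flag. The 1:1 optimal
match is solved exactly as a minimum-cost bipartite assignment (a
Jonker–Volgenant/Hungarian shortest-augmenting-path solver in C++); a greedy
nearest-neighbour variant is provided for comparison and is never better
than the optimal solution. Options mirror the standard repertoire for
difficult matches:

* **caliper** — a maximum admissible distance, expressed as a multiple of
  the pooled SD of the logit scores (0.2 is the conventional width);
* **exact** — categorical variables on which pairs must agree; matching is
  solved independently within each stratum;
* **common support** — discard treated subjects whose logit lies outside
  the control range;
* **tiered matching** — match on the most important metrics first, then
  re-fit and re-match on the next tier within the matched sample.

Discarding is off by default (pure optimal matching pairs every treated
subject when controls suffice); with `discard_unmatchable = TRUE`,
infeasible treated subjects are recorded with a reason
(`no_candidate_in_caliper`, `empty_exact_stratum`,
`insufficient_controls`, `outside_common_support`). Ties are broken
lexicographically by subject id, and equal-cost pairings are normalized so
results are deterministic.

**Design note — equal-sized groups.** With equal group sizes and no
discarding, 1:1 matching retains everyone and cannot change balance. A
matching *protocol* that is expected to improve balance must therefore be
allowed to discard: the pipeline default applies the 0.2-SD caliper with
discarding enabled, trading a few extreme subjects for balance, which is
exactly the trade the caliper literature describes.

## Balance diagnostics

Balance is quantified by standardized mean differences (SMD): the group
mean difference divided by a reference SD, with `|SMD| < 0.1` the
conventional criterion. The reference SD is the pooled
(average-of-variances) SD computed on the *unmatched* sample and reused for
the post-matching SMD, so the pre and post values share one scale. A
synthetic `distance` row reports balance on the propensity logit itself.
Variance ratios are included as a secondary diagnostic (an extension beyond
SMD reporting). Love-plot data (covariate x phase x SMD, with the 0.1
reference recorded in the header) is exported as TSV for plotting.

## Quality-control protocols

* `full_inclusion` — identity.
* `exclusion` — drop records with `iqr_pct` strictly below the threshold
  (default 70%). "Below" is read literally: a scan exactly at 70.0 is
  retained; the boundary behavior is unit-tested.
* `matching` — fit the propensity model on the three quality metrics,
  solve the 1:1 optimal match, and keep the paired subjects (equal group
  sizes by construction).

Between-group scan-quality comparisons use the Welch (unequal-variance)
two-sample t-test by default — the paper-style tables report per-group
(min, max) ranges, t, Welch–Satterthwaite df, two-sided p, and the Pearson's
r effect size `r = sign(t) * sqrt(t^2 / (t^2 + df))`. A pooled-variance
option exists for sensitivity. All p-values are two-sided.

## Site harmonization

Multi-site voxel data are harmonized with the parametric empirical-Bayes
location/scale batch model: for subject $i$ at site $s$ and feature $v$,

$$y_{isv} = \alpha_v + x_i^\top \beta_v + \gamma_{sv} + \delta_{sv}\,\varepsilon_{isv}.$$

Fitting standardizes each feature by the full design (site indicators plus
protected covariates — group, age, sex by default, so biological
variability is preserved), estimates per-site locations and scales on the
standardized residuals, and (with `eb = TRUE`) shrinks them with a normal
prior on locations and an inverse-gamma prior on squared scales,
hyperparameters by method of moments, the coupled solution iterated to
relative tolerance 1e-6. With `eb = FALSE` the raw per-site estimates are
used, which *exactly* equalizes covariate-adjusted site means.

Numerical conventions: per-site scales use the MLE ($1/n_s$) denominator,
the same convention as the pooled variance, which makes the no-covariate
location/scale adjustment an exact fixed point (harmonizing twice changes
nothing); with protected covariates the second pass perturbs coefficients
only at the sampling-noise level. Zero-variance features pass through
untouched and are recorded on the model. A single-site dataset yields a
no-op model by construction. Harmonization operates on the unsmoothed voxel
matrix and precedes smoothing, and protocol selection happens after
harmonization and smoothing (both use all subjects); re-harmonizing on a
selected subset is available for sensitivity analysis.

## Voxel-based morphometry

**Smoothing.** Separable Gaussian smoothing with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis (8 mm FWHM isotropic by
default, so $\sigma = 3.3972$ mm), converted to voxels via the affine
(axis-aligned affines only). The convolution is mask-normalized — the
smoothed image is divided by the smoothed mask — so in-mask constants are
preserved exactly and no intensity bleeds across the mask edge.

**Per-voxel GLM.** Ordinary least squares of each voxel on
intercept + group + nuisance covariates (total intracranial volume, age,
sex dummy), $t = c\hat\beta / \sqrt{\hat\sigma^2\, c (X^\top X)^{-1} c^\top}$
with $\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank})$. Voxels with
numerically zero residual report a $\pm\infty$ sentinel t with the smallest
attainable p and are counted, not dropped.

**FWE correction.** Voxel-level FWE control uses the permutation maxT
distribution with the Freedman–Lane scheme for nuisance covariates: the
nuisance-only model is fitted, its residuals are permuted and added back to
the nuisance fit, the full model is refitted, and the maximum |t| over the
mask is recorded per permutation;
$p_{\mathrm{FWE}}(v) = (1 + \#\{\max T \ge |t_v|\})/(n_{\mathrm{perm}}+1)$.
This replaces parametric random-field correction deliberately: the
permutation test is exactly valid at any mask size and makes no smoothness
assumptions. When fewer distinct permutations exist than requested they are
enumerated exhaustively.

**Clusters.** The suprathreshold set (voxel-level FWE $p \le \alpha$,
default 0.05) is decomposed into connected components (26-connectivity by
default, 6 available), components below the extent threshold `k` are
dropped, and within each cluster the global |t| peak is reported plus any
local maxima farther than 8 mm (world distance) from every
already-reported peak, greedily in descending |t| — the conventional
distinct-peak rule. Coordinates are world mm via the affine; Cohen's d at
peaks is $d = t\sqrt{1/n_1 + 1/n_2}$. `k` can be supplied or derived from
the permutation null's cluster sizes (`empirical_extent_threshold`: the
smallest k whose null exceedance rate is at most 5%).

## The synthetic cohort generator

The generator is first-class, tested code: it produces cohorts carrying the
confound structure the pipeline exists to handle, with full ground truth.

* **Motion** is lognormal — nonnegative and right-skewed, matching motion
  phenomenology — with the group difference entering on the log scale:
  `log m ~ N(mu + shift * treated, sd^2)`, default shift 0.5 and sd 0.3.
  The lognormal choice also gives closed-form moments for tests.
* **Quality metrics** are linear in motion plus Gaussian noise, clipped to
  valid ranges (a mild nonlinearity at the extremes): quality grades fall
  with motion, Euler number and defect size rise. The default intercepts,
  slopes and noise SDs are calibration choices (no published motion-to-metric
  slopes exist); they are set so that a shifted cohort's image quality
  rating spans roughly the low-50s to high-80s percent range reported for
  large multi-site clinical releases.
* **Voxel data**: in-mask value = smooth baseline field + blob amplitude
  for treated subjects + motion artifact + site effects + noise. The
  artifact is linear in motion with separate boundary-shell and interior
  slopes (defaults 1.0 and 0.2 GMV units per unit motion), both *reducing*
  gray matter as motion rises — the direction the artifact literature
  reports; the linear form is a modeling choice. Site effects are additive
  offsets plus multiplicative noise scaling, the same location/scale form
  the harmonization model removes. The analysis mask is a centered sphere;
  the boundary shell is its outer rim. The default grid is 12x12x12 at
  3 mm voxels — deliberately desk-scale; simulation sizes of 40/40 to
  100/100 subjects are used throughout the validation suite.

What the generator does **not** emulate: template anatomy, k-space/ringing
artifacts, spatially correlated subject noise, nonlinear metric responses,
or site-by-group interactions. Passing tests therefore demonstrate the
statistical machinery under the stated model, not performance on real MRI.

## What the validation shows — and a known limitation

The test suite verifies, among others: exact agreement of the matching
solver with an exhaustive dynamic-programming oracle; agreement of the
logistic fit with an independent numeric-Hessian Newton oracle; balance
improvement (and mean post-match |SMD| < 0.1) on confounded 100/100
cohorts under the caliper protocol; nominal FWE of the permutation VBM on
null cohorts; site-mean equalization and shrinkage behavior of
harmonization; and better recovery of the true effect size (Cohen's d at
the true blob peak, against an artifact-free same-noise counterfactual) by
the matched protocol than by full inclusion.

One validation check is deliberately left failing rather than papered
over: with the default calibration, a motion artifact and *no* true
effect, the matched protocol's FWE rejection rate (~0.17) stays somewhat
above the nominal band even though full inclusion rejects at rate ~1.
Diagnostics show why: matching can only balance what the metrics measure.
The quality metrics observe motion with noise (measurement error SD ~0.2
on the log-motion scale at the default calibration), so matched groups
still differ slightly in *true* motion (residual motion SMD ~0.28), and a
boundary artifact of 1 GMV unit per unit motion remains partly detectable.
With noiseless metrics the matched rate is exactly nominal. This is a
faithful property of quality-metric matching in general — residual
confounding survives in proportion to the proxy's measurement error — and
we keep the default calibration rather than tuning it to make the check
pass.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every headline
quantity from scratch: pre/post SMDs and matched sample size on a 100/100
confounded cohort, the Welch-t attenuation of the group quality gap, the
null FWE rate (60 replicate cohorts, 200 permutations), full-inclusion vs
matched rejection rates under the artifact-only confound, the percent
change in significant voxels for a cohort with a true effect, and Cohen's d
at the true peak under each protocol against the counterfactual truth. All
randomness derives from `--seed`.
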