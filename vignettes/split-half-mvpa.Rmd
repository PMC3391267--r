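---
title: "Behavior-sorted split-half pattern analysis: model, generator, and validation"
author: "patternsplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-sorted split-half pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistic

Face perception research distinguishes *holistic* representations — in
which the parts of a face and their canonical arrangement
(eyes-above-nose-above-mouth) are encoded interdependently — from
*parts-based* representations that encode features irrespective of their
configuration.  A sensitive way to ask which scheme a cortical region
uses is to test whether the *reliability* of its multi-voxel activation
pattern predicts behavior: if a region's pattern carries the information
the subject uses, its spatial pattern should be more reproducible on
trials answered correctly than on trials answered incorrectly — and for
a holistic region this advantage should appear only when the face
configuration is intact (veridical faces), not when the same parts are
spatially scrambled.

The statistic is the behavior-sorted odd/even split-half correlation.
For one subject and one region of interest (ROI):

1. estimate a response amplitude for every trial and voxel (trial-wise
   GLM betas);
2. split the session's runs by parity into an odd half and an even half
   (runs 1,3,5,... versus 2,4,6,...);
3. within each half, average the trial amplitudes of each *stimulus
   condition x behavioral response* cell (veridical/scrambled x
   correct/incorrect) across trials, giving four voxel patterns per half;
4. subtract, voxel by voxel, the mean across the four cells within each
   half ("cocktail-blank" centering), so that a shared activation
   profile cannot masquerade as cell-specific reliability;
5. Pearson-correlate the odd and even centered patterns of the same
   cell.

This yields four correlations per subject and ROI.  Group inference
treats them as a 2 x 2 within-subject factorial: every 1-df effect
(condition, response, their interaction) is the squared paired t of the
per-subject contrast score, with weights normalized so the score is a
difference of cell means; the effect size is partial
eta squared, $\eta_p^2 = F \, df_1 / (F \, df_1 + df_2)$.  Post-hoc
paired t tests compare correct against incorrect within each condition,
with the paired Cohen's $d = \bar{d}/s_d$.  A holistic region shows a
condition x response interaction with a correct-over-incorrect advantage
for veridical faces only; a parts-based region shows a response main
effect without the interaction.

## The synthetic cohort generator

No public data accompany this design, so the package pairs the analysis
chain with a generator whose ground truth is known exactly.  Every stage
of the analysis can then be validated by parameter recovery rather than
by eyeballing.

### Experimental design

`generate_experimental_design()` emulates an event-related session: per
run, 36 veridical and 36 scrambled 4-s trials plus twelve 2-s fixation
jitters in seeded-random order, an 8-s lead-in and lead-out, TR 2 s —
a 328-s run (164 scans).  `generate_localizer_design()` produces the
blocked localizer: sixteen 16-s category blocks (faces, objects, houses,
scrambled objects; one of each per quarter, seeded-random within
quarter) interleaved with five 16-s fixations — 336 s.  Within a block,
20 stimuli at 300 ms on / 500 ms off account exactly for the 16 s.
Trial order is a seeded random permutation rather than an optimized
counterbalancing sequence; `transition_counts()` exposes the realized
first-order transition structure so a user can check the balance that an
optimizer would have enforced.  Optimized orderings matter for design
efficiency on real noise, not for the validity of the statistics tested
here.

### Behavior

Each non-fixation trial receives a response: missing with probability
0.001 (matching a reported no-response rate under 0.1 %), otherwise
correct with per-condition probability 0.847 (veridical) or 0.727
(scrambled) — the group accuracies the generator is calibrated to.
Response times are shifted lognormal (shift 0.3 s, sdlog 0.25, median
0.55 s veridical / 0.75 s scrambled).  No printed RT summary exists to
anchor these; only the ordering veridical < scrambled is treated as a
constraint, and the RT parameters are free configuration.

### Ground truth: the stability model

The generative claim behind the method is that behavioral accuracy
tracks pattern reliability.  `make_ground_truth()` encodes this
minimally.  Each ROI holds one fixed spatial pattern per cell,
$p_{v,c} \sim N(\mu_{\text{cond}}, \sigma_p^2)$, and each cell a
*stability* $s_c \in [0,1]$.  A trial in cell $c$ then has true
amplitude

$$a_{v,t} = s_c \, p_{v,c} + (1 - s_c)\,\varepsilon_{v,t},
\qquad \varepsilon_{v,t} \sim N(0, \sigma_\varepsilon^2),$$

a convex mixture of the recurring pattern and fresh per-trial noise: at
$s_c = 1$ every trial reproduces the pattern exactly (split-half r = 1
in the noiseless limit); as $s_c \to 0$ nothing recurs and the
correlation tends to zero.  The scenarios set the stability table of the
fusiform-like ROI:

| scenario      | veridical correct | veridical incorrect | scrambled correct | scrambled incorrect |
|---------------|------------------:|--------------------:|------------------:|--------------------:|
| `holistic`    | base + effect     | base                | base              | base                |
| `parts_based` | base + effect     | base                | base + effect     | base                |
| `both`        | base + effect     | base                | base + effect/2   | base                |
| `null`        | base              | base                | base              | base                |

with defaults base = 0 and effect = 0.7.  An occipital-like ROI, when
present, carries the parts-based table under every non-null scenario, so
a two-ROI cohort reproduces the full dissociation (interaction in one
region, response main effect in the other, a region x response effect
for scrambled faces).

Two of these defaults deserve justification:

* **Null base stability of 0.** With the convex-mixture mechanism the
  expected split-half correlation of a cell depends on its trial count
  (more trials average away more per-trial noise).  Accuracy differs by
  condition, so correct/incorrect counts differ across cells, and *any*
  common positive stability would give the four cells systematically
  different expected correlations — a trial-count confound, the very
  artifact the matched-trial control (`match_trial_counts()`) exists to
  address, and not a null for the correlation contrasts.  Setting the
  common stability to zero makes every cell's correlation exactly
  mean-zero whatever the counts, which is the appropriate null for
  type-I calibration of the whole chain.  Under the effect scenarios
  the count dependence is real and intended — it is a property of the
  method, not of the generator.
* **Effect size 0.7.** The package commits to a default at which the
  design it emulates (13 subjects) is adequately powered: at effect
  0.7 the interaction test rejects in ≈96 % of holistic cohorts and the
  full holistic verdict (interaction + veridical-only post-hoc pattern)
  obtains in ≈90 %, while parts-based cohorts yield a response main
  effect without interaction in ≈92 %.  This value was chosen once, by
  the power requirement, and is documented configuration
  (`ground_truth$stability_effect`).

The mean amplitudes are $\mu_{\text{veridical}} = 1$,
$\mu_{\text{scrambled}} = 0.93$ ($\sigma_p = \sigma_\varepsilon = 1$):
the scrambled mean response is deliberately almost as strong as the
veridical one, so the pooled-magnitude control analysis
(`roi_mean_magnitude()`) finds little to distinguish the conditions —
reproducing the situation in which magnitude-based analysis fails and
only pattern reliability carries the effect.

### BOLD simulation and noise

`simulate_bold_run()` encodes the true amplitudes through the same
design-matrix construction the estimator uses: each compound trial's
boxcar convolved with the gamma HRF, weighted per voxel by $a_{v,t}$,
plus a constant baseline (100), a random-slope linear drift, and
stationary AR(1) noise (marginal SD `sigma_thermal` = 6, coefficient
0.3).  Using one encoding/decoding pair is what makes the
noiseless-recovery test exact; it also means the simulation cannot probe
HRF misspecification, which is out of scope.

Trial-beta estimation under the default noise has an empirical error SD
of ≈4.2 per beta (pattern units).  The amplitude-level simulation mode
(`level = "amplitude"`) exploits this: it draws the same behavior and
true amplitudes but replaces the BOLD round trip with additive
$N(0, 4.2^2)$ estimation noise.  The two levels agree on the
group-level statistics (checked in the test suite); the amplitude level
is two orders of magnitude faster and is what the large Monte-Carlo
studies use.

## The estimation chain

* **HRF** — gamma, $h(t) \propto ((t-\delta)/\tau)^\alpha
  e^{-(t-\delta)/\tau}$ with onset delay $\delta = 2.25$ s, dispersion
  $\tau = 1.25$ s, and shape exponent $\alpha = 2$ (the FS-FAST
  convention; the analysis stream this mirrors names only delta and
  tau), peak-normalized, peaking at $\delta + \alpha\tau = 4.75$ s.
* **Compound-trial boxcar** — a trial presents two images (0.7–1.2 s
  and 1.7–2.2 s after trial onset) judged with a single response, so the
  pair is modeled as one compound event.  The boxcar spans the
  stimulation window, trial start + 0.7 s to + 2.2 s (1.5 s).  The
  window is configuration (`stim_window`) because no canonical choice
  exists; any fixed window differs only in a scalar rescaling of all
  betas, which the split-half correlation ignores.
* **Convolution grid** — boxcars are convolved on a 0.1-s grid and
  sampled at scan acquisition midpoints $(k + 0.5)\,TR$.
* **Trial-wise GLM** — least-squares-all: one GLM per run with a
  regressor per trial, linear drift and constant (`drift_order = 1`).
  A least-squares-separate variant was considered and not implemented:
  with 4-s trials, TR 2 s and jittered fixation, adjacent-trial
  regressor correlations stay near 0.3, where LSA is unbiased and
  simpler.  Trial-regressor pairs with |r| > 0.99 abort estimation as
  unestimable.  Cell patterns are averages of trial betas; re-fitting a
  cell-level GLM per half is a near-equivalent alternative we did not
  take, since averaging is the direct reading of "averaged spatial
  pattern".
* **ROI definition** — the faces-vs-objects localizer contrast t map is
  thresholded one-tailed at p < 0.01 uncorrected (the contrast is
  directional), components are labelled under 26-connectivity (both
  exposed in config), and the component containing — or failing that,
  nearest to — the seed coordinate is returned, subject to a minimum
  size.  An empty result is an explicit signal (`roi_is_empty()`) so the
  subject is excluded from that ROI's group analysis by listwise
  deletion, with degrees of freedom reported from the subjects actually
  analyzed.
* **Smoothing** — separable Gaussian, $\sigma = FWHM / (2\sqrt{2\ln 2})$
  per axis in voxel units, edge-renormalized (constants are preserved
  exactly); FWHM 0 is the identity.  Split-half input is never smoothed;
  localizer smoothing is configurable.

## Degenerate inputs and numerical choices

Cells with no trials in a half, and centered patterns with zero
variance, propagate as flagged missing values — never as silent zeros —
and drop the subject from affected contrasts only.  Paired t with
zero-variance differences is reported as degenerate (no finite t);
`rm_anova_1df` maps that to F = 0.  Fisher's z transform of the
correlations is available (`fisher_z`) but off by default, matching the
convention of running the ANOVA on raw correlations.  Matched-trial
subsampling draws once per seed; a repeat-and-average variant is easy to
script but is not the default because the control is defined as a single
random selection.  All tests are two-tailed, no multiplicity correction
is applied, and verdicts use alpha = 0.05 (configurable).  The
least-squares solver is QR; singular designs fall back to the
Moore-Penrose pseudo-inverse with a warning.

## What the validation shows — and what it cannot

The test suite validates, among others:

* exact accounting of the default designs (328-s experimental runs,
  336-s localizer, 4-s trials);
* equality of the split-half implementation with a brute-force loop
  oracle to 1e-12, and of the 1-df contrast F with a full
  sums-of-squares repeated-measures ANOVA decomposition to 1e-8;
* exact inversion: generator to trial-beta estimator is the identity on
  amplitudes without noise (1e-6);
* ROI recovery: with the category effect (1.0) against white noise of
  SD 6, two unsmoothed localizer runs, Dice ≥ 0.8 against the true
  mask.  White noise is used here because the uncorrected threshold's
  nominal false-positive rate assumes exchangeable residuals; under
  unmodelled AR(1) the OLS t map's empirical false-positive rate roughly
  doubles and stray voxels attach to the component.  That is a property
  of uncorrected OLS thresholds, not of the component selection being
  tested;
* type-I calibration: 2000 null-scenario cohorts (13 subjects, 4 runs,
  one 28-voxel ROI — a reduced volume chosen so the study runs at desk
  scale), every test's rejection rate inside the 99 % binomial band
  around 0.05;
* scenario recovery: 50 cohorts per effect scenario at the default
  effect size, ≥80 % correct verdicts;
* behavioral calibration to 84.7 % / 72.7 % within three binomial
  standard errors at 3600 trials per condition.

The generator deliberately omits head motion, physiological noise,
spatially correlated noise, anatomical variability, and HRF variability
across voxels and subjects.  Behavioral heterogeneity between subjects
arises only from binomial and lognormal sampling around common
parameters; real between-subject variance is larger, so simulated group
effect sizes for the behavioral contrasts (especially RT) run higher
than empirical ones and should not be read as realistic.  Passing tests therefore establish the
*internal* consistency and calibration of the statistical chain — that
the pipeline finds exactly the structure that is present, at the
advertised error rates — not robustness to the artifacts of real
acquisitions.  Analyses of real data should treat motion correction,
physiological regressors and registration as upstream preprocessing
outside this package's scope, then enter at `analyze_session()` with
BIDS-style events tables, NIfTI volumes and ROI masks.

## Reproducibility

All randomness descends from one master seed; child seeds are derived
by stable hashing of (subject, run, purpose) labels, so regenerating any
stage in isolation reproduces it bit for bit.  `run_pipeline()` writes a
manifest with the configuration, its fingerprint, and every subject
seed; rerunning a configuration reproduces every artifact byte for
byte.
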