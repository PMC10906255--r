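---
title: "Methods: simulated LDI-MS fingerprints and the diagnostic workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated LDI-MS fingerprints and the diagnostic workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingermet)
```

# The problem

Laser desorption/ionization mass spectrometry (LDI-MS) with an inorganic
matrix records a plasma sample's small-metabolite content as a profile
spectrum in the low-mass window (here 100–400 Da). Metabolites appear
predominantly as singly charged cation adducts — [M+H]⁺, [M+Na]⁺,
[M+K]⁺ — and the vector of aligned peak intensities (the *metabolic
fingerprint*) is used as a holistic feature profile for classification:
healthy control (HC) versus chronic obstructive pulmonary disease
(COPD), and stable COPD (SCOPD) versus acute exacerbation (AECOPD).
`fingermet` implements the computational workflow — simulation,
spectral processing, sparse classification, biomarker screening,
annotation, enrichment, and power analysis — with every stage testable
against a synthetic ground truth.

# The synthetic-cohort generator

## Signal model

A cohort is generated from a *template library*: each metabolite
template carries a name, a monoisotopic mass, one cation adduct, a base
log-intensity, and a per-group additive effect. A spectrum is

$$ y(m) = A\,e^{-\delta (m - 100)} \;+\;
   \sum_j h_j \exp\!\left(-\frac{(m - c_j)^2}{2\sigma^2}\right)
   \;+\; \varepsilon(m), $$

with

* a single-exponential baseline (amplitude $A$, decay $\delta$ per Da),
  typical of low-mass LDI background;
* one Gaussian peak per template adduct, with **constant width**
  $\sigma$ across the window (default 0.08 Da; a shape parameter, not a
  noise parameter — `noise_none()` keeps it);
* jittered centers $c_j \sim \mathcal N(\text{adduct } m/z,
  \tau^2)$ (default $\tau$ = 0.02 Da);
* log-normal peak heights
  $\log h_j \sim \mathcal N(\mu_j + \Delta_j \sigma_{\log},\,
  \sigma_{\log}^2)$, where $\sigma_{\log} = \sqrt{\log(1 + \text{CV}^2)}$
  reproduces a target intensity coefficient of variation (default CV
  0.15, in the range reported for replicate nanoparticle-assisted LDI
  measurements);
* independent per-peak dropout (default probability 0.02) and additive
  Gaussian noise (default sd 5 intensity units), clipped at zero.

## Standardized effects

Planted group effects $\Delta_j$ are **standardized** (Cohen's *d* on
log intensity): the realized additive log shift is
$\Delta_j \sigma_{\log}$, so the natural-scale fold change converges to
$\exp(\Delta_j \sigma_{\log})$ and a two-class cohort with a single
planted marker of effect $\Delta$ has the binormal single-feature AUC
$\Phi(\Delta/\sqrt 2)$. This makes effect sizes comparable across noise
settings and lets closed-form oracles check the classifier. The
alternative convention (a raw log shift) would entangle the effect with
the noise level and break those oracles; in the noise-free limit a raw
shift would also be the only surviving signal, which is why the
generator treats $\sigma_{\log} \to 0$ as "no variation, no effect".

## Packing and ground truth

Differential templates are drawn from the embedded reference set (the
exacerbation markers lactic acid, 3-hydroxybutyric acid, uric acid,
malondialdehyde — up-regulated — and creatine, dimethylglycine,
threonine, fucose — down-regulated, followed by glucose and other common
plasma metabolites); the first half of the requested markers is planted
up, the second half down. Each marker gets a Na⁺ or K⁺ adduct (chosen at
random among those whose m/z fits the window); reference metabolites
whose adducts all collide with already-placed peaks are skipped — real
masses do collide at unit resolution (e.g. pyruvic acid [M+K]⁺ sits
0.06 Da from 3-hydroxybutyrate [M+Na]⁺). Background peaks are placed on
a jittered uniform grid with a guaranteed minimum spacing of $4\sigma$
(and $8\sigma$ clearance around planted markers); an impossible packing
raises an error rather than silently overlapping peaks. The ground-truth
manifest lists every planted (name, m/z, adduct, direction, effect) and
all background m/z; the m/z values are produced by the same adduct
calculator used for annotation, so the round trip is exact by
construction.

`simulate_feature_matrix()` draws the same log-normal intensity model
directly at the feature level, skipping spectral rendering. It exists so
that classifier and screening calibration studies can run at fingerprint
scale (hundreds of features, hundreds of samples) in seconds; the
spectral stage is exercised separately by the round-trip tests, which
verify that the spectrum→matrix path reproduces template intensities
(per-sample correlation > 0.999 in the noise-free limit).

## What the simulator does not emulate

No isotope patterns, matrix-cluster peaks, detector saturation,
fragmentation, correlated metabolite panels, or batch effects; features
are independent given the group. Consequently, passing calibration tests
demonstrates the *statistical machinery* is correct — recovery rates,
AUC values and power on real plasma data, where features are correlated
and effects are smaller, will differ.

# Spectral processing

* **Baseline**: rolling minimum over a `baseline_window` (default 5 Da)
  followed by a rolling mean of the same width, subtracted with a floor
  at zero. A constant spectrum maps to zero, and a second pass changes
  total intensity by < 1% (near-idempotence).
* **Smoothing**: Savitzky–Golay (moving polynomial of degree 2, default
  7 points) — symmetric, so peak apexes do not shift.
* **Peak detection**: local maxima above `snr_min` (default 3) times a
  robust noise floor — the larger of the MAD and the upper-quartile
  deviation of the detrended signal. The quartile term keeps the
  estimate calibrated when rectification piles intensities at zero (a
  pure-noise spectrum yields under 5% false peaks among its local maxima
  at SNR 3). In very dense spectra (~900 peaks in 300 Da) peak flanks
  inflate this floor and only the stronger peaks survive; the aligned
  feature count is therefore data-dependent output, not a target.
* **Centroiding**: Gaussian (log-parabolic) interpolation through the
  apex and its two neighbours, which is exact for Gaussian peaks and
  reaches well below 1 ppm on the simulator's profile spectra; a
  truncated intensity-weighted mean (the fallback when a neighbour is
  non-positive) carries a 10–20 ppm truncation bias for off-grid
  centers, incompatible with 5 ppm annotation.
* **Alignment**: pooled peak m/z are clustered by single linkage in one
  dimension — clusters split where the sorted gap exceeds `tol` (default
  0.2 Da, the unit-resolution LDI-TOF convention). This is exactly the
  single-linkage dendrogram cut at `tol`, verified against
  `hclust(method = "single")`. The feature m/z is the median member m/z;
  features present in fewer than `min_presence` (default 0.1) of samples
  are dropped; missing entries are 0 (absence of signal, not missing
  data — LDI intensity semantics).
* **Normalization**: every sample is scaled to the cohort-median raw
  total ion current, preserving within-sample relative abundances.
* **QC**: cosine similarity of each sample against its group's
  leave-one-out median profile (the reference excludes the scored
  sample, so a perfect score is not an artifact), summarized as the
  fraction of samples above 0.85; at the generator's default noise this
  fraction exceeds 0.95 by calibration. Replicate CVs are sd/mean × 100
  per feature, `NA` for zero-mean features.

# Sparse diagnosis

"Sparse learning" is realized as L1-penalized logistic regression — the
canonical sparse linear classifier, and the one whose refits define a
selection frequency for the biomarker screen. The solver is `glmnet`;
the surrounding procedure is the package's own so the permutation test
can rerun it identically:

1. standardize features with **discovery statistics only** (validation
   data are transformed, never refit — verified by a leak test);
2. a log-spaced penalty grid (50 values by default) from the
   data-derived maximum;
3. stratified, seeded cross-validation folds (default 5); per-fold
   held-out rank-AUC per penalty; the penalty maximizing the mean CV-AUC
   wins, ties to the sparser model;
4. refit on the full discovery set at the chosen penalty.

Both the tuned mean CV-AUC (`cv_auc`, the tuning statistic) and the
refit discovery AUC (`auc`) are reported and labelled distinctly, since
averaging schemes differ across published workflows. AUC is the rank
statistic (pairwise concordance with ties counted ½, verified against
the $O(n^2)$ oracle); confidence intervals are stratified-bootstrap
percentile intervals. The operating point maximizes Youden's J over
observed probabilities with an all-positive tie convention (equal
probabilities give sensitivity 1, specificity 0); a fixed 0.5 cut is
available. The permutation test permutes labels and reruns the *entire*
tuning procedure per permutation, with
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$ —
using the same statistic observed and under permutation keeps the null
exchangeable, and the calibration study (99 permutations, 100
repetitions) confirms uniform p-values under label-independent data.

# The four-criterion screen

Defaults follow the printed working points: selection frequency ≥ 0.90,
rank-sum p < 0.05 (raw; BH-adjusted q is reported alongside but not used
by the screen), mean abundance > 500 (mean normalized intensity over all
discovery samples — the statistic and unit are a documented choice, the
threshold is configurable in the same arbitrary units), single-feature
AUC > 0.7 (oriented ≥ 0.5, direction recorded separately). Frequency is
estimated by stratified 80% subsampling without replacement
(stability-selection convention) refit at the tuned penalty. Boundary
comparisons are closed so vacuous criteria (p ≤ 1, AUC ≥ 0.5, frequency
≥ 0, abundance > 0) admit every feature; at the default working points
the distinction from strict inequalities is measure-zero. A fold change
of exactly 1 is labelled "up" (tie convention). The screen is a pure
intersection, deterministic given the statistics, monotone in every
threshold.

A genuine property of this screen worth knowing: the selection
frequency of a *redundant* marker falls when the classes are close to
separable, because the sparse model doesn't need it. Full recovery of a
planted panel therefore requires fingerprint-scale feature counts and
moderate effects (the calibration studies use 900 features, 100 samples
per group, d = 1.5); with 30 features or d = 2 the same screen
legitimately returns a subset.

The panel model is ordinary (unpenalized) logistic regression on the
surviving features; separable panels are refit with a small ridge
penalty (flagged in the result). The heatmap summary standardizes each
panel feature to mean 0, sd 1 across samples and orders samples by group
and then by panel-model probability.

# Annotation and enrichment

Adduct m/z = monoisotopic mass + cation isotope mass − electron mass
(the electron correction — about 0.5 mDa, i.e. 3–5 ppm in this window —
can be disabled for comparison with legacy tables). Elemental formulas
are parsed and summed from a built-in isotope-mass table at call time;
no mass is stored as a literal, so the embedded reference set is
oracle-checkable. Matching reports every (metabolite, adduct) within
`ppm_tol` (default 5 ppm, the accuracy of orbitrap/FT-class
identification workflows), ranked by absolute ppm error.

Pathway over-representation is the one-sided hypergeometric tail with BH
adjustment across pathways. The background universe may be a name vector
or a plain count; the embedded 26-metabolite table is far smaller than
the detectable plasma metabolome, and using it as the universe makes the
test very conservative (a 3-of-7 overlap that is p ≈ 0.36 against 26
becomes p ≈ 0.001 against a 200-metabolite background). The shipped
pathway map is a small KEGG-style fixture for offline testing; real
analyses should supply their own tables.

# Power under FDR control

From a pilot matrix (log intensities for log-normal data) the package
estimates per-feature Cohen's d with the pooled sd, the null fraction
π₀ by the histogram rule (twice the fraction of pooled-t p-values above
0.5, clipped to [0, 1] — chosen over spline fits for determinism), and
shrinks the effects by a positive-part James–Stein factor computed on
the non-null set implied by π₀ (a global factor would be dominated by
the null majority and wash out sparse signals). The assumed non-null
count is `round(m(1−π₀))`, floored by the number of pilot features
BH-significant at q ≤ 0.25 when there are at least three of them: the
histogram π₀ is noisy and upward-biased at moderate m, and an
underestimated non-null count inflates predicted power through top-k
selection bias, while one or two lenient BH hits can be chance.

`predicted_power()` solves for the per-test level α\* at which the
expected BH false-discovery proportion,
$\pi_0 m \alpha / (\pi_0 m \alpha + \sum_i \text{power}_i(\alpha))$,
equals the target FDR (by `uniroot` on [10⁻¹⁰, FDR]; α\* is capped at
the FDR target, so the construction is never anti-conservative, and a
single-feature pilot with π₀ = 0 reduces to α\* = FDR). Power is the
mean two-sample t-test power (`power.t.test`) over the non-null effects
— the standard metabolomics approximation; the empirical pipeline uses
rank-sum tests, whose Pitman efficiency of 0.955 against the t-test is
inside the self-consistency tolerance. All-null pilots raise an error
(power undefined) rather than returning 0.

# The Bragg utility

d = nλ / (2 sin θ) with θ = 2θ/2, default Cu Kα (0.15406 nm — lab
low-angle diffractometers almost universally use this line; the choice
is a documented default, not a measurement claim). For the low-angle
mesopore peak reported near 2θ = 0.46°, note a printed-precision
subtlety: with the angle taken exactly at 0.46° the formula gives
19.19 nm, while a spacing of 19.00 nm corresponds to 2θ = 0.4646°, which
also prints as 0.46° at two decimals. The two printed values are
therefore mutually consistent only through rounding of the angle, and
the package's checks treat the rounding envelope
[d(0.465°), d(0.455°)] ≈ [18.98, 19.41] nm as the resolution to which a
reported spacing can be recovered from a two-decimal angle.

# Problem sizes and numerical choices

The calibration studies in the test suite use sizes chosen once for
statistical meaningfulness at desk scale: marker recovery and the
annotation round trip at 900 peaks × 100 samples per group (20 seeds for
the recovery medians); binormal calibration at 200 per group; null
CV-AUC over 50 seeds; permutation uniformity at 99 permutations × 100
repetitions on 40 × 15 matrices (the smallest size at which the tuning
procedure is non-degenerate); power self-consistency at 200 features
with a 20-per-group pilot and 20 simulated cohorts at the recommended
n. The m/z grid spacing is σ/4 (the spec of a profile-mode instrument
resolving its own peak width); random number streams are split from one
master seed per cohort, with per-spectrum seeds recorded in the
metadata.

# Known limitations

* Independent features: the simulator plants uncorrelated markers, so
  combination gains and stability-selection frequencies are optimistic
  relative to correlated real panels.
* The noise floor of the peak detector is conservative in very dense
  spectra; weak background peaks are lost there by design rather than by
  a density-aware noise model.
* The power model assumes equal variances and a common effect scale on
  log intensities; π₀ estimation is the simple histogram rule.
* The embedded metabolite and pathway tables are deliberately small
  offline fixtures, not a substitute for HMDB/KEGG.
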