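---
title: "Methods: survival-signature discovery, hypoxia scoring and collagen texture analysis"
author: "PDACsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-signature discovery, hypoxia scoring and collagen texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PDACsig)
```

PDACsig implements, as one tested pipeline, the computational machinery
behind a stromal/hypoxia analysis of resectable pancreatic ductal
adenocarcinoma (PDAC): discovery of a PCA-metagene survival signature from
bulk expression cohorts, its application as a risk score across cohorts and
species, construction and scoring of a hypoxia meta-signature from curated
gene sets, gene-set over-representation, the supporting survival statistics,
and gray-level co-occurrence (GLCM) texture quantification of second
harmonic generation (SHG) collagen images. This vignette explains the
models, the tunable parameters and the numerical choices; the README shows
the worked example.

## The screening statistic

For a cohort of $n$ tumors with log-scale expression, follow-up times
$t_i$ (months) and event indicators $\delta_i \in \{0,1\}$, each transcript
$g$ is screened for univariate survival association with the score-type
statistic

$$ s_g = \frac{1}{n} \sum_{i:\,\delta_i = 1}
   \Big( z_{gi} - \overline{z}_{g,R(t_i)} \Big), $$

where $z_g$ is the expression standardized across samples and
$\overline{z}_{g,R(t_i)}$ is its mean over the risk set
$R(t_i) = \{j : t_j \ge t_i\}$. This equals the Cox partial-likelihood
score at $\beta = 0$ divided by $n$ (the FAST feature-screening statistic
for censored outcomes); positive values mean higher expression is
hazardous. Two properties make it ideal for high-dimensional screening:

* it is linear in $z_g$, so $s_g = z_g \cdot v / n$ for a weight vector $v$
  that depends only on $(t, \delta)$.  The permutation screen exploits this:
  one shared stream of joint $(t_i, \delta_i)$ permutations is applied to
  all transcripts as a single matrix product, which both makes duplicated
  transcripts receive identical p-values and keeps a 10,000-round screen on
  thousands of genes interactive;
* it is invariant to affine transforms of expression, so normalization
  scale does not matter.

Ties are handled Breslow-style: samples whose time equals an event time
remain in the risk set. Two-sided add-one permutation p-values
$p_g = (1 + \#\{|s^\ast| \ge |s_g|\})/(B + 1)$ are used, so no p-value is
ever zero; screening is on $|s_g|$ because both hazardous and protective
transcripts must survive the screen.

## Local FDR selection

Transcripts are selected when their local false discovery rate at the
observed p-value is below 0.15. The lfdr is estimated from the p-values
themselves with a semi-parametric two-component mixture: the marginal
density $f(p)$ is the Grenander estimator — the monotone non-increasing
density given by the left slopes of the least concave majorant (LCM) of the
empirical CDF — and the null proportion $\hat\eta_0$ is read off the flat
tail, $\hat\eta_0 = \min(1, \mathrm{mean}(p > 0.8)/0.2)$. Then
$\mathrm{lfdr}(p) = \hat\eta_0 / \hat f(p)$, clipped to $[0, 1]$. Because
$\hat f$ is non-increasing, the lfdr is non-decreasing in $p$, so selection
by lfdr is a p-value threshold chosen adaptively from the data. The LCM is
built with a stack-based upper-hull pass over the ECDF knots; the density on
an interval is evaluated left-continuously (the interval *ending* at an
observed p-value carries its mass — evaluating on the right would
systematically dilute the smallest, most interesting p-values, which sit
exactly on grid knots of the discrete permutation distribution).

With permutation p-values the add-one grid $\{1/(B+1), \dots, 1\}$ is
discrete; the Grenander estimator is well defined on ties and the tail
estimator of $\hat\eta_0$ is unaffected.

## Metagenes, orientation, and the hazardous/protective split

The selected transcripts are mean-centered per transcript and decomposed by
SVD; component $k$'s transcript loadings are the $k$-th left singular
vector and the per-sample metagene score is the loading-weighted sum of
centered expression. The SVD sign is arbitrary, so each component is
*oriented*: the sign is chosen so that the FAST statistic of its sample
scores is positive — higher score, higher hazard. After orientation the
component splits into a hazardous set (oriented loading $> 0$) and a
protective set (loading $< 0$); zero loadings go to the protective set with
a warning. This makes the labels deterministic and the partition exhaustive
and disjoint, which the `SignatureModel` class enforces as a validity
invariant.

Component quality is assessed by leave-one-out cross-validation of the
*entire* pipeline: for each held-out sample the variance filter, probe
collapse, permutation screen, lfdr selection, PCA and orientation are re-run
on the remainder, and the held-out sample is scored with the training
loadings (centered by training means). The association of the out-of-fold
score vector with survival is summarized by its FAST statistic and a
permutation p-value. Re-screening in every fold is what protects the
estimate from selection bias; to keep it tractable the per-fold screen uses
a reduced permutation count (default 1,000; the recovery analyses in the
test-suite use 200), while the final out-of-fold association p-value uses
9,999 permutations of the single score vector, which is cheap and resolves
well below 0.01.

Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `keepFraction` | 0.5 | standard array practice for variance filtering; no principled cutoff exists, so it is exposed and the recovery tests run at the default |
| `nPerm` | 10,000 | p-value resolution of $10^{-4}$ at desk-scale runtime; the screen scales linearly if finer resolution is wanted |
| `lfdrThreshold` | 0.15 | the selection rule the signature definition uses |
| probe collapse | max-variance probe per gene | deterministic; variance ties break to the lexicographically smallest probe id |

## Risk scoring and the hypoxia meta-signature

A fitted signature scores a new cohort by standardizing each matched
transcript across the cohort's samples and summing, per sample, the
standardized values weighted by the oriented loadings. Scores therefore sum
to zero within a cohort, and a positive score means
hazardous-above-average. Symbols match case-insensitively so a human
signature (LOX) scores mouse data (Lox); an explicit ortholog table can be
supplied, unmatched transcripts are dropped, and the matched fraction is
reported alongside the scores.

The hypoxia meta-signature is built from a gene-set collection by taking
the sets whose names contain "HYPOXIA" and keeping the genes present in
strictly more than 20% of them ("more than" is strict: a gene in exactly
one of five sets is excluded). Samples are scored by the first principal
axis of the row-centered meta-signature expression; the per-sample score is
the sample-side coordinate and the gene-side weights carry the sign rule:
if the VEGFA weight is negative, weights and scores are both flipped, so
increased expression of a canonical hypoxia-induced transcript always
increases the score. VEGFA being absent is an error rather than a fallback,
because without the anchor the score's direction is meaningless. (Where a
source describes using the "loadings" of the first component as per-sample
scores, sample-side coordinates are the only interpretation that yields one
value per sample; the gene-side weights are what the anchor sign applies
to.)

Score stratification uses empirical type-7 quantiles (R's interpolation
default): tertiles, top/bottom quartiles, arbitrary quantile extremes, or a
median split; middle samples are labelled `"mid"` and are meant to be
excluded from two-group survival comparisons.

## Enrichment and supporting statistics

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ with $N$ = universe size, $K$ = set size (after intersection
with the universe), $n$ = query size, corrected across all tested sets by
Benjamini–Yekutieli (valid under arbitrary dependence — gene sets overlap);
significance is strict $p_{adj} < \alpha$. The universe defaults to the
genes of the filtered, collapsed matrix and is overridable. Sets empty
after universe intersection are skipped, not tested at $K = 0$.

Supporting statistics delegate to the standard R machinery behind stable
wrappers: Kaplan–Meier product-limit curves (`survival::survfit`) with the
median reported as the first time survival reaches 0.5 (a conservative
convention; NA if never reached), the log-rank test (`survival::survdiff`),
the Yates continuity-corrected chi-square on 2×2 tables, Mann–Whitney U
(exact for small untied samples, tie-corrected normal approximation
otherwise — matching mouse-cohort sizes), and Spearman correlation with a
t-approximation p-value, which remains valid with ties.

## GLCM texture analysis of SHG stacks

An image stack is reduced to a maximum-intensity projection, thresholded
automatically (Otsu on 256 bins), and the resulting mask restricts all
subsequent pair counting to foreground — out-of-mask pixels are excluded
rather than zero-filled, so the background noise floor cannot bias the
texture statistics. In-mask intensities are quantized to 64 gray levels
(standard GLCM practice) over the in-mask range. For every offset distance
$d$ (default 1–100 px) and each direction (0°, 45°, 90°, 135°) the
symmetric, normalized co-occurrence matrix is accumulated and five Haralick
parameters are computed — contrast, correlation, energy (angular second
moment), homogeneity (inverse difference moment) and entropy — giving the
5 × 4 × 100 grid of parameter values per image. Offsets with no in-mask
pair are recorded as missing rather than zero.

Each parameter's direction-averaged value-vs-distance curve is fit by the
double-exponential decay model
$f(d) = A_1 e^{-d/\lambda_1} + A_2 e^{-d/\lambda_2} + c$ with $A \ge 0$,
$\lambda$ bounded above by the largest measured distance (scales beyond the
measured range are not identifiable), and a bounded offset $c$ (allowed but
constrained to the curve's range, since a free offset can absorb the whole
curve). The fit uses raw Levenberg–Marquardt least squares with ten starts
— two moment-style starts derived from where the normalized curve crosses
$1/e$, the rest with log-uniform $\lambda$ — keeping the best residual.
The scalar summary is the **weighted mean decay distance**
$(A_1\lambda_1 + A_2\lambda_2)/(A_1 + A_2)$, reported as NA when both
amplitudes vanish (a non-decaying curve).

The headline parameter is Haralick **correlation**: for a spatially
correlated field its curve decays from near 1 on the scale of the spatial
correlation length, which is exactly what the decay-distance score is meant
to capture. Contrast — a common default elsewhere — *rises* with offset
distance toward a plateau for such fields, and a nonnegative-amplitude
decay model cannot represent a rising curve, so contrast (and any other
non-decaying parameter) is fit but yields NA for the decay distance. All
five parameters are fit and reported so the choice is transparent.

Depth-resolved quantification binarizes each optical slice (one global Otsu
threshold from the pooled stack by default, per-slice or fixed thresholds
as options) and reports per-slice foreground percent plus the stack total —
the depth profile of fibrillar, cross-linked collagen signal.

## What the synthetic generators emulate

The package is exercised end to end on generated data; the generators are
first-class, tested code and define the conditions under which the pipeline
is validated.

**Survival cohorts.** A post-normalization, log-scale matrix with a
latent-factor structure: factor 1 loads on a planted set of signature genes
(Gaussian loadings, SD `loadingScale`), additional factors load on random
gene subsets as survival-neutral correlated background, and i.i.d. Gaussian
noise is added. Survival is exponential proportional hazards with linear
predictor `hazardCoefficient` × factor 1 (log-hazard per SD of the factor);
censoring is independent exponential with its rate solved numerically so
the expected censored fraction matches the request — the simplest model
satisfying the screening stage's assumptions. Optional batches add
gene-wise constant shifts, mimicking residual batch structure after
normalization (batch *removal* is treated as upstream preprocessing and is
out of scope). Defaults emulate a resected-PDAC array cohort: 73 patients,
median survival near 18 months, ~30% censoring, 2,000 genes of which 300
carry the signature. Two thousand genes is deliberate desk scale relative
to a ~47k-probe array; the recovery analyses are defined at this size.
The follow-up horizon and censoring law of the real cohort are not
published, so the defaults are a field-plausible choice, not a calibration.

**What passing recovery tests do and do not show.** The generator draws
Gaussian, homoscedastic expression with exponential survival; real array
cohorts have heavy-tailed probes, probe-level artifacts, non-proportional
hazards and informative censoring. Recovery of the planted signature
(Jaccard overlap, loading correlation, cross-validated association) shows
the pipeline is correct and calibrated under its own assumptions — it does
not certify performance on any real cohort.

**Gene-set collections.** Random sets with controllable sizes, an exact
number of "HYPOXIA"-named sets, VEGFA forced into every hypoxia set, and
optional exact per-gene membership frequencies, so the strict >20% rule is
testable against known counts. The published construction (22 hypoxia
sets, 1,377 union genes, 55 meta-signature genes from a specific licensed
collection) is an external-data check, not something the synthetic
collection reproduces.

**Cross-species cohorts.** Ortholog mapping is simulated as title-casing of
symbols plus random dropout at rate 1 − `mappingRate` — mirroring
human/mouse symbol conventions without a lookup service — and a metastasis
effect shifts hazardous-set genes upward by `effect` SD units in metastatic
samples only.

**SHG-like stacks.** Anti-aliased random line segments convolved with a
Gaussian of scale `correlationLengthPx` (the planted decay scale), then
thresholded at the pooled intensity quantile that realizes the target
foreground area fraction, plus background noise. A band-matrix separable
convolution with edge renormalization is used so mass is conserved on
images of any size. This is a statistical stand-in for SHG acquisition —
no optics, no depth attenuation, no detector model; per-slice area
fractions fluctuate around the stack-level target because the threshold is
pooled.

## Numerical choices and degenerate inputs

* Zero-variance expression: screening statistic defined as 0 with a
  warning; zero-variance matched genes are dropped from risk scoring.
* Permutation p-values are add-one valued, never 0; the local FDR
  estimator requires ≥ 50 p-values.
* PCA requires the component count not to exceed the matrix rank; rank-1
  inputs give a first component explaining all variance.
* All-equal scores cannot be stratified (degenerate quantiles, an error).
* Constant images give an empty mask with a warning and area 0; GLCM
  offsets with no in-mask pair are missing values; correlation of a
  constant co-occurrence distribution is NA.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state, so results are pure functions of their arguments.
* Text outputs round to 10 significant digits so reruns diff cleanly.

## Simulation sizes used by the test-suite and acceptance script

Calibration runs pool four null cohorts of 500 genes × 100 samples at
1,000 permutations; recovery runs use cohorts of 2,000 genes × 120 samples
(300 signature genes, log-hazard 1.0) with 1,000 screening permutations,
200 per LOO-CV fold and 9,999 for the out-of-fold association; texture
recovery uses 160 × 160 px single-slice stacks with planted correlation
lengths {2, 6, 18} px, distances 1–48 and 16 gray levels; enrichment
calibration uses 200 random 30-gene queries against 25 sets in a 500-gene
universe. These sizes are the package's chosen validation conditions and
are stated here so they can be scaled up externally.

## Known limitations

* The lfdr estimator uses a fixed flat-tail null-proportion estimate;
  strongly non-uniform null distributions (e.g. heavy discreteness from
  very small permutation counts) will bias $\hat\eta_0$ upward.
* LOO-CV reruns the screen with fewer permutations than the full
  discovery, trading p-value resolution inside folds for tractability.
* The GLCM decay summary presumes some texture parameter actually decays;
  on structureless (noise-only) foregrounds the fits degenerate and NA is
  the correct, and returned, answer.
* Cross-species matching by case-insensitive symbol equality is a
  convention, not orthology; supply an ortholog table where one exists.
* The survival statistics are desk wrappers: no multivariate Cox
  modelling, no hazard-ratio estimation, and KM tertile plots are left to
  plotting packages.
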