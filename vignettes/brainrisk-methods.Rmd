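---
title: "Methods: combined lifestyle risk and the aging brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined lifestyle risk and the aging brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the combined lifestyle risk score and its model family, the three
neuroimaging analyses the score is evaluated against, the polygenic risk
score used for adjustment, and the synthetic-data generators that make the
whole pipeline testable. It also records the numerical and design choices
made where the methodology left them open.

## 1. The combined lifestyle risk score

Four behaviours enter the score. Two are treated as risk variables — alcohol
consumption (grams of pure alcohol per period, summed over beverages as
grams-per-unit × drinking frequency) and lifetime smoking (years of smoking ×
cigarettes per day) — and two as protective — physical activity (MET value ×
hours, summed over up to four sportive and four other physical activities)
and a Berkman-style social integration index (2 points for being
married/cohabiting, plus counts of children, close relatives, friends, and
monthly-attended organization memberships).

Each derived variable is z-transformed with the sample SD (n − 1
denominator). Protective variables are sign-reversed, and every variable is
then shifted by its sample extreme so that risk contributions are
non-negative (`z − min(z)`) and protective contributions non-positive
(`min(z) − z` after reversal). The per-participant score is the sum of the
shifted contributions of the model's variables. Three properties follow by
construction and are enforced in the test suite: the score is invariant to
affine rescaling of any raw variable; it is monotone (increasing a risk
behaviour never decreases it); and a participant at the joint sample minimum
of all contributions scores exactly 0.

A note on the smoking unit: the package computes lifetime exposure as
years × cigarettes/day, i.e. cigarette-years, because that is how the index
is defined in the epidemiological instrument this package models. The
conventional pack-year (cigarettes/day ÷ 20) is available via
`cigyears_to_packs()`. Similarly, alcohol may be expressed per week or per
month depending on the questionnaire window; the z-transform makes the score
invariant to this choice, but reported tables should label the unit.

The model family (`enumerate_models()`) has a documented canonical order:
the combined model; four triple models in left-out order ACT, ALC, SOC, SMO;
four protective × risk pairs (ACT+ALC, ACT+SMO, SOC+ALC, SOC+SMO); four
singles. Pair models always combine one protective with one risk variable so
that cancellation between opposing behaviours can be examined; the family
totals 13 models, 8 of them multi-variable reduced models.

Outlier exclusion is a single pass: mean and SD are computed once from all
scores, and participants beyond ±3 SD are flagged. No re-standardization
loop follows, mirroring a one-shot exclusion step in a real cohort workflow.
Sensitivity analysis (`sensitivity_residualize()`) replaces each variable by
its OLS residual on the other three before re-scoring, removing shared
variance between behaviours.

## 2. Surface inference

`fit_vertexwise_glm()` fits, at every mesh vertex, OLS of the field value on
an intercept, the score, and covariates (age centered, gender coded 0/1;
optionally PRS, BDI-II, ISCED). The two-sided test on the predictor is
carried by the signed t statistic; the F map is t². Cluster formation
converts the cluster-forming p (default 0.05, two-sided) to a |t| cutoff at
the model's residual dof and finds edge-connected components, positive and
negative sets separately. Cluster size is summed vertex area in mm² (one
third of incident triangle areas per vertex), the surface-based convention,
rather than a vertex count.

Two null engines provide the max-cluster-size distribution:

* **Monte-Carlo**: Gaussian white noise on the mesh is smoothed by iterated
  neighbour averaging to the FWHM estimated from the model residuals,
  standardized, and thresholded at the matching two-sided normal cutoff.
  Smoothness is estimated from the variance of residual differences across
  mesh edges relative to the residual variance through the Gaussian
  autocorrelation relation ρ(h) = exp(−h²/2s²), FWHM = s·√(8 ln 2); on
  fields with exactly Gaussian autocorrelation the estimator is accurate to
  a few percent (checked in the tests against convolution-generated fields).
  The iteration count matching a target FWHM is calibrated empirically per
  mesh (`smoothing_iterations()`), which keeps the generate–estimate round
  trip self-consistent.
* **Permutation**: the predictor is permuted across participants with
  covariates fixed (simple permutation; a Freedman–Lane scheme would permute
  covariate-residualized data and is noted as the main alternative), the GLM
  is refit and clusters re-formed per iteration.

Positive and negative supra-threshold components are clustered separately
but ranked against one pooled null, matching a two-sided test at α = 0.05.
Whether reference GUI implementations pool signs internally is not
documented; pooling was chosen and is flagged here. Cluster-wise p uses the
add-one estimator `(1 + #{null ≥ size})/(n_iter + 1)`, bounded below by
1/(n_iter + 1) — with 9,999 iterations the smallest attainable cwp is 1e-4.
The default reporting threshold is cwp < 0.01.

Post-hoc, `extract_cluster_values()` pulls the field at a cluster's peak
vertex and `remove_method_regression()` fits the full model of those values
on all four lifestyle variables plus covariates, then removes the lifestyle
variables in a stated order, reporting the F change and R² change of each
step relative to the model before the removal (denominator MSE from that
larger model).

## 3. Subcortical screening

`partial_spearman()` rank-transforms x and y (average ranks on ties),
residualizes both rank vectors on an intercept plus untransformed covariates
(age, gender, total intracranial volume) by OLS, and correlates the
residuals; p comes from the t approximation at n − 2 − k dof. This is the
standard "Pearson on covariate-adjusted ranks" construction; with no
covariates it reduces exactly to Spearman's ρ, and it inherits rank
invariance to monotone transforms. `correlation_matrix()` screens all 13
models against all structures with nominal and Bonferroni flags
(0.05/20 = 0.0025 for the default roster). The 20-structure roster is
configurable; the default is 10 structures per hemisphere (hippocampus,
amygdala, thalamus, putamen, globus pallidus, caudate, accumbens, and three
cingulate segments), since the exact roster used with real segmentations
varies by atlas.

## 4. Resting-state functional connectivity

The per-participant order is fixed and load-bearing (an integration test
asserts that reordering changes the result): discard the first 4 frames →
nuisance regression → band-pass → seed eigenvariate → correlation → Fisher z.

Nuisance regression uses the six motion parameters, their first derivatives
(backward differences, zero-padded first element), and mean GM/WM/CSF
signals; every confound is standardized and entered linearly and squared.
Standardization before squaring was adopted (and is the flagged resolution
of an ambiguity — raw-mean squares would differ only by column scaling and
an intercept shift, but standardizing first conditions the design).

The band-pass (0.01–0.08 Hz) is an FFT ideal filter applied after
demeaning: exactly unit passband gain, complete stopband suppression up to
spectral leakage, and zero phase. This frequency-domain construction is a
standard choice in resting-state preprocessing and satisfies the filter
contract directly (a 0.04 Hz sinusoid at TR 2.2 s passes within 5%, a 0.2 Hz
sinusoid is attenuated by far more than 90%).

The seed series is the first eigenvariate of the VOI voxels (leading left
singular vector of the centered voxel matrix, scaled by the leading singular
value over √(voxel count), sign aligned with the VOI mean). Correlations of
±1 are clipped to ±(1 − 1e−7) before arctanh; zero-variance voxels are
masked and logged.

The second level replaces a MANOVA with non-sphericity correction by
per-voxel OLS plus permutation cluster-level familywise correction — for a
single-predictor design the point estimates coincide and the permutation
null is distribution-free at desk scale; this is a documented deviation.
Voxel clusters use 18-connectivity by default (6/26 configurable), and the
cluster-forming threshold is p < 0.001 two-sided. Both increases and
decreases are always computed and reported.

## 5. Polygenic risk score

The packaged panel transcribes a published 16-SNP table (9 smoking, 7
alcohol) verbatim, including a missing chromosome entry and one indel effect
allele; signed per-allele effect sizes are used as printed. QC filtering
retains candidates with MAF difference ≤ 3% versus the reference population,
imputation info ≥ 0.9, Hardy–Weinberg p > 0.05, and no LD r² ≥ 0.8 with a
retained SNP of the same trait; within a correlated pair the SNP with the
smaller discovery p is kept (standard pruning tie-break, chosen here). The
25-row candidate fixture contains the 16 published SNPs plus 9 synthetic
rejected candidates (flagged `synthetic`) whose QC statistics each violate
exactly one rule, so the 11 + 14 → 9 + 7 accounting is exercised; the QC
statistics of the published SNPs are likewise synthetic-but-plausible, since
no cohort-level statistics are published.

The score is the per-trait mean of dosage × effect over non-missing SNPs,
and the combined PRS is the sum of the two set means (the combiner was
unstated; summation was chosen, with separate covariates available by
passing the set means individually). PRS is linear in dosages, so scaling
all effects scales all scores — a tested invariant. `adjust_for_prs()`
appends the PRS to a design and drops participants without genotypes
listwise, reproducing the smaller-subsample behaviour of genotyped cohorts.

## 6. The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults encode the study conditions: 715 available
participants; exclusion cascade 2 (incidental findings), 70 (unusable
imaging), 63 (missing behavioural data), 31 (score outliers) → 549 analysed;
mean age 67.4 y in 55–85; 216/549 alcohol abstainers and 255/549 never
smokers; exposure mean/SD pairs from the published descriptives (SD
recovered as SE·√549): alcohol 70.0/103.3 g per week, smoking 12.77/18.74
cigarette-years, social index 12.72/5.86, activity 40.75/40.0 MET·h. The
positive parts of the zero-inflated exposures are gamma with moments matched
to those targets — the simplest right-skewed family, since only mean, SE and
range are published. Social-index components are negative-binomial counts
plus a Bernoulli marital state calibrated to the index's mean and SD; BDI-II
and ISCED are generated independently of lifestyle (they are used only as
covariates).

The planted outliers deserve a note: they receive risk exposures orders of
magnitude beyond the published maxima *and* protective behaviours at the
sample minimum. This pins their combined score at the sample maximum, far
beyond mean + 3 SD, while simultaneously inflating the SD enough that all
naturally skewed scores stay inside the fence — so the single-pass ±3 SD
rule deterministically removes exactly the planted set and the ledger
reproduces 715 → 549 for any seed. Real cohorts do not behave this cleanly;
the construction exists to make the exclusion accounting testable, not to
model real outliers.

Surface fields are baseline + slope·score inside a planted, BFS-grown
connected patch, plus neighbour-averaged Gaussian noise rescaled to the
target SD. Planted magnitudes (slope −0.5 per score unit against noise SD 1,
FWHM 3 mm on a unit-spacing mesh) were fixed once as "weak but detectable at
n = 40" and are not tuned. Time series share a latent signal between seed
and target voxels with correlation tanh(z₀ + slope·x); because signal and
noise are generated with identical (white) spectra, the band-pass leaves the
planted correlation unbiased, which is what makes the slope-recovery test a
clean parameter-recovery check. Genotypes are binomial(2, MAF) draws, i.e.
exact Hardy–Weinberg sampling.

What the generator does *not* emulate: real spatial covariance structure of
cortical maps (folding-aligned anisotropy), physiological noise spectra and
motion–signal coupling in BOLD data, LD between SNPs, correlation between
lifestyle behaviours and covariates (configurable but off by default), or
any image-level artefact. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its own assumptions,
not that those assumptions hold in any particular cohort.

## 7. Problem sizes and numerical choices

The test-suite and acceptance-script simulations run at sizes chosen to make
their Monte-Carlo error small relative to the property being checked while
staying desk-scale: the null-calibration study uses 200 datasets of 40
participants on a 2,500-vertex mesh with 500 null iterations per engine
(binomial SE ≈ 0.015 around a 0.05 target, checked against the band
[0.03, 0.07]); recovery studies use 20 replicates; oracle-equivalence
studies use 1,000 random meshes / count triples. The Monte-Carlo engine
estimates residual smoothness from the first null dataset and reuses one
shared null across datasets drawn from the identical generative process —
per-dataset nulls would differ only by estimation noise in the FWHM. Other
conventions: mean and SD of a Monte-Carlo field are standardized globally
(not per vertex); the permutation engine computes the predictor t through
covariate residualization (algebraically identical to the full OLS t, and
what makes 100,000 refits tractable); BFS flood fill on a precomputed
adjacency index performs cluster labelling; ties in ranks use average ranks;
degenerate inputs (constant vectors, empty VOIs, rank-deficient designs,
all-missing PRS) raise informative errors rather than propagating NaNs.

## 8. Known limitations

* The mesh generators are planar lattices; curvature-dependent effects of
  real cortical meshes (variable vertex areas, irregular valence) are
  exercised only lightly.
* The Monte-Carlo engine assumes stationary Gaussian residual fields with a
  single global FWHM; heteroscedastic smoothness would require a
  non-stationary extension.
* Permutation of the raw predictor is exact only under full exchangeability;
  with strong covariate–predictor correlation a Freedman–Lane scheme is
  preferable.
* The PRS panel's QC statistics are synthetic stand-ins, and the LD fixture
  encodes only the strongest within-trait pair per SNP.
* `run_pipeline()` demonstrates the full cascade at reduced default sizes;
  production-scale runs should raise `n_iter_surface` and `n_perm_rsfc` to
  the conventional 10,000.
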