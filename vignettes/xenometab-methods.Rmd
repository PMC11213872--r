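---
title: "Methods and design notes for the xenometab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the xenometab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenometab)
```

# Scope and data model

`xenometab` implements the analysis chain of an untargeted HILIC-HRMS
differential-metabolomics experiment of the cell-exposure kind: two groups
(exposed / control) sampled at up to three timepoints in quadruplicate, a
pooled QC sample injected repeatedly across the sequence, and blank,
solvent-control and medium-control preparations. The pipeline starts at the
*aligned feature table* (peak areas per feature and sample, with m/z,
retention time, ion species and a per-sample integration rating); raw
spectral peak picking and retention-time alignment are upstream,
vendor-side steps and are out of scope by design.

The central container is the `feature_table`: a features × samples area
matrix plus sample metadata (role, group, timepoint, replicate pairing,
injection order) and feature metadata. Missing entries encode peaks not
detected in a sample; the original detection mask is carried through
imputation because the presence filter is defined on *detection*, not on
imputed values.

# Quality control and normalization

The stage order is: peak-rating filter → presence ("usable hits") filter →
random-forest imputation → QC drift correction → QC RSD filter → median
normalization → log transform and Pareto scaling.

**Peak-rating filter.** Keep features rated strictly above 5 (scale 0–10)
in at least 5 samples. The rating is a vendor integration-quality score
with no public definition; the pipeline treats it as supplied metadata and
the synthetic generator fabricates it from a signal-to-noise proxy.
"Above 5" is read as a strict inequality (the literal wording), while the
QC RSD "maximum allowed" bounds below are read as inclusive maxima.

**Presence filter.** A feature must be detected in ≥ 80% of the study
samples of at least one group × timepoint cell. Whether this filter should
see pre- or post-imputation data is ambiguous; it operates on the
pre-imputation detection mask here, since imputation would otherwise make
every feature 100% "present".

**Imputation.** Iterative random-forest regression (100 trees, at most 10
iterations): missing entries start at the feature mean, then each feature
with missing values is regressed on all other features and its missing
entries replaced by forest predictions, sweeping features from least to
most missing. Iteration stops early when the relative change of the imputed
values increases, returning the previous iterate. The forests use *all*
other features as split candidates (`mtry = p − 1`): with the conventional
`mtry = √p` a feature collinear with one partner is recovered poorly
because most splits never see the partner; with full `mtry` the
collinear-pair example in the test suite is recovered to a few percent.
Features more than 50% missing are imputed but flagged with a warning;
all-missing features are an error naming the offenders.

**Drift correction.** Per feature, a 200-tree random forest is trained on
the QC injections only, with injection order plus the 10 most QC-correlated
other features as predictors (samples are one batch). The drift estimate at
the QC points uses the *out-of-bag* predictions — training-set predictions
would chase each QC's own technical noise and the correction would inject
that noise into drift-free data. The QC-point estimates are interpolated to
every sample's injection order with a monotone piecewise-cubic spline
(`monoH.FC`; injection orders outside the QC range are clamped), all
intensities are divided by the interpolated curve, and the feature is
rescaled so its QC median is preserved exactly. Features with zero QC
variance pass through unchanged and are logged. This is a re-implementation
of the QC-based random-forest correction idea, not of any specific released
code; the published method is cited by name only in the source study.

Two numerical notes. First, the correction is mathematically equivariant
under rescaling a feature by a constant, but the tree learner resolves
near-tied split decisions chaotically under sub-ulp perturbations of the
response, so bitwise equivariance holds only for floating-point-exact
factors; the test suite checks the property with a power-of-two factor.
Second, on drift-free data the correction cannot be an exact identity: with
QC technical noise of log-sd 0.05 the out-of-bag drift estimate still
wiggles at the percent level, so "corrected ≈ original" is asserted as a
median relative change below 2% and 95% of entries within 5%.

**RSD filter.** RSD = 100·sd/mean over QC injections; keep features with
before-correction RSD ≤ 50% *and* after-correction RSD ≤ 25%.

**Normalization.** Each sample is scaled by `reference / median(sample)`.
The phrase "maximum peak area median of all samples" admits two readings;
the default reference is the maximum of the per-sample medians (a
median-of-medians alternative is selectable). Blank and control
preparations never set the reference but are scaled alongside. Pareto
scaling then centers each log feature and divides by the square root of its
standard deviation, leaving the feature with variance equal to its
pre-scaling standard deviation — large features are damped, not flattened.
Zero-variance features cannot be scaled and are dropped with a log record.

# OPLS-DA, VIP, p(corr), CV-ANOVA

The discriminant model has exactly one predictive component. With
column-centered X and class vector y (0/1, centered), the predictive weight
is w ∝ Xᵀy (normalized). Each orthogonal component removes from X the part
of the loading p that is orthogonal to w (the classic orthogonal-signal-
correction step), and the predictive score t = Xw is re-formed on the
deflated matrix. Orthogonal components are accepted one at a time while
each raises 7-fold cross-validated Q² by more than 0.01, capped at 3; the
model reports its shape as "1 + K". Fold assignment is a seeded random
partition into contiguous blocks — the fold scheme of the chemometrics
suite used in the source study is proprietary, so the scheme here is
declared and seeded rather than guessed.

Per-feature diagnostics: VIP over the single predictive component,
VIPⱼ = √p·|wⱼ|/‖w‖, which enforces mean(VIP²) = 1 exactly; and p(corr),
the Pearson correlation of the (processed) feature with t, set to 0 with a
log record for zero-variance features.

CV-ANOVA compares the cross-validated predictive residuals against the
total corrected sum of squares of y: with A = 1 + K components,
F = ((SS_tot − PRESS)/A)/(PRESS/(N − 1 − A)) on (A, N − 1 − A) degrees of
freedom; PRESS ≥ SS_tot gives p = 1. The F-approximation is meaningful when
N is clearly above the component count: at the per-timepoint size of the
emulated design (n = 8) the test is strongly conservative (its null
rejection rate is essentially zero), which is the safe direction for a
reliability gate but means per-timepoint "not significant" calls should be
read as "no cross-validated evidence", not as a calibrated p = 0.05 test.
The calibration property test therefore runs at the full-study size
(n = 24, 50-feature null panel, 400 seeded label permutations), where the
empirical type-I error lands inside the binomial 95% band around 0.05.

Discriminant features are the intersection VIP ≥ 1.5, |p(corr)| ≥ 0.50 and
paired-t p ≤ 0.05, applied only when the model's CV-ANOVA p ≤ 0.05 (a
non-significant model returns an empty list with an explicit status).
Paired t-tests run on log-scale values — the Pareto step is a per-feature
affine map and leaves the paired t statistic unchanged — while the
direction of change (increase/decrease in exposed) is computed on the
normalized pre-log areas, matching the relative-concentration semantics of
reported tables. No multiple-testing correction is applied by default: the
triple criterion is the filter; a Benjamini–Hochberg option exists.
Refitting after excluding features (e.g. the parent compound's own
biotransformation products, which otherwise dominate the class separation)
returns both models side by side.

# Exact-mass screening

Monoisotopic masses use CODATA/IUPAC atomic masses over
{C, H, N, O, S, P, Cl, Na, K}; ion m/z applies the adduct composition and
always the electron-mass correction (−z·mₑ), which is irrelevant at 3
decimals but matters in fourth-decimal fragment work. The adduct table is
data, not code: the ten ion species of the acquisition method, extensible.

The default biotransformation set is formula algebra only — demethylation
(−CH₂), desaturation (−H₂), oxidation (+O), di-oxidation (+2O), reduction
(+H₂), hydration (+H₂O), two ring-opening oxidative-deamination composites
reproducing the pyridyl keto- and hydroxy-acid formulas (−CH₅N +3O and
−CH₃N +3O), glycine conjugation (+C₂H₃NO) and acetylation (+C₂H₂O) — with
chains capped at depth 2 and products deduplicated by formula. Positional
isomers are inherently indistinguishable at the formula level and are
separated downstream by retention time. No structure-based metabolism
prediction is attempted. Matching against observed features uses the 5 ppm
peak-picking tolerance and deliberately keeps every feature within
tolerance (isomer series are real).

# MS2 similarity and networking

The similarity is a modified cosine scaled to 0–100: fragment pairs are
candidate matches within 2.5 mmu either directly or after shifting one
spectrum by the precursor-mass difference; candidates are resolved
one-to-one greedily by decreasing intensity product, with ties broken on
symmetric keys (sum, then absolute difference, of the two m/z) so the score
cannot depend on argument order. "Coverage" — the vendor term is not
public — is interpreted as the percent of total fragment intensity of the
less intense spectrum explained by matched peaks. Edges require score ≥ 50,
≥ 3 matched fragments and coverage ≥ 70; nodes without qualifying edges
stay as singletons, and the node order is canonicalized so the edge set is
invariant to input order. The same 0–100 scale serves the 85% spectral-
similarity cutoff in annotation. Because the vendor's score definitions are
proprietary, numeric thresholds are honored but absolute score values on
real data may differ from the original software.

# Annotation levels

Level 1 requires at least two independent orthogonal properties against an
authentic in-house standard (m/z + retention time within 0.2 min, or m/z +
MS2 at ≥ 85%); level 2 is an MS2 match to a spectral-library entry; level 3
is an externally supplied class label only; level 4 is unknown. Whether the
original identification additionally required isotope-pattern agreement is
not stated; here an optional two-isotopologue ratio check counts as
supporting, not orthogonal, evidence. A putative identity is refuted — and
demoted to level 3 or 4 — when the feature's spectrum scores below the
cutoff against an authentic standard. The bundled ~40-entry demo library
(the parent-compound series plus polar metabolites of the relevant
pathways) carries *synthetic* retention times and reference spectra
generated from the formulas; it exists for examples and closed-loop tests,
not as a measurement reference, and is labelled accordingly.

# The synthetic-data generator

`study_design()` defaults encode the emulated study: exposed/control ×
t0/t1/t4 in quadruplicate; six leading pooled-QC injections plus one QC
every eighth study injection and a closing QC; three each of blank, solvent
and medium controls. Feature baselines are log-normal (meanlog = log(10⁶),
sdlog = 1.2 — a broad, realistic intensity spread); study samples add
log-sd 0.2 biological+technical noise, QCs log-sd 0.05 technical noise.
Ten percent of features are truly differential with ±1 log₂ effects in
exposed samples at t1/t4 (effect sizes are overridden per experiment where
a scenario states its own, e.g. 8-fold for the recovery experiment).
Multiplicative injection-order drift runs linearly from 1 − a to 1 + a with
per-feature sensitivity exponents in [0.5, 1.5]; effects are injected
before drift so correction and differential analysis remain separable
failure modes. Missingness is intensity-censored:
P(missing) = plogis((log c − log x)/s) with c = exp(meanlog − 2·sdlog),
s = 0.6, giving a low-intensity-loaded missing fraction whose expectation
is checked against numerical integration of the model. Peak ratings are a
saturating function of intensity, 10·x/(x + k) with k = exp(meanlog) plus
noise, calibrated so roughly half of the low-intensity features fail the
rating filter — mirroring the scale of attrition between raw and retained
feature counts in real studies without claiming exact counts.

The spiked biotransformation series contains 17 products (including
formula-level isomer triplets at distinct retention times) at exact
theoretical m/z, present only in exposed samples, with a lactam-dominant
abundance profile. Family MS2 spectra share 80% of a random parent scaffold
shifted by each product's precursor difference, plus minor unique
fragments; decoys carry unrelated fragments.

What the generator does *not* emulate: correlated metabolite modules,
isotopologue envelopes beyond the spike-free M+0, retention-time drift,
adduct/in-source-fragment redundancy of a single analyte, and heavy-tailed
contamination. Passing closed-loop tests therefore demonstrates the
pipeline's internal correctness and its behavior under the stated noise
model — not performance on any real instrument run.

# Problem sizes and determinism

The test and acceptance experiments use 50–300 features and the design's
24 study samples; these sizes keep each experiment in seconds-to-a-minute
on one CPU while leaving every statistic (VIP, Q², RSD, recovery rates)
in the regime the methods target. All stochastic stages (generation,
imputation, drift forests, fold assignment, permutations) are seeded, and
reruns with the same seed are bit-identical; seeded helpers save and
restore the global RNG state so library calls do not perturb user code.

# Known limitations

* CV-ANOVA is conservative at small n (see above); per-timepoint models at
  n = 8 essentially never reject under the null.
* The drift model in the corrector is as good as the QC coverage: drift
  components faster than the QC spacing alias and cannot be recovered.
* Formula-level biotransformation enumeration cannot distinguish isomers
  and will enumerate chemically implausible chains; it is a screen, not a
  structure predictor.
* Similarity and coverage scores are interpretations of proprietary vendor
  scores; thresholds transfer, absolute values may not.
* The demo library's retention times and spectra are synthetic; annotation
  levels computed against it exercise the logic, not real identifications.
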