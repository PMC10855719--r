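---
title: "Methods: spark emission spectroscopy for tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spark emission spectroscopy for tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During electrosurgical spray coagulation, radio-frequency sparks ionize
tissue vapour and ignite a micro-plasma. The light it emits carries atomic
and molecular emission lines of the elements present in the tissue (Mg, Ca,
Zn, P, K, Na, Fe, C and the molecular C2 band), recorded by a high-resolution
spectrometer over roughly 200–800 nm. Because several of these elements are
differentially abundant in neoplastic versus healthy breast tissue — Mg, Zn,
P and K enriched in abnormal tissue, C2 (a proxy for fat) enriched in normal
tissue, Ca nearly equal — a per-spectrum classifier can support real-time
margin assessment during breast-conserving surgery.

`sparkspec` implements that analysis chain end to end: acquisition-level QC,
local-baseline SNR estimation with a carbon-line quality gate, emission-line
detection and catalogue matching, occurrence-based feature panel selection,
total-intensity normalization with windowed feature integration, and
leave-one-patient-out (LOPO) evaluation of a support-vector classifier with
per-patient diagnostic metrics. Because the clinical spectra are available
only on request, the package ships a synthetic cohort generator with the
same statistical structure, so every stage is testable.

## The processing model

### QC and the carbon gate

Spectra flagged at acquisition (`instrument_contamination`,
`poor_spectral_quality`, `memory_error`) are removed by `apply_qc()`.
`carbon_gate()` then removes spectra whose carbon line (247.856 nm) is weak:
a spark that ablated too little tissue produces no usable elemental
signature. The gate excludes spectra with carbon SNR strictly below 20
(`qc.carbon_snr_min`); a spectrum at exactly 20 is kept. The gate runs on raw
counts before normalization; since the SNR is a ratio of counts it is
invariant under global rescaling, so the order provably does not matter (and
is asserted on random spectra in the test suite).

### Local baseline and SNR

The "surrounding baseline" of a line is operationalized as two flanking
annuli `[c - outer, c - inner]` and `[c + inner, c + outer]` around the line
centre `c`, with defaults `inner = 0.15 nm`, `outer = 0.60 nm` for atomic
lines and both scaled by `broad_scale = 4` for the broad Na and C2 entries.
These defaults bracket the narrow line profiles (sigma = 0.015 nm) with
clean flanks and provide >= 20 grid points per estimate at the default
0.02 nm grid. `mu` and `sd` are the mean and *population* SD of the pooled
flanks — a fixed convention chosen so unit tests have exact closed forms;
at >= 20 points the n versus n−1 difference is immaterial. SNR is the
baseline-subtracted peak height over `sd` ("signal" conventionally excludes
the pedestal). A constant flank would give `sd = 0`; it is replaced by a
machine-epsilon-scaled floor with a warning, so zero-noise synthetic spectra
produce large finite SNRs rather than dividing by zero.

Several catalogue lines are close neighbours (the Mg 279.522/279.805/280.270
triplet, P/Zn at 213.6/213.9, C/Fe at 247.9/248.3): a neighbour falling into
a flank would inflate the baseline SD and depress the SNR. Catalogue-aware
callers therefore mask every *other* catalogue line
(± max(3 sigma, tolerance)) out of the flanks via the `exclude_nm` argument
of `local_baseline()`; `carbon_gate()` masks the Fe line by default. After
masking, every default line retains >= 10 points per flank on the default
grid.

### Features

Peak detection reports local maxima strictly greater than both neighbouring
values, with plateaus resolved to their leftmost point, and is verified
against an independent brute-force neighbour scan. Detected peaks are
matched to the catalogue greedily by increasing wavelength difference
(tolerance 0.05 nm for atomic lines, 0.5 nm for broad ones — well under half
the 0.283 nm Mg doublet gap), each peak and line used at most once.

A line enters the feature panel iff it is detected with SNR strictly above
`features.min_snr = 20` in at least `features.min_occurrence = 5%` of the
spectra (boundary inclusive). Panel selection checks, per line and spectrum,
for a local-maximum apex within the match tolerance of the line centre —
an equivalent, windowed form of detect-then-match that avoids scanning the
full 30,001-point grid for every spectrum.

Each spectrum is then normalized to its total intensity and integrated
(trapezoid rule) over `wavelength ± 3 sigma` per panel line, minus the local
baseline mean over the same window, floored at zero. The floor means a line
absent from one spectrum still yields a defined value (0), keeping feature
vectors fixed-length. The 3-sigma window captures > 99% of a Gaussian line.
Feature values are dimensionless and invariant under global rescaling of the
raw counts.

The per-feature "score" reported by `feature_scores()` is the absolute
standardized mean difference `|mean_abnormal − mean_normal| / pooled SD` —
the simplest two-class separability measure; this is the package's own
definition, chosen because no canonical formula exists for this quantity in
the source workflow.

### Classification

`run_lopo()` evaluates an RBF-kernel C-SVC under leave-one-patient-out
cross-validation: each fold's test set is all spectra of one patient, the
training set everyone else's, preventing patient-identity leakage (asserted
structurally on every fold). Within each fold, features are centred and
scaled on the training rows only and the transform is embedded in the model.
Hyperparameters — `cost = 1`, `gamma = 1/(n_features × mean feature
variance)`, KKT tolerance `1e-3` — are fixed, exposed defaults: the
classifier family is given but its settings were unreported, and fixed
defaults make runs reproducible. The solver is a deterministic SMO
(sequential minimal optimization) implementation in C++; no randomness
enters training, so identical inputs give identical models. The positive
class is `abnormal`; accuracy, sensitivity, specificity, PPV and NPV are
computed per patient, with zero-denominator metrics reported as undefined
(`NA`) and skipped (with a logged count) in the arithmetic means over
patients rather than imputed — with both classes present per patient this
arises only in synthetic edge cases, and skipping is the least distorting
choice.

No SVM binding was available in the target environment, so the solver is
implemented in the package (Platt's SMO with a full error cache and
deterministic working-set selection) rather than wrapped from `e1071` or
`kernlab`.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the analysis assumes:

* 18 patients with the historical per-patient normal/abnormal spectrum
  counts (`default_patient_counts()`; 481 + 494 = 975 spectra);
* 17 catalogue lines at the field-standard wavelengths, Gaussian profiles
  (sigma = 0.015 nm atomic, 0.30/0.35 nm for Na/C2);
* tissue effects as amplitude fold-changes: Mg ×3, P/Zn ×2.5, K ×2 higher
  in abnormal tissue, C2 ×0.5 (higher in normal), Ca ×1.1, C/Fe/Na ×1 —
  the qualitative pattern reported for real tissue, with magnitudes chosen
  once to reflect the "much higher"/"slightly higher" contrasts described
  there;
* a per-patient log-normal random effect (`sigma_patient = 0.15`) shared by
  all of a patient's spectra, plus independent per-spectrum, per-line
  log-normal jitter (`sigma_spectrum = 0.2`). Effects are multiplicative
  because emission intensities are positive and global factors (spark
  strength, optical coupling) act multiplicatively; drawing the jitter per
  line makes *relative* line intensities vary, which survives per-spectrum
  normalization;
* a flat background (`baseline_level = 30` counts) with additive
  homoscedastic detector noise (`noise_sd = 5` counts), truncated at zero —
  the simplest model under which the 20×SD carbon gate is exercisable;
* a uniform 0.02 nm grid (30,001 points), finer than the narrowest line
  width so peak detection is meaningful; and `qc_fail_fraction = 0.02` of
  spectra flagged with a random acquisition failure, mirroring the 20/992
  historical exclusion rate.

Cohorts are byte-reproducible from `seed`.

**What a green test does and does not establish.** The generator reproduces
the *statistical skeleton* of real spark spectra: line positions, tissue
fold-changes, patient-level correlation, detector noise, QC attrition. It
does not model plasma physics (Boltzmann/Saha excitation), the rovibrational
structure of the C2 Swan band, continuum/fluorescence background, wavelength
miscalibration, or fiber-contamination drift. Passing the acceptance suite
therefore establishes that the *pipeline* is correct and can recover
class structure of the stated effect sizes at the stated noise levels — not
that the clinical performance figures would be reproduced on real tissue.

## Numerical choices

* Population SD in baselines; SD floor `sqrt(eps) * max(1, |mu|)`.
* Gate boundary: exclude strictly `< 20`, keep at exactly 20; panel SNR
  strictly `> 20`; occurrence boundary inclusive at 5% — all following the
  stated criteria literally.
* Plateau peaks resolve to the leftmost point; matching ties break toward
  smaller wavelength difference, then smaller wavelength.
* Trapezoid integration on the native grid; baseline area subtracted as
  `mu ×` window width; features floored at 0.
* Undefined (0/0) metrics are `NA`, never 0; feature scores define 0/0 = 0.
* Decision values exactly 0 map to `normal` (no-signal default).

## Chance level under LOPO is assessed by permutation, not a binomial band

A natural check on the generator is that a null cohort (all tissue
multipliers 1) classifies at chance. The naive test — pooled LOPO accuracy
inside the 95% binomial band around 0.5 — is misspecified here: predictions
are correlated within a patient (all spectra share the patient random
effect, so they land on the same side of the decision surface together) and
across folds (folds share most training rows), inflating the variance of
pooled accuracy to roughly three times the binomial standard error. Across
15 independent null cohorts at the test scale, pooled accuracy was unbiased
(mean 0.515) with SD ~0.055 and range 0.375–0.609 — a correct, leakage-free
generator would fail the literal binomial band for roughly a third of
seeds. The test suite therefore assesses the same hypothesis with an exact
label-permutation test: 99 within-patient label permutations of the null
cohort must (a) centre on 0.5 (|mean − 0.5| < 0.05; the standard error of
the permutation mean is ~0.005, so this detects any systematic bias beyond
about one percentage point) and (b) not leave the observed null accuracy
significantly *above* the permutation distribution (one-sided exact test at
level 0.025 — leakage inflates accuracy, whereas below-chance draws are
cluster-variance noise). The same centring check is applied to full label
permutations of an effect-bearing cohort.

## Scaled-down test worlds

The LOPO integrity checks (null-effect and label-permuted cohorts) run on
8-patient, 24-spectrum-per-patient cohorts with the identical generator
model, purely to stay inside the test-suite runtime budget; the full
18-patient default world is exercised once, in the acceptance suite and the
acceptance script.

## Known limitations

* The two unnamed atomic peaks of the original 18-peak selection cannot be
  reconstructed from published wavelengths; the catalogue therefore carries
  16 named atomic lines + C2.
* The classifier's hyperparameters in the original workflow are unknown;
  results are reported for the fixed defaults above.
* Evaluation treats the spectrum (not the sample) as the unit, consistent
  with per-patient spectrum counts.
* The on-disk spectrum dialect is the package's own (plain two-column CSV);
  proprietary spectrometer exports are out of scope.
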