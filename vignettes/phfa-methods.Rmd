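---
title: "Quantifying interictal high-frequency background activity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interictal high-frequency background activity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phfa)
```

## The problem

Interictal high-frequency oscillations (HFOs) are brief (20-100 ms)
paroxysmal events whose rate per channel is an established biomarker of the
epileptogenic zone in intracranial EEG.  HFOs, however, occupy well under 2%
of a high-sampling-rate record.  This package quantifies the other 98%: the
long-duration high-frequency (>30 Hz) *background* activity (HFA) that
remains after every detected HFO and artifact has been redacted.  The
working hypothesis is that this background carries information about
pathological tissue that is distinct from, and complementary to, the HFO
rate — and the package's two analyses (an inferential association analysis
and a cross-validated predictive score) are built to measure exactly that.

The intended user has multichannel intracranial recordings (order 1-10 kHz
sampling), channel metadata with clinical labels — seizure onset zone (SOZ),
resected volume (RV), temporal lobe (TL) — seizure times, and per-channel
HFO/artifact annotations from a separate detector.  Detector internals,
anatomical localization, and clinical report parsing are out of scope; the
annotations are inputs.

## Pipeline overview

1. **Preprocess** (`common_average_reference`, `interictal_mask`,
   `build_epochs`, `redact_events`): group-wise common average reference
   (depth channels referenced to the depth mean, grid/strip channels to the
   grid+strip mean); restriction to interictal time (default: at least 30
   min from every seizure start, plus the ictal interval itself whenever
   the seizure end is known — the margin criterion alone is stated from the
   start, but ictal samples must never leak into a background analysis);
   tiling into fixed epochs anchored at the recording start, dropping any
   epoch that is not fully interictal; and per-channel removal of all
   annotated HFO/artifact sample ranges from each epoch.  Events on one
   channel never redact another, since detections are per channel.
2. **Band filtering** (`design_bandpass`, `apply_filter`): two zero-phase
   elliptic band-passes, 30-80 Hz ("band 1", low gamma) and 80-500 Hz
   ("band 2", the usual HFO detection range), order 10, 0.5 dB passband
   ripple, 65 dB stopband attenuation, applied forward and backward.
3. **Features** (`compute_epoch_features`): 19 morphology features per band
   per channel per epoch — 38 in the default two-band analysis.
4. **Time integration** (`median_adjust`, `integrate_q75`): per epoch the
   across-channel median of each feature is subtracted, then each channel
   keeps the 75th percentile of its adjusted values over epochs.
5. **Association** (`fit_feature_model`): per-feature logistic regression
   of the channel label on the sMAD-scaled integrated feature, with
   patient-equalizing weights and Bonferroni-corrected Wald p-values.
6. **pHFA score** (`fit_fold`, `lopo_scores`): hold-out-one-patient
   cross-validated whitening + PCA (components to 95% explained variance) +
   logistic regression on SOZ membership, yielding a score in [0, 1] per
   channel, plus the channel-wise HFO-rate x pHFA product.
7. **Asymmetry** (`asymmetry`, `cohort_summary`, `paired_difference`):
   per-patient effect sizes `A = (x_in - x_out)/(x_in + x_out)` of any
   nonnegative biomarker with respect to a label, cohort medians with
   bootstrap CIs, and paired differences between biomarkers.

## The feature set

Within one epoch, let `x` be the band-filtered samples that survive
redaction and `y = (x - mean(x))/sd(x)` its z-scored version.  With `fS`
the sampling rate in kHz, four transforms are applied sample-wise:
rectification `R(y) = |y|`; line length `L(y) = |diff(y)|*fS`; curvature
`C(y) = |second difference|*fS^2`; and the Teager-Kaiser energy
`T(y) = (y_j^2 - y_{j+1} y_{j-1})*fS^2`.  The `fS` powers give derivatives
per millisecond rather than per sample, so features transfer across
sampling rates.  Each transform is summarized by moment statistics and
compressed: decibels (`10*log10`) for means, standard deviations and
kurtoses; arctangent for skewnesses (log-like compression that accepts
negative values).  The only feature computed on the non-normalized signal
is `f5 = 10*log10(sd(x))`, the band amplitude; everything else is
amplitude-invariant by construction, which the test suite asserts directly.

Conventions that the literature leaves open and that we therefore pin
explicitly (all configurable where noted):

* **Standard deviation**: sample (n-1) everywhere, declared once, used in
  the normalization and in `f5`-`f9`.
* **Skewness/kurtosis**: population central-moment ratios `m3/m2^1.5` and
  `m4/m2^2`; kurtosis is *non-excess* by default so its logarithm is
  defined for every sample (`excess_kurtosis = TRUE` is available, but any
  non-positive log argument then flags the record invalid rather than
  emitting infinities).
* **First difference**: `f6`/`f16` use the signed difference `D(y)*fS`,
  consistent with `L = R(D(y))`; a table of the feature grid sometimes
  labels these rows by `R(y)`, but the defining formulas use `D`.
* **Segments**: transforms are computed within each contiguous
  post-redaction segment (no differences are taken across a redaction
  gap), transformed samples are pooled across segments, and the epoch's
  normalization uses the pooled surviving samples only.  Splitting an
  epoch at an interior point therefore changes features only through the
  couple of boundary samples lost per cut (asserted < 1e-3 dB at 1e5
  samples).
* **Floor**: an epoch/channel record is dropped when fewer than 25% of the
  nominal samples survive redaction (partially redacted epochs are
  otherwise used as-is); degenerate records (zero variance, non-positive
  log arguments) are flagged and excluded from integration.

## Filtering choices

The elliptic design order is taken as the order parameter of the canonical
band-pass design call (20 poles for the band-pass); this matches how such
filters are usually specified in the field's analysis environments.  The
design is carried entirely in zero-pole-gain form and realized as a cascade
of second-order sections, because a 20-pole transfer-function polynomial at
4096 Hz has poles within 2e-4 of the unit circle and is numerically
fragile.  The single-pass magnitude response is verified in the tests:
band 2 at 4096 Hz is at -69.7 dB by 30 Hz and within [-0.5, 0] dB across
the passband interior; bidirectional application doubles attenuation and
cancels phase (cross-correlation peak at lag 0).

Filtering is applied to the full referenced record per channel *before*
segments are cut, so redaction gaps create no filter transients; the
startup transient at the record edges decays with the slowest pole
(time constant roughly 1500 samples for band 2, 6000 for band 1 at 4096
Hz) and is negligible relative to a multi-minute record.  No padding is
used; `apply_filter` rejects inputs shorter than three filter lengths.

## Time integration

Subtracting the per-epoch across-channel median removes shifts common to
the whole implant (state changes, technical artifacts) and makes every
feature a *relative* measure across channels — without it, temporal
variability swamps the channel contrast.  The median pools all analysed
channels of the patient, including mixed electrode kinds.  The 75th
percentile over epochs follows the half-sample-offset convention (the k-th
order statistic at percentile `100*(k-0.5)/n`, linear interpolation,
clamped extremes; R's `quantile` type 5), which is the percentile
definition of the numerical environments these analyses are usually run
in; the convention is recorded in the run manifest and configurable.

## Association model and weights

Features are scaled by their sMAD (median absolute deviation divided by
`qnorm(0.75)`), a robust spread measure: the heavy-tailed channels are the
signal, so the ordinary standard deviation would be dominated by exactly
the observations of interest.  Each feature then enters its own
single-covariate logistic regression (features are strongly correlated, so
a joint inferential model would be uninterpretable), with observation
weights that give every patient equal total weight regardless of implant
size.  The weights are normalized to overall mean 1 (each patient's
channels sum to `n_channels/n_patients`): in a weighted GLM the absolute
weight scale acts as an information scale, and mean-1 weights keep the
nominal calibration of Wald p-values — measured type-I error 0.05 at
`alpha = 0.05` over 2000 null cohorts in the acceptance checks — while
reducing exactly to the unweighted fit when implant sizes are equal.
Normalizing each patient's total to 1 instead would shrink every z-statistic
by about the root of the mean channel count and drive the type-I error to
zero.  The chosen scale is recorded in the output.  Significance uses
Bonferroni correction over 39 tests by default (38 features plus the HFO
rate, which is always modelled alongside as the comparison biomarker); the
denominator is configurable.

Complete separation is reported as a flagged result, not a number.

## Predictive score

Each cross-validation fold whitens the 38 integrated features with
training mean/sd, keeps the smallest number of principal components whose
cumulative explained variance reaches 95%, and fits an unweighted logistic
regression of SOZ membership on the component scores (patient weighting is
stated for the association analysis only; a weighted option exists).
Whitening makes the covariance and correlation PCA coincide, removing that
ambiguity.  Zero-variance training features get sd 1 with a warning.  On
separation the fit falls back to a deterministic Newton ridge with penalty
1e-6 — scores then saturate near 0/1, which is the honest answer for a
strongly separable cohort.  Held-out channels are transformed with
training parameters only; the test suite asserts bit-identical fold models
under arbitrary corruption of the held-out patient.

The product biomarker multiplies the HFO rate (events/min over analysed
interictal time) by the pHFA score; multiplication is insensitive to the
unit mismatch and damps channels where either signal is low, an and-like
concordance.

## Asymmetry statistics

`A = (x_in - x_out)/(x_in + x_out)` over mean biomarker values inside and
outside a label is scale-invariant and lies in [-1, 1] for nonnegative
biomarkers.  Cohort summaries use the sample median with a 95%
percentile-bootstrap CI of the median (10,000 resamples, fixed seed); the
paired comparison of two biomarkers bootstraps the per-patient difference
in asymmetries.  The bootstrap was chosen because no particular parametric
CI for a median of ~14-20 patients is standard; the method name and seed
are stored with the output.  Coverage for the median of a uniform sample
at n = 14 is asserted to fall in [90%, 99%] in the tests (at reduced
resample counts, 500 trials x 600 resamples, to keep the suite fast).

## The synthetic cohort

Every statistical claim in the tests is exercised on synthetic cohorts with
known ground truth, generated by `cohort_spec()` / `generate_patient()`:

* background: unit-variance 1/f-amplitude Gaussian noise (20 uV) plus
  white noise (5 uV) per channel — the simplest process with a realistic
  spectral slope and controllable band power;
* pathological (SOZ) channels: additional white noise filtered into
  80-500 Hz and scaled so band power is multiplied by `band_power_gain`,
  plus Hann-windowed 30-ms broadband bursts with Laplace-distributed
  amplitude at Poisson times (high kurtosis without mimicking HFOs);
* injectable HFOs (windowed 80-250 Hz sinusoidal bursts, 20-100 ms) and
  artifacts (signed exponential spikes), Poisson counts at configurable
  rates, every event listed exactly in the annotation set;
* determinism: patient `i` is generated under seed `seed + i`, so cohorts
  are reproducible and parallelizable.

The default specification — 20 patients, 8 depth channels (2 SOZ, 3 RV),
20 epochs of 30 s at 2048 Hz, gain 4, 6 bursts/min, HFO rates 2/0.2 per
min in/out, 1 artifact/min — is the package's simulation-study condition:
large enough that the planted contrast is decisively detectable, small
enough that the full pipeline runs in minutes on one CPU.  These sizes,
and the reduced replicate counts noted above, are the problem sizes used
throughout the tests and the acceptance script.

What the generator does *not* emulate: physiological seizure dynamics,
sleep/state structure, spatial correlation across electrode geometry,
realistic HFO morphology diversity, or inter-patient covariance shifts.
Passing tests therefore demonstrate that the pipeline detects the kind of
band-power/burstiness contrast it is designed for and that its statistics
are calibrated — not that any particular clinical performance level will
be reached on real recordings.

## Degenerate inputs and numerical notes

Empty reference groups are skipped with a warning; seizures outside the
recording span are ignored with a warning; an epoch fully covered by
events yields an empty segment list and is skipped; constant signals,
zero-variance features and non-positive log arguments flag records rather
than propagate infinities; `integrate_q75` of an empty vector is a missing
channel value, excluded downstream with a warning.  Moment accumulation
uses extended-precision compounded sums (permutation-invariant to < 1e-9
relative).  Sample indexing is 0-based with half-open `[start, end)`
intervals throughout the epoch/segment bookkeeping.

## Known limitations

* The EDF reader/writer is minimal (16-bit, uniform rate, 1-s records) and
  intended for interchange of synthetic cohorts, not for arbitrary
  clinical EDF+ files.
* Scores' absolute magnitudes are not calibrated probabilities; the
  relative ranking across channels within a patient is the meaningful
  output, and under strong separability the cross-validated logistic
  saturates scores at 0/1 by design.
* The three-band variant (30-80, 80-250, 250-500 Hz) is supported as
  configuration but carries no separate validation.
* Bad-channel screening is the user's responsibility, as it is in clinical
  review.
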