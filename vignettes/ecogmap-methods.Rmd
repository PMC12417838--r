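---
title: "Methods: spectral and connectivity mapping of glioma cortical compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral and connectivity mapping of glioma cortical compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecogmap` analyzes intraoperative electrocorticography (ECoG) recorded over
and around diffuse gliomas during awake surgery, and discriminates four
cortical compartments — tumoral, close peritumoral (≤ 15 mm from the FLAIR
tumor border), far peritumoral (15–30 mm) and healthy (> 30 mm) — from the
periodic and aperiodic structure of the power spectrum and from phase
synchrony between contacts. This vignette explains the models, the tunable
parameters, the synthetic-data generator the test suite runs on, and the
numerical choices made where the design was genuinely open.

## Electrode labeling

`label_compartment()` maps metadata to compartments: an electrode flagged as
lying on the MRI-positive or macroscopically suspicious area is `tumoral`;
otherwise the distance from the FLAIR border decides, with half-open,
gap-free intervals (0, 15], (15, 30], (30, ∞) mm. Integer reporting
conventions ("< 15", "16–30", "> 31") leave the 15–16 and 30–31 mm bands
undefined; closing the intervals at 15 and 30 makes the rule total on every
nonnegative distance, which a pipeline needs. Electrodes with neither flag
nor distance stay unlabeled and are excluded from group statistics.

## Preprocessing

Recordings are acquired monopolar at high rate (20 kHz in the motivating
setting) and analyzed at 2000 Hz. `resample_recording()` uses Fourier-domain
resampling — the DFT is truncated at the target Nyquist and inverted at the
new length. This is an ideal brick-wall anti-aliasing decimator with exactly
flat passband gain for any rational rate ratio; FIR/IIR polyphase decimators
we evaluated showed up to 5 % passband ripple, which would contaminate band
powers directly.

`bandpass_zero_phase()` applies a forward–backward (zero net phase)
Chebyshev type II cascade. Two design points matter:

- **Cascade, not bandpass.** A single IIR bandpass with a lower edge at
  0.1 Hz against a 1000 Hz Nyquist is numerically fragile; a high-pass plus
  low-pass cascade, order 4 per edge and 40 dB stopband attenuation per
  section, is well conditioned. An unstable design raises an error rather
  than silently corrupting data.
- **Stopband-edge placement.** Chebyshev II designs are specified by their
  *stopband* edge. Stop edges are placed one octave outside the requested
  band (low/2, 2·high), which for order 4 at 40 dB puts the −3 dB points at
  the band edges. When 2·high exceeds Nyquist the transition is compressed
  and the order raised (up to 12) to keep the −3 dB point in place.

The default analysis passband is 0.1–250 Hz: a narrow 0.1–50 Hz preset is
sometimes used for visual review, but the analysis itself needs high gamma
(55–100 Hz) and aperiodic fits to 200 Hz, so the wide band is the default
and the narrow band remains a configuration choice.

`reject_artifacts()` makes segment exclusion explicit and automatic: each
channel is scanned in 1-second windows; a window is excluded when the robust
z-score of its peak amplitude (median/MAD across that channel's windows)
exceeds 8 **and** the peak exceeds 5× the median window peak, or when its
variance falls below a flatline epsilon. The multiplicative guard is needed
because 1/f-weighted signals have heavy-tailed window peaks: on clean
synthetic channels the robust z alone produces false exclusions, while a
genuine artifact (a 20× amplitude pulse, an amplifier saturation) passes
both criteria easily. Channels retaining less than 10 s (capped at the
recording length) are flagged noisy and removed.

## Welch spectra and band powers

`welch_psd()` averages Hann-tapered periodograms with a window of
`2 × sampling rate` samples (0.5 Hz resolution) and 50 % overlap, with
one-sided density scaling so that `sum(psd)·Δf` equals the signal variance
(Parseval; verified to 5 % on stochastic fixtures and to 1 % on a unit
sinusoid, which integrates to a²/2 = 0.5). Windows are drawn only from
artifact-free intervals; a channel with no interval long enough for one
window is flagged feature-missing.

`remove_line_noise()` masks bins within ±1 Hz (configurable) of 50 Hz and
each harmonic; every downstream total sums retained bins only. The
densities themselves are untouched, so the mask is reversible bookkeeping,
not interpolation.

`band_powers()` uses the six canonical bands (delta 0.5–4, theta 4–8, alpha
8–12, beta 12–29, low gamma 30–45, high gamma 55–100 Hz), half-open
`[low, high)` so shared edges are never double counted. The relative-power
denominator is the retained total from 0.5 Hz to the Nyquist of the
analysis rate — the full computed range, since no narrower convention is
canonical. Relative powers are invariant to channel gain by construction.

`normalize_per_patient()` divides each feature column, within each patient,
by that patient's maximum of the column, making amplifier- and
impedance-scale differences between patients commensurable. Per-feature
(rather than one global per-patient maximum) is the default because it
keeps features on comparable scales; the global mode is available by
configuration. The aperiodic offset is a log10 power and can be negative
throughout a patient, where max-division is meaningless; it is therefore
normalized on the power scale, `10^offset / max(10^offset)`, which is a
maximum-power normalization in the literal sense and lands in (0, 1].

## Aperiodic parameterization

`fit_spectral_model()` decomposes log-power into an aperiodic line plus
Gaussian peaks:

1. robust line fit of `log10 PSD` on `log10 f` (ordinary least squares,
   refitted after discarding the top 2.5 % of positive residuals, since
   oscillatory peaks only push the line up);
2. iterative peak removal — locate the largest positive residual, fit a
   Gaussian (linear frequency, log power) to it by bounded L-BFGS-B,
   subtract; stop after `max_peaks` (default 6) or when the next peak is
   lower than `min_peak_height` (default 0.1 log10 units);
3. final line refit on the peak-subtracted spectrum; `offset` is the
   intercept and `exponent` the slope magnitude (reported positive for a
   decaying spectrum).

The knee-free form is used: the fit ranges are either narrow or start at
1 Hz, where no knee is resolvable. Gaussian SDs are bounded to 0.5–12 Hz —
wide enough for broad beta bumps, narrow enough not to absorb the line
curvature. On a noiseless power law the procedure is exact to numerical
precision (no residual exceeds the peak threshold, so the final fit is plain
OLS on a line), which the tests assert at 1e−6; on simulated 1/f^χ noise
(120 s at 2000 Hz) the exponent is recovered within 0.1 for χ ∈ {1, 2, 3}.

Fits run over six ranges — 1–200, 20–30, 20–40, 30–45, 40–60, 60–120 Hz —
and `aperiodic_feature_block()` emits 7 features: one offset (from the
widest fit, matching the 7 = 1 + 6 feature inventory) and six exponents. On
composite spectra with oscillations the narrow-range exponents are biased
upward near band edges (an oscillation shoulder looks locally steep); the
group *orderings* these features support are robust to that bias, but the
absolute values should not be read as pure background exponents.

## Phase-locking connectivity

For each band (0.5–4, 4–8, 8–12, 12–30, 30–45, 55–100 Hz — the beta band
differs from the power table, 12–30 vs 12–29, and both tables are kept
verbatim per stage), channels are zero-phase band-filtered, the analytic
signal is taken by frequency-domain Hilbert transform, one second is trimmed
from each end against filter transients, and
`PLV(i, j) = |mean(exp(i(φ_i − φ_j)))|` is computed over all simultaneous
pairs (pairs are restricted to channels sharing an acquisition block when
the metadata records one, since strips are placed sequentially during
surgery). PLV is 1 for any fixed lag, amplitude-invariant, and for
independent phases concentrates at the Rayleigh mean √(π/4N) — the test
suite checks that null calibration within 10 %. Narrowband autocorrelation
makes the *effective* N much smaller than the sample count, so empirical
null levels on filtered noise sit well above √(π/4N) computed from raw
sample counts; comparisons should always be within-band.
`compartment_plv_summary()` averages distinct unordered pairs per
label-pair block, never the unit self-PLV.

## Group statistics

Features are compared across the four compartments with the tie-corrected
Kruskal–Wallis test and Dunn's post hoc z-tests (tie-corrected variance,
all 6 pairs, Holm adjustment by default — the multiplicity method is not
canonical, and Bonferroni is available); astrocytoma/oligodendroglioma-style
two-group contrasts use Mann–Whitney; feature–distance and
feature–infiltration associations use two-sided Spearman correlations.
Biopsy infiltration counts (tumor cells / 250 µm²) are stratified
healthy = 0, low < 50, high ≥ 50 — the boundary count 50 is assigned to
"high" since "< 50" and "> 50" leave it unassigned — and correlations run
within each stratum, reported missing below n = 4. Contact-level
observations are treated as independent, as in standard contact-level ECoG
statistics; patient-level clustering is a known limitation, not modeled.

## Classification

`assemble_features()` produces the 38-column table (12 periodic + 7
aperiodic, each raw and normalized); rows with any missing feature are
excluded from training with a logged count (no imputation).
`split_train_test()` draws a stratified 70/30 split with largest-remainder
rounding, so a 708-row cohort yields exactly 496/212.
`cross_validate()` runs seeded stratified 5-fold CV on the training split.

The kNN model is a random-subspace ensemble: 30 learners, each on a random
19-dimensional feature subspace (half the feature set), majority vote,
deterministic tie-break toward the lowest class index. The phrase
"19-neighbor subspace" in the motivating setting is ambiguous between the
subspace dimension and the neighbor count; it is read here as dimension 19,
and the neighbor count k is tuned over {1, 3, …, 19} by CV macro-F1 (capped
below the fold training size). With one learner on the full space the
ensemble reduces exactly to plain kNN, which the tests assert. The SVM uses
a polynomial kernel of degree 3 (one-vs-one multiclass), with feature
standardization frozen from the training split only — the API exposes only
the fitted transform, so test-set leakage into the scaling is impossible by
construction.

The 2-class scheme defaults to tumoral vs non-tumoral; tumoral vs healthy
(dropping peritumoral rows) is available by configuration. Summary
precision/recall/F1 are macro-averaged — robust to the class imbalance that
real cohorts show (peritumoral contacts dominate) — with per-class values
always reported alongside. No resampling or class weighting is applied by
default, mirroring plain practice; significance of an observed accuracy is
assessed against a permutation null (`permutation_null_accuracy()`).

## The synthetic generator

`generate_recording()` builds each channel as

> colored background + band oscillations + 50 Hz line + patient gain,

with per-compartment profiles carrying the generative truth:

- **Background**: spectral shaping of white noise to `10^b · f^(−χ)`
  (random-phase Fourier amplitudes ∝ f^(−χ/2)), exact in expectation. The
  law is flattened below 0.5 Hz: amplifiers high-pass near DC, and an
  unfloored f^(−χ) would fill the record with sub-delta wander that no real
  recording contains (and whose leakage would swamp the delta band).
- **Oscillations**: Gaussian noise band-limited by exact spectral masking
  and rescaled to a target RMS. An ideal mask rather than an IIR bandpass,
  because a −40 dB stopband floor from a filtered oscillation would sit
  above the 1/f tail and flatten every wide-range slope fit.
- **Coupling**: each compartment has one shared background and one shared
  oscillation per band; a channel mixes shared and private components of
  identical law as `√(1−c²)·private + c·shared`, preserving the marginal
  spectrum while phase locking rises monotonically with the coupling
  strength c — in every band.
- **Line noise**: a single phase-coherent 50 Hz sinusoid common to all
  channels (outside every PLV band, masked from all spectra).
- **Patient gain**: log-normal per-patient scale (SD 0.15 log10 units),
  emulating amplifier/impedance differences — what per-patient
  normalization exists to remove.

The default profiles encode the compartment signatures qualitatively:
tumoral — dominant delta (RMS 3.5), suppressed faster rhythms, flattest
exponent (χ = 1.7), strongest coupling (0.8); close/far peritumoral —
elevated beta (0.45/0.42), steepest exponents (2.4/2.35), intermediate
coupling; healthy — full physiological rhythms, χ = 2.0, weakest coupling
(0.3). Close and far peritumoral differ only marginally, mirroring how
similar those zones look electrophysiologically. Default channel counts are
121/243/212/134 (= 710) across the compartments and are configuration, not
constants — published counts for this kind of cohort vary between sections
(718/710/708) and nothing downstream assumes a total.

`generate_infiltration_table()` draws biopsy counts from a Poisson whose
log-rate is linear in the standardized target feature plus log-normal
noise; the coefficient is calibrated by bisection against Monte-Carlo
estimates of the realized low-stratum Spearman ρ, so a requested effect
(default ρ = −0.5 against absolute beta, the direction seen in low
infiltrated tissue) is recovered within ±0.15 at n = 200. Fractions of
biopsies are forced to count 0 (healthy) and to a tenfold rate (highly
infiltrated) so all three strata are represented; at a realistic 26
biopsies the realized correlation fluctuates widely, which is itself a
faithful property of small biopsy series.

What the generator does **not** emulate: interictal discharges and
seizures, stimulation artifacts, non-stationarity within a recording,
spatially graded (rather than block-wise) coupling, electrode geometry, and
any anatomical structure. Passing tests therefore show that the pipeline
recovers compartment-level spectral/connectivity structure from signals
with realistic statistical form — not that it would survive every artifact
of a real operating room.

## Problem sizes and determinism

The test suite and the acceptance script exercise the pipeline at reduced
scale — typically 500 Hz sampling, 8–20 s per channel, and 30 channels per
compartment for the end-to-end cohort (120 channels) — sizes chosen so the
full suite runs in well under a minute while keeping every statistical
check comfortably powered; exponent-recovery checks use the full 120 s at
2000 Hz that the analysis assumes. Every stochastic step (generation,
splits, folds, subspaces, permutation nulls) is seeded, and a pipeline
rerun under the same configuration and seed is byte-identical; the run
manifest records the package version, config hash and seed needed to
reproduce any artifact.

## Known limitations

- Narrow-range exponents on oscillation-rich spectra are band-edge biased
  (see above); they are discriminative features, not unbiased estimates.
- EDF export quantizes to 16-bit integers; the plain two-file text format
  round-trips exactly and is preferred for archival of synthetic data.
- Dunn's test assumes the omnibus ranking; both omnibus and pairwise
  results are always reported so neither is silently selected.
- Contact-level independence is assumed throughout; mixed-effects
  alternatives are out of scope.
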