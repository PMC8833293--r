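---
title: "Methods: signal features, anatomical ranking, and mixed-model
  inference for STN-DBS contact selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal features, anatomical ranking, and mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ernarank)
```

## The problem

A quadripolar DBS lead implanted in the subthalamic region carries four
contacts (0–3, ventral→dorsal: substantia nigra pars reticulata, two STN
contacts, zona incerta). Post-operative programming must pick the
contact whose stimulation yields the most motor benefit. `ernarank`
implements and evaluates objective per-contact rankings — ERNA power,
beta power, HFO power, anatomical proximity — against the per-contact
motor benefit measured in a monopolar survey, using a synthetic cohort
generator so that every stage is testable without patient data.

## Signal model and feature pipeline

**Re-referencing.** All channels are monopolar; each lead is
re-referenced to the mean of the contralateral lead's four unstimulated
contacts (`rereference_contralateral_average()`), which cancels
components common to both leads (mains interference, stimulation
artifact coupled through the shared reference) up to per-channel gain
differences.

**ERNA.** Burst stimulation (10 × 60 µs biphasic pulses at 130 Hz, one
burst per second, 10 s, 3.375 mA) evokes a damped oscillation after the
last pulse of each burst. The conditioned signal (2 Hz second-order
Butterworth high-pass, 49–51 Hz second-order Butterworth band-stop,
both zero-phase; then a centred moving average of 21 points at
38.4 kHz, scaled to the nearest odd sample count at other rates) is
epoched from the *offset* (end of second phase) of each burst's last
pulse, linearly detrended per epoch, and averaged over all bursts.
ERNA power at a contact is the square of the mean 4–20 ms RMS over the
available stimulation conditions (the other three contacts; fewer if
one is missing).

Decisions where the procedure was genuinely open:

- *t = 0 at pulse offset, not onset.* "Immediately after the burst"
  does not fix the origin; using the offset keeps the residual artifact
  out of the 4 ms guard. Both window endpoints are arguments of
  `rms_in_window()`.
- *All bursts averaged*; no first-burst discard.
- *Linear detrend* per epoch as the minimal implementation of baseline
  removal.
- *Smoothing applied to the continuous conditioned signal before
  epoching* (the alternative order is indistinguishable away from epoch
  edges).

**Zero-phase filtering.** A forward–reverse pass of an IIR filter has
transfer function |H(ω)|² and zero phase. The package applies that
operator exactly in the frequency domain (DFT multiplication by |H|²)
instead of running `filtfilt` in the time domain. The reason is
numerical, and we consider the usual time-domain implementation simply
wrong for this chain: the 49–51 Hz and spike ±0.5 Hz band-stops have
quality factors so high that a forward–reverse time-domain pass must
re-acquire the phase of any in-notch oscillation at every padding
boundary, leaving a transient of roughly 1/(πBW) seconds whose energy
dominates the notch residual regardless of padding strategy (we
measured 4–13 % residual RMS on a pure 50 Hz tone for reflect-padded,
long-padded and Gustafsson variants alike). The frequency-domain form
is transient-free, exactly linear, exactly zero-phase, and leaves a
50 Hz tone at ~10⁻⁸ of its input RMS. Its boundary condition is
periodic; that matters only within one filter time constant of the
segment ends, far from any analysed epoch.

**Spectra.** Beta power is the trapezoidal integral over 13–30 Hz of a
PSD from non-overlapping 1 s Blackman–Harris epochs (window-power
normalised, one-sided). HFO power integrates 200–400 Hz of a Thomson
multitaper PSD (20 DPSS tapers, time–bandwidth NW = (K+1)/2 = 10.5,
eigenspectra averaged over tapers and epochs). DPSS tapers are
computed from the standard symmetric tridiagonal eigenproblem at a base
length ≤ 1024 and spline-interpolated to the epoch length with
re-orthonormalisation; tapers are unit-energy, so Parseval holds to
within the estimator's leakage (≤ 5 % on stationary test signals).
Band integration uses the PSD *integral* (µV²), not mean density, so
band additivity and Parseval checks are exact on the grid.

**Spike handling.** Sharp interference tones in 200–400 Hz (mains
harmonics) are detected on the *STFT* spectrum — the multitaper's
~10 Hz smearing would hide a tone from its own running median — as
bins exceeding 8× the running median over ±10 Hz, merged within 1 Hz.
Each detected tone is removed by a zero-phase second-order Butterworth
band-stop at ±0.5 Hz before multitaper HFO estimation. The beta path is
*not* notched (line handling there is unnecessary at 13–30 Hz and the
rest-LFP path never passes the ERNA conditioning chain).

**Peak visibility.** `detect_band_peak()` replaces visual inspection:
a log–log linear 1/f background is fitted outside the candidate band
(excluding mains harmonics ±2 Hz), and a peak is "visible" when ≥ 3
consecutive in-band bins exceed 2× the fitted background. Thresholds
are arguments.

## Anatomy

The ideal target is constructed from red-nucleus landmarks: x = lateral
border displaced 3 mm further lateral (sign by side; the STN lies
lateral to the red nucleus), y = the supplied Bejjani-line point's y,
z = superior border − 2 mm. Contacts are ranked by Euclidean distance;
the expert adjustment (contact centrality within the STN, local STN
width ≥ 2 mm) is not algorithmically reproducible and is modelled as a
declarative override file validated to preserve a rank permutation,
with an audit trail (`apply_expert_overrides()`).

## Ranking and ties

Rank 1 is the largest power/benefit or the smallest distance. Measured
powers essentially never tie; the package still defines a total order:
ties break toward the more dorsal contact, reflecting the clinically
favoured dorsal STN region, and missing contacts rank last. The rule is
a package convention, exposed in `rank_by_value()`.

## Statistical layer

The response is per-contact motor benefit,
100·(off − on)/off, computed from hemibody UPDRS Part III sums (items
20–26); negative values (worsening) are retained, and 100 is a
structural upper bound (on-score ≥ 0).

- **Model.** `benefit ~ stim_fraction + rank factors + (1 | patient)`,
  fitted with `lme4`. Ranks enter as 4-level categorical predictors
  (reference rank 1): benefit does not step linearly across ranks, and
  the categorical coding imposes no shape. Stimulation fraction (1,
  0.75, 0.5, 0.25 of the chronic amplitude, reduced on side effects) is
  a numeric covariate. A nested hemisphere intercept is available but
  off by default.
- **ML, not REML**, whenever AICs are compared across fixed-effect
  structures — REML likelihoods are not comparable there.
- **Conditional r²** is the variance partition
  (σ²fixed + σ²patient) / (σ²fixed + σ²patient + σ²residual), with
  σ²fixed the variance of the fixed-effect linear predictor over the
  data; the convention is stated here because several exist.
- **Best subset**: all 15 non-empty subsets of
  {ERNA, beta, HFO, anatomy} are fitted by ML and ordered by AIC
  (`AIC = 2k − 2logLik`, recomputed and asserted in tests); the best
  model is compared with each nested sub-model by likelihood-ratio
  χ² tests, Holm-adjusted.
- **Holm** is the standard step-down with the monotonicity
  enforcement (`stats::p.adjust`): adjusted p's are running maxima of
  (m−i+1)·p(i). Note that equal raw p-values therefore share one
  adjusted value.
- **Blocked repeated-measures ANOVA**: a two-way fixed-effects least
  squares fit (condition + patient block), type-II sums of squares for
  imbalance; error df = N − 1 − (c−1) − (b−1), which reproduces the
  design dfs of a 111-observation/4-rank/14-patient table (94) and a
  168-observation/6-category/14-patient table (149). Tukey pairwise
  comparisons use least-squares means (`emmeans`), which collapse to
  the plain t-test at two levels.
- **Covariate screening** fits one mixed model per candidate (condition
  order; stimulation fraction) and retains Wald p < 0.05 with
  Satterthwaite dfs (`lmerTest`).

## The synthetic cohort generator

`generate_study()` emulates the statistical structure the analysis
assumes, not biophysics. Per hemisphere:

- A lead of four contacts with exact 3 mm centre spacing on a jittered
  oblique trajectory near (±11.5, −1.5, −9) mm; a latent benefit source
  near the dorsal STN contact (contact 2, jittered along and across the
  lead axis).
- **Per-modality sources.** ERNA, beta, and HFO each have their own
  source, displaced from the benefit source by Gaussian jitter of 0.3,
  0.8 and 1.5 mm per axis respectively. This expresses that the three
  signals co-localise to the dorsal STN only imperfectly, makes ERNA
  the most faithful and HFO the least faithful proxy of the effective
  stimulation site, and keeps the factor rankings correlated without
  being collinear (a single shared source makes the rankings nearly
  identical and the joint model rank-deficient).
- Rest LFP per contact: 1/f^1.5 background (FFT-shaped noise), an
  optional beta bump (Gaussian spectral bump at 16–24 Hz, visible with
  probability 19/28), an optional HFO bump (250–320 Hz, probability
  3/28), 50 Hz mains with a weak third harmonic, and optional
  narrowband tones at mains harmonics in 200–400 Hz. Source components
  scale as exp(−d/λ) with λ = 3 mm; one waveform per hemisphere scaled
  per contact (volume conduction of a common source), so band powers
  are strictly monotone in distance when the background is off. The
  aperiodic background instead decays with λ = 6 mm and carries
  per-contact log-normal gain jitter (SD 0.2): broadband activity is
  spatially diffuse and electrode gains vary, which bounds how
  informative band power can be in hemispheres without a visible peak.
- Burst segments: background + interference, a clipped biphasic
  artifact transient at every pulse (present on both leads through the
  shared reference, with 5 % gain jitter — so re-referencing cancels
  most of it, as in the recording setup it emulates), and a damped
  sinusoid (default 275 Hz, τ = 5 ms, onset 3 ms after last-pulse
  offset — defaults chosen to place the energy inside the analysed
  4–20 ms window, since no generative ERNA parameters are established
  for this cohort) scaled by exp(−d/λ) of the ERNA source distance.
- Outcomes: off-score uniform on 15–35 points; expected benefit
  70·exp(−d/3 mm)·fraction plus a patient intercept (SD 10) and
  measurement noise (SD 12 percentage points — single-session hemibody
  UPDRS scoring is noisy); on-scores floored at zero, so benefit ≤ 100
  structurally and may be negative. Side-effect-driven amplitude
  reductions occur with probability 0.4·(1 − exp(−d/4 mm)), drawn from
  {0.75, 0.5, 0.25} with weights 17:11:1. Condition order follows a
  balanced 4×4 Latin square across hemispheres ("counterbalanced" is
  otherwise unspecified). The clinician-selected contact equals the
  true best contact except with probability 3/28.
- Faults: each contact can be missing independently
  (`missing_channel_prob`), or exactly one ventral contact in the
  cohort (`force_one_missing = TRUE`, giving 111 analysable contacts in
  28 hemispheres).

Identical configuration (including its seed) reproduces a study
byte-for-byte.

**What the generator does not emulate:** volume-conduction or
neural-mass dynamics, non-stationarity (microlesion/"stun" drift within
a session), movement or cardiac artifacts, bipolar chronic
configurations, and any image content. Passing tests therefore show
that the pipeline is correct *given* the assumed statistical structure,
not that the structure matches any particular patient cohort.

For power, calibration and model-selection simulations that need
hundreds of replicate cohorts, `simulate_rank_table()` draws analysis
tables directly from the rank→benefit model (patient intercepts,
informative vs random factor rankings, stimulation-fraction covariate),
skipping signal synthesis.

## Numerical conventions and problem sizes

- Default sampling rate 4800 Hz (Nyquist 2400 Hz, six times the 400 Hz
  HFO edge); 38 400 Hz is supported for acquisition-faithful runs. The
  moving-average window scales to the odd sample count nearest 21
  samples at 38.4 kHz (3 at 4800 Hz, 1 at 1600 Hz).
- Unit tests run miniature cohorts (1–2 patients, 2–4 s segments,
  1600–4800 Hz); the acceptance script uses full 14-patient,
  28-hemisphere cohorts with 15 s rest segments at 4800 Hz, a
  strong-signal cohort for ranking recovery (ERNA amplitude 100 µV,
  background 2 µV, benefit noise 2, ERNA-source jitter 0 — "low noise"
  zeroes spatial as well as amplitude noise), 200 replicate cohorts for
  best-subset selection, and 1000 for null calibrations.
- Degenerate inputs: empty RMS windows, all-missing leads, constant
  responses, aliased ANOVA designs and non-nested model pairs raise
  classed errors (`ernarank_*_error`); a contact with no usable
  stimulation condition yields a flagged missing feature, not an error.
- Singular mixed fits (zero variance components) are returned with
  full diagnostics but `converged = FALSE`, and are excluded from
  best-subset winners.

## Known limitations

- The expert anatomical override is consumed, never inferred.
- ERNA is summarised by window RMS only; latency, frequency and decay
  features are out of scope.
- The statistical layer assumes one row per tested monopolar contact;
  bipolar chronic settings enter only as a flagged extra condition and
  are excluded from per-contact rankings.
- Ipsilateral stimulation effects on the contralateral hemibody are not
  modelled.
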