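---
title: "Decoding covert attention from posterior alpha power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding covert attention from posterior alpha power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(covertAlpha)
```

covertAlpha implements an offline analysis pipeline for a gaze-independent
brain-computer interface: a subject fixates a central dot and covertly shifts
visual attention to one of six peripheral discs; the direction of the shift
is decoded from the topography of posterior alpha-band (8-12 Hz) EEG power.
Because no recordings of the original experiment are publicly available, the
package pairs the analysis with a synthetic-data generator whose ground truth
is known exactly, so that every stage — spatial filtering, spectral
estimation, classification, and the cohort-level statistics — can be
validated end to end.

This vignette documents the generative model, each analysis stage with its
parameters and defaults, the numerical choices, and what the validation on
synthetic data does and does not establish about real EEG.

## Task design and the trial table

One session is 600 trials in six blocks of 100. A central cue indicates one
of six target discs (direction codes 1-6, anticlockwise from top-right; the
discs sit at clock positions top-right, top, top-left, bottom-left, bottom,
bottom-right, so two discs lie in each lateral hemifield and one each at top
and bottom). The cue is valid in 80% of trials. The target appears 2000 ms
after cue onset in 50% of trials, after 500 ms in 30%, and after a uniformly
random latency strictly between otherwise. Only the 2000 ms-latency subset
enters the neurophysiological analysis: in those trials the full two seconds
contain nothing but the shift and maintenance of attention.

`generateTrialTable()` enforces all of these proportions *exactly* by
stratified assignment followed by a seeded shuffle, rather than by Bernoulli
draws: design counts (600/480/300/180) are then deterministic test targets,
and directions are balanced both overall and within each latency class.
Reaction times are lognormal with geometric means of 719 ms (valid) and
881 ms (invalid) and sigma 0.2 on the log scale; responses are correct with
probability 0.87.

## The signal model

`generateSession()` synthesizes a 64-channel recording (63 scalp channels of
the extended 10-10 system plus an infraorbital EOG electrode) as a sum of
four processes per channel:

1. **Background.** 1/f ("pink") Gaussian noise with the amplitude spectrum
   flattened below 0.5 Hz, plus white sensor noise (`noiseSd`, default 3 uV).
   The pink process is generated band-limited to 30 Hz — the top of the
   analysis band — at a reduced sample rate and interpolated; above 30 Hz the
   white noise dominates the floor in any case.
2. **Cue-locked transient.** A Gaussian-windowed 5 Hz oscillation peaking
   250 ms after cue onset with *fixed phase across trials*, with a posterior
   topography. This reproduces the early delta/theta synchronization that is
   phase-locked to the cue (it reflects visual processing of the cue), and it
   is the only phase-locked component: the phase-locking factor isolates it.
3. **Alpha process.** Per channel, a narrowband Gaussian process (a complex
   lowpass envelope with Gaussian spectrum of width 1.2 Hz mixed onto a
   10 Hz carrier) scaled by a smooth posterior topography and by the subject's
   `alphaAmp`. Its envelope is modulated per trial:
   an early direction-*independent* dip around 500 ms post-cue (the
   desynchronization accompanying the preparation of the shift), then from
   about 1600 ms a multiplicative rise `1 + g0 + kappa * w(e, d)` — a
   direction-independent late synchronization `g0 = 0.4` plus the
   direction-tuned part that carries all decodable information.
4. **Ocular deflections.** A smooth sustained deflection after cue onset
   whose horizontal and vertical amplitudes follow the direction's sine and
   cosine, injected into F9/F10 and Fp2/EOGvu with opposite signs, scaled by
   `eogConfound`. With `eogConfound = 0` the EOG channels carry no direction
   information; with it large and `effectKappa = 0` the generator produces
   the dissociation used to validate the confound analysis.

The direction tuning `w(e, d)` is a von Mises bump (concentration 2) over a
preferred-direction angle assigned to each electrode by mapping the azimuth
of the parieto-occipital strip contralaterally onto the full direction
circle, so that each direction has a distinct preferred electrode and
opposite directions have maximally distinct topographies. The six per-
direction maps are normalized to equal total drive: directions differ in
*where* alpha synchronizes, not in overall power — the premise of
topography-based decoding. For right-directed shifts the left-hemisphere
weights are multiplied by `1 + hemiAsym`, reflecting the asymmetric
involvement of the hemispheres in directing attention; `hemiAsym = 1` makes
the left hemisphere's sensitivity to lateral shifts twice the right's.

`generateResting()` produces the 6-minute relaxation measurement: ten
15-second eyes-closed phases alternating with ten eyes-open phases, 2-second
breaks in between. The posterior alpha amplitude equals `alphaAmp` with eyes
closed and is attenuated by a factor 0.4 with eyes open (the attenuation
factor is a modeling choice; it merely needs to make the eyes-closed peak
unambiguous).

`generateCohort()` couples the two subject-level quantities that matter for
the performance predictor: `alphaAmp` is lognormal (median 6 uV, log-sd
0.35) and `effectKappa = -0.8 + 0.45 * alphaAmp + N(0, 0.1)`, truncated at
zero. The coupling constants were calibrated once, before the acceptance
suite was frozen, so that a cohort spans weak (peak accuracy near chance) to
strong (peak accuracy near 90%) decoders with a clearly positive
alpha-to-performance association; they are not fit to any quantity reported
for human subjects.

What the generator does *not* emulate: artifacts other than smooth ocular
deflections (no blinks, muscle, line noise), non-stationarity across blocks,
individual alpha peak frequencies (all subjects oscillate at 10 Hz),
volume-conduction correlations between channels (background noise is
independent per channel), and re-orienting dynamics on invalidly cued
trials. Green tests on synthetic data therefore establish the correctness of
the computations and the recoverability of effects of the assumed form — not
robustness to real-world artifacts.

## Current source density

The spatial filter is a spherical-spline surface Laplacian. With electrodes
on the unit sphere and kernels

$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^m}P_n(x), \qquad
  h(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m-1}}P_n(x),$$

the spline coefficients solve \((G + \lambda I)c + c_0\mathbf{1} = v\) subject
to \(\sum_i c_i = 0\), and the CSD at electrode \(i\) is \(\sum_j c_j
h(\cos\theta_{ij})\). Defaults are `m = 4`, `lambda = 1e-5`, `nTerms = 50` —
conventional spherical-spline settings; the reference describing the method
does not fix them, so they are package decisions, all exposed in
`buildSplineBasis()`. At 50 terms the series has converged to well below
1e-6. The head-radius scale is left at 1 (unitless CSD): only relative power
matters downstream. The transform is linear, reference-free (adding a
constant to all channels changes nothing) and maps a constant field to
exactly zero; the sign convention makes a potential bump a positive source.
The whole transform is precomputed as a single matrix, so applying it to
epochs is one matrix product.

CSD is applied to epoched data; since the operation is linear and acts per
time sample, applying it before or after epoching is equivalent.

## Time-frequency analysis and the phase-locking factor

`morletTransform()` convolves each trial and channel with complex Morlet
wavelets (Gaussian-windowed complex exponentials, unit energy) on a 4-30 Hz
grid in 1 Hz steps. The wavelet family uses a constant cycle count
`cycles = 3.5` with Gaussian truncation at `truncK = 3` standard deviations,
giving the widest (4 Hz) wavelet a half-support of \(k\,q/(2\pi f) =
417.8\) ms. That value matters for baseline correction: wavelets are acausal,
so post-cue activity can leak backwards into the baseline; a baseline window
ending at -419 ms (the default) is exactly safe, and `baselineCorrect()`
fails hard if the window end exceeds minus the realized half-width. Baseline
correction subtracts (default) or divides by the mean amplitude in the
window, per trial, channel and frequency.

Coefficients whose wavelet support extends past the epoch edge are
edge-contaminated. They are kept but flagged in a validity mask
(freqs x times) rather than NA-filled: a mask keeps low-frequency rows
usable near the epoch center while making edge handling explicit. (At 4 Hz
the default baseline window itself lies within the start-edge region — the
same compromise the original analysis makes implicitly; the leakage the
-419 ms bound guards against is specifically *post-cue* activity.)

The phase-locking factor normalizes complex coefficients to unit magnitude,
averages across trials and takes the magnitude: 1 for perfect phase locking,
and for n independent uniform phases \(E[\mathrm{PLF}] =
\sqrt{\pi}/(2\sqrt{n}) \approx 0.886/\sqrt{n}\). Zero-magnitude coefficients
are excluded and counted; a bin where all coefficients are zero is NA. PLF
is invariant to per-trial amplitude rescaling by construction.

## Bandpower features

Features are Welch-method alpha bandpower estimates per trial and electrode
over the 500-2000 ms window — the late synchronization; the early
desynchronization carries no direction-specific pattern and is not used. The
window of N samples is split into exactly 8 segments of length
\(L = \lfloor 2N/9 \rfloor\) with 50% overlap (floor rounding discards at
most 8 trailing samples and guarantees the printed segment count at every
sampling rate), each segment is Hamming-tapered, periodograms are
taper-power normalized one-sided densities, averaged across segments, and
the feature is the mean PSD over bins whose center frequency lies in
[8, 12] Hz inclusive. The electrode set is the nine posterior channels PO3,
PO4, PO7-PO10, Oz, O1, O2.

## Classification

Each of the fifteen unordered direction pairs is classified with
L2-regularized logistic regression: minimize mean negative log-likelihood
plus \((\lambda/2)\lVert w\rVert^2\) with the intercept unpenalized, by
damped Newton iterations to a gradient infinity-norm below 1e-7 (the final
per-fold fits; inner grid-search fits use the same solver). The protocol is
a stratified 10-fold outer cross-validation; within each outer training set
the features are z-normalized (the same statistics are applied to the outer
test fold — never fit on test data), a stratified 5-fold inner
cross-validation evaluates the candidate grid, and the *smallest* lambda
among the accuracy maximizers is chosen (ascending grid, first maximum);
the classifier is then retrained on the full outer training set. Reported
accuracy pools the correct fraction over all outer test predictions. The
default grid is logarithmic, \(10^{-3}\) to \(10^{3}\) in 13 steps; the
paper-level protocol (fold counts, normalization placement, tie-break) is
fixed, the grid is configuration.

Significance per pair is a McNemar test against assigning every trial to the
majority class (ties broken toward the first direction of the pair): with
b = trials the classifier gets right and the majority predictor wrong and
c the reverse, an exact two-sided binomial test of b against b + c when
b + c < 25, otherwise the continuity-corrected chi-squared
\((|b-c|-1)^2/(b+c)\).

A caveat worth documenting: against a *constant* majority predictor on a
balanced design, type-b discordances can only arise on one class and type-c
on the other, so \(\mathrm{Var}(b-c)\) is half of what the conditional
binomial model assumes and the test is conservative by \(\sqrt{2}\) in
sigma — its realized false-positive rate on null data is ~0.5% at a nominal
5%. The test never over-flags; it under-flags. This is a property of the
published construction itself, reproduced faithfully here.

## Ancillary statistics

- **Behavior**: per-subject accuracy and geometric-mean reaction times
  (exp of mean log RT) by cue validity, compared across subjects with paired
  t-tests (on log geometric means for RT), with and without the 2000 ms
  latency filter.
- **Left/right topography**: trials pooled over the two left vs the two
  right discs; per electrode the signed squared point-biserial correlation
  \(\mathrm{sgn}\,r^2\) between alpha power and the class indicator, right
  coded positive. Zero-variance electrodes yield 0 with a degenerate flag.
- **Hemisphere comparison**: the all-pairs analysis is rerun on the
  left-hemisphere posterior subset {PO3, PO7, PO9, O1}, the right subset
  {PO4, PO8, PO10, O2}, and all nine electrodes; per-subject peak accuracies
  are compared with a one-way ANOVA (`aov`) and Tukey-Kramer post-hoc
  contrasts (`TukeyHSD`).
- **EOG confound**: the identical nested-CV machinery (one code path) is
  applied to features from the two bipolar EOG derivations (vertical
  Fp2 - EOGvu, horizontal F10 - F9): the 0-2000 ms time series, low-pass
  filtered at 20 Hz (4th-order Butterworth, zero-phase) and decimated to 40
  samples per channel — 80 features. The exact feature construction is not
  prescribed anywhere, so this is a documented package decision
  (configuration-exposed); it captures slow ocular deflections without
  dimensional explosion. Cohort-level, the Pearson correlation between EEG
  and EOG accuracies is computed over pairs significant in either modality.

## The resting-alpha predictor

`alphaPeak()` takes the eyes-closed phases of the resting recording, applies
the CSD transform, estimates the Welch PSD per phase (2 s Hamming segments,
50% overlap — chosen for 0.5 Hz resolution within 15 s phases; unstated in
the source and configuration-exposed), averages across segments of all
phases, and extracts the maximum PSD and its frequency within [8, 12] Hz
inclusive (no prominence requirement). `alphaIndex()` pools a symmetric
parieto-occipital pair — PO3-PO4 by default, PO7-PO8 as the documented
alternative — as the *mean* of the two peak powers ("pooled" could also mean
sum or max; the mean is the package's reading and is exposed).
`correlatePredictor()` reports the Pearson correlation (two-sided) between
per-subject indices and peak decoding accuracies plus a least-squares line
for plotting. Peak accuracy is taken to be the best-pair accuracy of each
subject (the natural reading of "peak performance").

## Orchestration, determinism and problem sizes

`runSubject()`/`runCohort()` chain the stages with a validated configuration
(`runConfig()`; unknown keys are rejected) whose MD5 hash is stamped into
every output table and the manifest. All randomness derives from integer
seeds: the subject seed drives the generator, and CV fold assignments use
seeds derived from it by a fixed affine scheme, so stages can be rerun
independently and a rerun of the same configuration is bit-identical.
Generators restore the caller's RNG state.

Defaults are study scale: 1000 Hz sampling, 600 trials, 8 subjects. The test
suite and the Monte-Carlo validations run the same code at reduced problem
sizes — 64 Hz sampling, 200-600 trial sessions, a 5-point lambda grid, and
2-4 resting cycles — chosen so the full suite exercises every stage within a
desk-scale budget; the reduced sampling rate leaves the alpha band fully
below Nyquist, and the design proportions, fold structure and electrode sets
are identical to the defaults. The acceptance script uses 250 Hz with the
full 600-trial design and the default grid. Numerical tolerances asserted in
tests: CSD zero-on-constant and reference invariance at 1e-9; logistic
gradient at 1e-6 by central finite differences; series convergence at 1e-6;
Monte-Carlo quantities at 2-3 standard errors of their estimators.

## Known limitations

- The generator's simplifications listed above; in particular, identical
  10 Hz alpha frequency across subjects makes the resting peak search easier
  than in real data.
- The McNemar-vs-majority conservatism described under Classification.
- EDF output quantizes to 16 bits with per-channel physical ranges taken
  from the data; round trips are exact only to one quantization step, and
  events travel in a sidecar TSV (EDF annotation dialects vary).
- The electrode layout is computed from the standard 10-10 construction
  (midline arc in 18-degree steps, outer ring at 72 degrees, great-circle
  interpolation); it is an idealized sphere, not a digitized head.
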