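---
title: "Decoding frequency-phase-space SSVEP codes from high-density EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding frequency-phase-space SSVEP codes from high-density EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdssvep)
```

## The problem

A steady-state visual evoked potential (SSVEP) brain-computer interface
presents the user with an array of flickering patches; each patch is
luminance-modulated at a fixed frequency and initial phase, and the EEG over
the parieto-occipital cortex phase-locks to whichever patch the user looks
at. Classical 40-target spellers code each command by one
(frequency, phase) pair. `hdssvep` implements a *frequency-phase-space*
scheme: each of 40 flickers additionally carries up to five fixation points
(right, down, left, up, center), and the command is the pair
(flicker, fixation). Because the visual field is mapped retinotopically onto
the cortex, fixating different points of the *same* flicker produces
different amplitude and phase topographies on the scalp, so up to
40 x 5 = 200 commands can be decoded — provided the montage is dense enough
to resolve those topographies. The package supplies everything needed to
study this computationally: the code table and stimulus geometry, idealized
montages at four densities (66/256, 32/128, 21/64, 9/64 — parieto-occipital
channels / total cap channels), a synthetic EEG generator, the filter-bank
TDCA decoder with a TRCA baseline, dynamic-window classification,
information-transfer-rate (ITR) and narrow-band SNR metrics, cross-validated
evaluation, and greedy electrode selection.

## Paradigm

Flickers are arranged in a 5 x 8 matrix (144-px patches, 50-px gaps,
1920 x 1080 screen at 240 Hz, 70-cm viewing distance). Frequencies run
8 to 15.8 Hz in 0.2-Hz steps and phases 0 to 2&pi; in 0.35&pi; steps,
increasing down each column and then left to right. `build_code_table()`
assigns `target_id` so that all 40 flickers under the first fixation of a
combination occupy ids 1-40, the second fixation 41-80, and so on: the
40-class frequency-phase task is nested inside every larger task, which is
the natural layout when decoders trained on the large task are probed on the
flicker-only or fixation-only subtasks. Stimulus luminance follows sampled
sinusoidal modulation evaluated at frame starts,
`0.5 * (1 + sin(2 pi f n / refresh + phi))`. Lateral fixation points sit
25% of the patch edge (36 px) from the patch center.

## Montages

No public table enumerates the exact parieto-occipital channel lists of the
commercial caps, so the package ships *idealized* montages: electrodes on a
9.2-cm spherical head laid out after the 10-10 / 10-5 nomenclature
(sagittal rows in 18- or 9-degree steps, lateral positions at fixed
fractions of the arc from midline to the 10% circumference circle). The
64-, 128- and 256-channel caps are nested, and the four decoding
configurations are the posterior pool (P row and behind) trimmed
symmetrically by distance from POz to exactly 21, 32 and 66 channels; the
9/64 baseline is the fixed set {Pz, POz, Oz, PO3-PO6, O1, O2}. The lists are
plain-text files under `inst/extdata/` and can be replaced by users with
digitized positions. Mean nearest-neighbour distances come out near 1.25 cm
(256-cap) and 2.5 cm (64-cap), in line with the ~1.5 cm and ~2.8 cm
spacings of the corresponding commercial caps; the idealization is adequate
for distance summaries, the simulator's spatial gains and the noise kernel,
and is not claimed subject-accurate.

## The synthetic generator

`synth_trial()` builds each trial as

`x_ch(t) = sum_h A alpha^(h-1) g_ch(fix, h) sin(2 pi h f (t - tau) + h phi + psi_ch) + eta_ch(t)`

with Nh = 5 harmonics, amplitude decay alpha = 0.5, a fixed visual latency
tau = 140 ms applied as a pure delay of the deterministic component, a
smooth linear channel phase gradient psi, and spatially correlated noise
eta. The spatial gain g is a focal von-Mises blob on the scalp sphere:
lateral fixations displace the blob into the fixation-side hemisphere
(12 degrees at the fundamental, 28 degrees at harmonics, where
lateralization is strongest), down fixation broadens and lowers the
fundamental blob, up fixation concentrates it superiorly. A smooth linear
lateralization was tried first and rejected: it is so spatially band-limited
that nine electrodes capture it fully and montage density stops mattering,
which misrepresents the phenomenon the package studies. The background noise
is 1/f^beta in time (beta = 1), mixed across channels by an exponential
distance kernel (`exp(-d / 3 cm)`) plus 25% spatially white sensor noise.

**Noise level.** The controlled quantity is the narrow-band SNR, not the
absolute amplitude: `target_snr_db` is the expected single-trial Eq.-9-style
ratio (target 1-Hz bin over the mean of its 10 neighbours, measured on a
0.5-s epoch zero-padded to 1-Hz resolution) at the reference channel.
Calibration root-solves that expectation over seeded probe noise
realizations, per code. Two subtleties are worth knowing. First, a 0.5-s
epoch zero-padded to 1 s leaks coherently into the odd neighbour bins, which
caps the measurable ratio near 14 dB regardless of noise; integer-second
epochs have no such leakage. Second, the leakage floor does not average away
over trials, so `realized_snr()` reports the mean per-trial measurement by
default (directly comparable to the target) and the trial-averaged
topography-style measurement only on request. The default target of 8 dB
places the 200-class task in the regime the paradigm operates in:
intermediate accuracy at 0.1-0.2-s windows, high accuracy by 0.5 s. The
40-class dynamic-stopping benchmark instead runs at 12 dB because the
40-target condition it emulates operated near 85-97% accuracy at short
windows; at 8 dB that task would be artificially hard and the published
threshold grid mismatched to the score-gap scale.

What the generator does *not* emulate: eye movements and blinks,
nonstationarity across blocks, subject differences, volume-conduction
forward physics. Passing the property suite therefore shows the algorithms
are correct and behave sensibly under the assumed signal structure; it does
not certify performance on recorded EEG.

## Preprocessing

Epochs are extracted at `onset + 140 ms`, resampled to 250 Hz (anti-aliased
integer decimation), and decomposed into Nm = 5 subbands whose passbands are
`[m * 8 - 2, 90]` Hz: [6, 90] ... [38, 90]. Each subband is a Chebyshev
type-I band-pass (order 4, 0.5-dB ripple) applied *in the frequency domain*
through its squared magnitude response: this is exactly the transfer
function of one forward and one backward pass, so the operator is exactly
zero-phase and linear, and it vectorizes over all trials and channels in a
single FFT. The 0.5-dB ripple keeps the two-pass passband deviation within
1 dB. Epoch windows are half-open `[start, stop)` with 0-based samples;
resampling precedes filtering in the pipeline.

## The TDCA decoder

Task-discriminant component analysis learns one spatiotemporal filter per
subband, shared by all classes:

1. **Delay embedding.** Each trial `X (Nc x Np)` is stacked with its lags
   1..l (l = 4): training trials must carry l extra samples; test trials
   zero-pad what is genuinely missing. When a test epoch does provide
   samples beyond the scored window, up to l of them are used so that a
   training trial scores correlation 1 against its own template.
2. **Reference augmentation.** The embedded trial is concatenated along
   time with its projection onto the sine-cosine subspace of its class's
   frequency (Nh = 5 harmonics): `Xa = [X~, X~ P_f]`, `P_f = Y'(YY')^-1 Y`.
3. **Fisher eigenproblem.** With Hb the class means around the grand mean
   and Hw the trials around their class means, W solves
   `max tr(W' Hb Hb' W) / tr(W' Hw Hw' W)`; computed by Cholesky whitening
   of `Hw Hw' + eps I` (eps = 1e-6 of the mean diagonal; an absolute floor
   handles exactly noise-free data) and a symmetric eigendecomposition.
   D = 8 components are kept.
4. **Scoring.** `r_nm` is the Pearson correlation between the flattened
   projected trial and the flattened projected template (time-major over
   components — the value is invariant to the flattening order, the
   convention only fixes reproducibility); the fused feature is
   `rho_n = sum_m f_m r_nm^2` with `f_m = m^-1.25 + 0.25`, and the argmax
   wins, ties toward the lowest target id. Zero-variance projections score 0
   with a warning.

Test augmentation uses each candidate class's own `P_f`; the implementation
projects `X~' W` first and applies the projector afterwards in factored form
(`P_f = Q' Q` with Q the orthonormalized 2Nh x Np reference basis), batching
all trials of a scoring call into a handful of matrix products per unique
frequency. Templates are stored in projected form (`X_bar' W`, 2Np x D per
class and subband), the sufficient statistic for scoring and ~40x smaller
than raw augmented means at 200 classes.

The ensemble TRCA baseline learns one spatial filter per class maximizing
across-trial reproducibility (`max w'Sw / w'Qw`, S the inter-trial
covariance), concatenates them, and fuses subbands with the same weights.

## Dynamic-window classification

Scores are computed at windows 0.1..0.5 s (Nk = 5) from a single model
trained at the 0.5-s fallback window, with shorter windows zero-padded
through the test-mode embedding. Window k is weighted by the confidence
factor `c_k = (k / 50)^2` — k indexes the window list and the denominator is
fixed at 50 exactly as specified, even though Nk = 5 — and a label is
emitted at the first window where `Ts > -(rho_max - rho_2max)` computed on
the *weighted* features (the alternative, unweighted gaps, makes the
published threshold scale unusable: raw gaps are orders of magnitude larger
than |Ts|). If no window qualifies, the 0.5-s result is adopted. The
threshold grid is `Ts = -s * 1e-5 / 2`, s = 1..50, i.e. -0.5e-5 to -2.5e-4.
`sweep_thresholds()` evaluates the whole grid from one pass of per-window
features; the actual ITR of each point uses the mean output time plus the
0.5-s cue.

## Metrics and evaluation

* **ITR** (Wolpaw): bits per selection
  `log2 N + P log2 P + (1-P) log2((1-P)/(N-1))`; the *actual* rate divides
  by stimulation + cue time (bpm), the *theoretical* rate by stimulation
  time only (bps). Below-chance accuracies return a flagged value with a
  warning rather than an error.
* **Narrow-band SNR**: amplitude spectra at exactly 1-Hz resolution by
  zero-padding to the next whole second; SNR is the dB ratio of the target
  bin to the mean of its ten 1-Hz neighbours.
* **Cross-validation**: leave-one-block-out, refitting the decoder per
  (fold, window) and cropping test epochs from their start.
* **Channel correlations**: Pearson over trials concatenated in time;
  constant channels correlate 0 with a warning so degenerate fixtures stay
  computable.
* **Complex features**: trials projected on the first TDCA component of the
  first subband, zero-padded FFT, complex bin at the fundamental.
* **Personalized configuration**: argmax of actual ITR over
  (target number, combination, window), ties toward fewer targets then
  shorter windows; ITRs within 1e-4 bpm count as tied.
* **Greedy electrode search**: backward elimination from a full
  configuration down to 2 electrodes, refitting the decoder on every
  candidate subset, caching evaluations by sorted subset, and breaking ties
  by removing the lexicographically-last channel name.

## Benchmark scales

The test suite verifies the qualitative structure on reduced problem sizes
chosen once as part of the benchmark design: the 200-class density and SNR
checks use 4 + 1 and 2 + 1 blocks (train + test) generated directly at
250 Hz with 0.2-0.5-s epochs, averaged over 20 seeds. Two training blocks
are enough for the 45-row 9-channel filter but starve the 330-row 66-channel
filter, which is why the density comparison uses four. With these sizes the
full suite runs in well under half an hour on a single core.

## Known limitations

* Montage coordinates and channel identities are idealized stand-ins.
* The generator's topographies are calibrated only to qualitative patterns
  (lateralization direction, superior/inferior spread, noise-correlation
  decay), not to quantitative scalp maps.
* Accuracy *levels* on synthetic data are not comparable to recorded-EEG
  accuracies; only orderings and trends are meaningful.
* The epoch and model containers are RDS files with JSON sidecars; the
  sidecar carries the schema (`fs`, `channels`, `latency_corrected`,
  dimensions) so other toolchains can at least inspect the metadata.
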