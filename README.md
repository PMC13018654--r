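# hdssvep

High-density EEG decoding for frequency-phase-space SSVEP brain-computer
interfaces.

## What this package is for

Steady-state visual evoked potential (SSVEP) spellers code each command by
the frequency and phase of a flickering patch the user looks at. This
package implements a *hybrid frequency-phase-space* paradigm: each of 40
flickers (8-15.8 Hz in 0.2-Hz steps, phases in 0.35&pi; steps) carries up to
five fixation points (right, down, left, up, center), multiplying the
command set to as many as 200 targets. Because the visual field maps
retinotopically onto the cortex, fixating different points of the same
flicker produces different scalp topographies — information that only a
sufficiently dense electrode montage can resolve. The package is aimed at
BCI researchers who want to study this encoding/decoding stack
computationally: it ships the paradigm, idealized parieto-occipital montages
at four densities (66/256, 32/128, 21/64, 9/64), a seeded synthetic EEG
generator with the spatial structure the decoder exploits, the filter-bank
task-discriminant component analysis (TDCA) decoder plus an ensemble TRCA
baseline, confidence-weighted dynamic-window classification, ITR and
narrow-band SNR metrics, leave-one-block-out cross-validation, and greedy
backward electrode selection.

The decoding core, in the field's standard notation: trials are decomposed
into subbands `[m*8-2, 90]` Hz; each trial `X` is delay-embedded with lags
0..l (`X~`) and augmented with its projection onto the sine-cosine reference
subspace of its class frequency (`Xa = [X~, X~ P_f]`); the common filters
`W_m` solve the Fisher criterion `max tr(W' Hb Hb' W) / tr(W' Hw Hw' W)`;
classification fuses per-subband template correlations as
`rho_n = sum_m f_m r_nm^2`, `f_m = m^-1.25 + 0.25`, `r_nm = cor(X' W_m,
X_bar_n' W_m)`. Dynamic stopping emits the argmax at the first window k
where the confidence-weighted gap clears a threshold,
`Ts > -(rho_max - rho_2max)` with `c_k = (k/50)^2`, falling back to the
0.5-s result. ITR follows the Wolpaw formula, with actual (stimulation +
cue time, bits/min) and theoretical (stimulation only, bits/s) variants.

## Worked example

Generate a synthetic 80-target session (40 flickers x {down, up} fixations)
on the 9-electrode baseline montage, cross-validate the TDCA decoder and
compute the ITR:

```r
library(hdssvep)

combo   <- enumerate_fixation_combos(2)[[6]]   # combination 6: {down, up}
codes   <- build_code_table(combo)
montage <- load_configuration("9/64")
cfg     <- sim_config(montage, codes, fs = 250, seed = 1)
es      <- synth_dataset(3, codes, duration = 0.52, cfg)
es
#> epoch_set: 240 trials x 9 channels x 130 samples @ 250 Hz (80 classes, 3 blocks)

crossvalidate(es, codes, windows = c(0.1, 0.2, 0.3))
#>   window_s  accuracy
#> 1      0.1 0.1291667
#> 2      0.2 0.4166667
#> 3      0.3 0.6375000

itr(80, 0.4166667, stim = 0.2, cue = 0.5)$rate
#> [1] 142.7018
```

Accuracy rises with the analysis window, as it must; at this reduced scale
(3 blocks, 9 channels, 8-dB single-trial SNR) the 80-class task is hard at
0.1 s and tractable by 0.3 s. With the published online operating points the
same `itr()` reproduces the reported rates, e.g.
`itr(80, 0.9375, stim = 0.2, cue = 0.5)$rate` = 479.20 bpm.

A command-line wrapper over the same functions is installed at
`system.file("cli", "hdssvep.R", package = "hdssvep")` with subcommands
`generate`, `fit`, `evaluate`, `sweep-dynamic`, `greedy` and `itr`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hdssvep.R",package="hdssvep"))')" \
  itr --n-targets 80 --accuracy 0.9375 --stim 0.2 --cue 0.5
```

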