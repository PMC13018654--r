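test_that("generation is deterministic under a fixed seed", {
  codes <- tiny_codes()
  cfg <- tiny_cfg(codes = codes, seed = 7)
  x1 <- synth_trial(codes[1, ], 0.5, cfg)
  x2 <- synth_trial(codes[1, ], 0.5, cfg)
  expect_identical(x1, x2)
  es1 <- synth_dataset(2, codes, 0.5, cfg)
  es2 <- synth_dataset(2, codes, 0.5, cfg)
  expect_identical(es1$data, es2$data)
  expect_identical(es1$labels, es2$labels)
  # different seed changes the data
  es3 <- synth_dataset(2, codes, 0.5, tiny_cfg(codes = codes, seed = 8))
  expect_false(identical(es1$data, es3$data))
})

test_that("noise-free trials carry the visual latency in their phase", {
  # 14-Hz flicker (index 31), center fixation, phase gradient disabled:
  # the fitted phase of the fundamental must be -2*pi*f*tau (mod 2*pi)
  codes <- build_code_table("center")
  code <- codes[codes$flicker_index == 31, ]
  expect_equal(code$frequency_hz, 14)
  cfg <- tiny_cfg(codes = codes, noise_scale = 0,
                  phase_gradient = c(0, 0))
  x <- synth_trial(code, 1.0, cfg)
  f <- 14; fs <- 250; t <- (seq_len(ncol(x)) - 1) / fs
  phi_code <- code$phase_rad
  for (ch in c(1, 5, 9)) {
    fit <- stats::lm(x[ch, ] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1)
    phase <- atan2(fit$coefficients[2], fit$coefficients[1])
    expected <- (-2 * pi * f * cfg$latency + phi_code) %% (2 * pi)
    delta <- (phase - expected) %% (2 * pi)
    expect_lt(min(delta, 2 * pi - delta), 1e-6)
  }
})

test_that("lateralization index flips sign between right and left fixation", {
  codes <- build_code_table(c("right", "left"))
  sub <- codes[codes$flicker_index == 10, ]   # one flicker, both fixations
  m <- load_configuration("21/64")
  cfg <- sim_config(m, codes, fs = 250, noise_scale = 0, seed = 1)
  lat_index <- function(code) {
    x <- synth_trial(code, 0.5, cfg)
    nfft <- 250
    p2 <- vapply(seq_len(nrow(x)), function(ch) {
      sp <- Mod(stats::fft(c(x[ch, ], rep(0, nfft - ncol(x)))))
      sp[round(2 * code$frequency_hz) + 1L]^2
    }, 0)
    xpos <- m$x_cm
    (sum(p2[xpos > 0.5]) - sum(p2[xpos < -0.5])) /
      (sum(p2[xpos > 0.5]) + sum(p2[xpos < -0.5]))
  }
  li_right <- lat_index(sub[sub$fixation == "right", ])
  li_left <- lat_index(sub[sub$fixation == "left", ])
  expect_gt(li_right, 0)
  expect_lt(li_left, 0)
})

test_that("datasets are balanced and block-shuffled", {
  codes <- tiny_codes(flickers = 1:5, fixations = "center")
  cfg <- tiny_cfg(codes = codes)
  es <- synth_dataset(3, codes, 0.3, cfg)
  expect_equal(n_trials(es), 15L)
  expect_true(all(table(es$labels) == 3L))
  expect_true(all(table(es$blocks) == 5L))
  # within each block every code appears exactly once
  for (b in 1:3) {
    expect_setequal(es$labels[es$blocks == b], codes$target_id)
  }
  es1 <- synth_dataset(1, codes, 0.3, cfg)
  expect_setequal(es1$labels, codes$target_id)
  expect_error(synth_dataset(0, codes, 0.3, cfg), "n_blocks")
  expect_error(synth_dataset(1, codes[0, ], 0.3, cfg), "empty")
})

test_that("generator rejects configurations violating the Nyquist bound", {
  codes <- tiny_codes()
  expect_error(sim_config(load_configuration("9/64"), build_code_table("center"),
                          fs = 100), "Nyquist")
  cfg <- tiny_cfg(codes = codes)
  expect_error(synth_trial(codes[1, ], duration = 0.004, cfg), "2 samples")
})

test_that("noise correlations decay with interelectrode distance", {
  m <- load_configuration("21/64")
  codes <- tiny_codes()
  near <- c(); far <- c()
  for (seed in 1:5) {
    cfg <- sim_config(m, codes, fs = 250, amplitude = 0, noise_scale = 1,
                      seed = seed)
    es <- synth_dataset(1, codes[1:2, ], 2, cfg)
    cm <- channel_correlation(es)$matrix
    d <- as.matrix(stats::dist(as.matrix(m[, c("x_cm", "y_cm", "z_cm")])))
    ut <- upper.tri(d)
    near <- c(near, mean(cm[ut & d < 2]))
    far <- c(far, mean(cm[ut & d > 6]))
  }
  expect_gt(mean(near), mean(far))
  # close pairs (~1.5 cm) correlate strongly, distant (~6+ cm) weakly
  expect_gt(mean(near), 0.4)
  expect_lt(mean(far), mean(near) - 0.2)
})

test_that("target SNR calibration is realized within 2 dB", {
  codes <- tiny_codes()
  r <- vapply(1:3, function(seed) {
    cfg <- tiny_cfg(codes = codes, seed = seed, target_snr_db = 0)
    es <- synth_dataset(6, codes, 0.5, cfg)
    mean(vapply(seq_len(nrow(codes)),
                function(i) realized_snr(es, codes[i, ]), 0))
  }, 0)
  expect_true(all(abs(r) <= 2))
})

test_that("noiseless narrow-band SNR is numerically large", {
  codes <- build_code_table("center")
  code <- codes[codes$flicker_index == 31, ]
  cfg <- tiny_cfg(codes = codes, noise_scale = 0)
  # integer-second epoch: the sinusoid leaks nothing into the 1-Hz bins
  es <- synth_dataset(1, code, 1.0, cfg)
  expect_gt(realized_snr(es, code), 40)
})

test_that("doubling the signal at fixed noise raises the SNR by ~6 dB", {
  # integer frequencies (8, 10, 12, 14 Hz) so the 1-s epochs leak nothing
  # into the neighbour bins and the denominator is pure noise
  codes <- tiny_codes(flickers = c(1, 11, 21, 31), fixations = "center")
  d <- vapply(1:3, function(seed) {
    cfg1 <- tiny_cfg(codes = codes, seed = seed, noise_scale = 3, amplitude = 1)
    cfg2 <- tiny_cfg(codes = codes, seed = seed, noise_scale = 3, amplitude = 2)
    es1 <- synth_dataset(4, codes, 1.0, cfg1)
    es2 <- synth_dataset(4, codes, 1.0, cfg2)
    mean(vapply(seq_len(nrow(codes)), function(i)
      realized_snr(es2, codes[i, ]) - realized_snr(es1, codes[i, ]), 0))
  }, 0)
  expect_equal(mean(d), 20 * log10(2), tolerance = 0.1)
})

test_that("epoch tensors are finite and carry consistent metadata", {
  es <- noisy_dataset(n_blocks = 2)
  expect_true(all(is.finite(es$data)))
  expect_equal(length(es$labels), n_trials(es))
  expect_equal(length(es$channels), n_channels(es))
  expect_false(es$latency_corrected)
})
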