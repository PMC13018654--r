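test_that("ITR reproduces closed forms and worked examples", {
  # online worked examples: 160 targets at 96.875%, 0.25-s stimulation,
  # 0.5-s cue; 80 targets at 93.75%, 0.2 s
  expect_equal(itr(160, 0.96875, stim = 0.25, cue = 0.5)$rate, 551.42,
               tolerance = 0.01 / 551)
  s3a <- itr(80, 0.9375, stim = 0.2, cue = 0.5)
  expect_equal(s3a$rate, 479.20, tolerance = 0.01 / 479)
  expect_equal(itr(80, 0.9375, stim = 0.2, mode = "theoretical")$rate,
               27.95, tolerance = 0.01 / 27)
  expect_equal(s3a$unit, "bpm")
  # closed forms
  expect_equal(itr(64, 1, stim = 1, mode = "theoretical")$bits, 6)
  expect_equal(itr(40, 1/40, stim = 1, mode = "theoretical")$bits, 0,
               tolerance = 1e-12)
  expect_equal(itr(32, 1, stim = 0.25, cue = 0, mode = "theoretical")$rate,
               5 / 0.25)
  expect_warning(low <- itr(40, 0.01, stim = 1), "below chance")
  expect_true(low$below_chance)
  expect_error(itr(1, 0.5, 1), "2 targets")
  expect_error(itr(10, 1.5, 1), "\\[0, 1\\]")
  # bits strictly increasing in P above chance
  p <- seq(1 / 40 + 1e-3, 1, length.out = 200)
  bits <- vapply(p, function(pp) itr(40, pp, 1)$bits, 0)
  expect_true(all(diff(bits) > 0))
})

test_that("narrow-band SNR matches spectral closed forms", {
  fs <- 64
  # unit impulse: perfectly flat amplitude spectrum -> 0 dB
  x <- c(1, rep(0, fs - 1))
  expect_equal(as.numeric(snr_spectrum(x, f = 16, fs = fs)), 0,
               tolerance = 1e-9)
  # target bin 10x the flat background -> 20 dB
  x10 <- x + (9 * 2 / fs) * cos(2 * pi * 16 * (0:(fs - 1)) / fs)
  expect_equal(as.numeric(snr_spectrum(x10, f = 16, fs = fs)), 20,
               tolerance = 1e-9)
  # hand-built spectrum: y(f) = 4, neighbours alternating 1 and 3 summing
  # to 20 -> 20*log10(40/20)
  mag <- rep(0.2, fs)
  mag[16 + 1] <- 4
  mag[16 + 1 + (1:5)] <- c(1, 3, 1, 3, 1)
  mag[16 + 1 - (1:5)] <- c(3, 1, 3, 1, 3)
  mag[fs - (1:31) + 1] <- mag[(1:31) + 1]  # hermitian magnitude
  xt <- Re(stats::fft(mag, inverse = TRUE)) / fs
  expect_equal(as.numeric(snr_spectrum(xt, f = 16, fs = fs)),
               20 * log10(40 / 20), tolerance = 1e-9)
  # invariance to uniform scaling
  expect_equal(as.numeric(snr_spectrum(3.7 * x10, 16, fs)),
               as.numeric(snr_spectrum(x10, 16, fs)), tolerance = 1e-12)
  expect_error(snr_spectrum(x, f = 3, fs = fs), "too close")
  expect_error(snr_spectrum(x, f = 30, fs = fs), "too close")
})

test_that("leave-one-block-out cross-validation folds by block", {
  codes <- tiny_codes()
  es <- clean_dataset(n_blocks = 3, codes = codes)
  cv <- crossvalidate(es, codes, windows = c(0.1, 0.3))
  expect_equal(dim(attr(cv, "folds")), c(2L, 3L))
  expect_equal(cv$accuracy, c(1, 1))
  # fold-order invariance under block relabeling
  es2 <- noisy_dataset(n_blocks = 3, codes = codes, seed = 6)
  cv1 <- crossvalidate(es2, codes, windows = 0.2)
  es3 <- es2
  es3$blocks <- c(3L, 1L, 2L)[es2$blocks]
  cv2 <- crossvalidate(es3, codes, windows = 0.2)
  expect_equal(cv1$accuracy, cv2$accuracy)
  # a class missing from a training fold is an error
  bad <- es2
  bad$labels[bad$blocks != 1] <- bad$labels[bad$blocks != 1][1]
  expect_error(crossvalidate(bad, codes, windows = 0.2), "missing")
  one <- select_trials(es2, es2$blocks == 1)
  expect_error(crossvalidate(one, codes, windows = 0.2), "2 blocks")
})

test_that("channel correlations are Pearson matrices with sane degeneracy", {
  set.seed(3)
  x <- array(rnorm(2 * 1e5), dim = c(1, 2, 1e5))
  es <- epoch_set(x, 250, labels = 1L)
  cc <- channel_correlation(es)
  expect_equal(diag(cc$matrix), c(ch1 = 1, ch2 = 1))
  expect_equal(cc$matrix, t(cc$matrix))
  expect_lt(abs(cc$matrix[1, 2]), 0.05)
  # constant channel -> correlation 0 with a warning
  x[1, 2, ] <- 5
  es2 <- epoch_set(x, 250, labels = 1L)
  expect_warning(cc2 <- channel_correlation(es2), "constant")
  expect_equal(cc2$matrix[1, 2], 0)
})

test_that("complex features separate fixations and scale linearly", {
  codes <- tiny_codes(flickers = 10, fixations = c("down", "up"))
  es <- clean_dataset(n_blocks = 3, codes = codes)
  model <- fit_tdca(es, codes, window = 0.5)
  z <- complex_feature(es, model, codes)
  expect_length(z, n_trials(es))
  # identical noiseless trials collapse onto their class centroid
  for (id in codes$target_id) {
    zi <- z[es$labels == id]
    expect_lt(max(Mod(zi - mean(zi))) / Mod(mean(zi)), 1e-3)
  }
  # the two fixation centroids are distinct
  c1 <- mean(z[es$labels == codes$target_id[1]])
  c2 <- mean(z[es$labels == codes$target_id[2]])
  expect_gt(Mod(c1 - c2), 1e-3 * Mod(c1))
  # scaling a trial doubles the amplitude, not the phase
  es2 <- es
  es2$data <- 2 * es$data
  z2 <- complex_feature(es2, model, codes)
  expect_equal(Mod(z2), 2 * Mod(z), tolerance = 1e-9)
  expect_equal(Arg(z2), Arg(z), tolerance = 1e-9)
  bad <- es
  bad$labels[1] <- 999L
  expect_error(complex_feature(bad, model, codes), "unknown label")
})

test_that("personalized configuration selection maximizes actual ITR", {
  tab <- expand.grid(n_targets = c(40, 80), combo = 1:2,
                     window_s = c(0.2, 0.3))
  tab$accuracy <- 0.8
  tab$accuracy[tab$n_targets == 80 & tab$combo == 2 & tab$window_s == 0.2] <- 0.97
  best <- select_personalized_config(tab)
  expect_equal(best$n_targets, 80)
  expect_equal(best$combo, 2)
  expect_equal(best$window_s, 0.2)
  # oracle: exhaustive argmax over the table
  rates <- vapply(seq_len(nrow(tab)), function(i)
    itr(tab$n_targets[i], tab$accuracy[i], tab$window_s[i])$rate, 0)
  expect_equal(best$itr_actual_bpm, max(rates))
  # ties prefer the smaller target number, then the shorter window
  tie <- data.frame(n_targets = c(80, 40), combo = 1,
                    window_s = 0.2, accuracy = c(NA, NA))
  tie$accuracy[2] <- 0.9
  # find the 80-target accuracy giving exactly the same ITR
  f <- function(p) itr(80, p, 0.2)$rate - itr(40, 0.9, 0.2)$rate
  tie$accuracy[1] <- stats::uniroot(f, c(0.5, 0.999), tol = 1e-12)$root
  expect_equal(select_personalized_config(tie)$n_targets, 40)
  tie2 <- data.frame(n_targets = 40, combo = 1, window_s = c(0.3, 0.2),
                     accuracy = c(NA, NA))
  g <- function(p) itr(40, p, 0.3)$rate - itr(40, 0.85, 0.2)$rate
  tie2$accuracy <- c(stats::uniroot(g, c(0.5, 0.9999), tol = 1e-12)$root, 0.85)
  expect_equal(select_personalized_config(tie2)$window_s, 0.2)
  expect_error(select_personalized_config(data.frame()), "non-empty")
})
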