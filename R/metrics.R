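#' Information transfer rate (Wolpaw formula)
#'
#' Bits per selection are
#' `log2(N) + P*log2(P) + (1-P)*log2((1-P)/(N-1))` (with `0*log(0) = 0`).
#' The *actual* rate divides by stimulation plus cue time and is reported in
#' bits per minute (bpm); the *theoretical* rate divides by stimulation time
#' only and is reported in bits per second (bps).
#'
#' @param n_targets Number of targets N (>= 2).
#' @param p Classification accuracy in \[0, 1\].
#' @param stim Stimulation time per selection, in seconds.
#' @param cue Cue (gaze-shift) time in seconds, default 0.5; used by the
#'   actual mode only.
#' @param mode `"actual"` or `"theoretical"`.
#' @return A list: `bits` per selection, `rate`, `unit` ("bpm" or "bps"),
#'   `t_select` (the selection time used) and `below_chance` flag (set with
#'   a warning when `p < 1/N`).
#' @examples
#' itr(160, 0.96875, stim = 0.25)$rate  # 551.42 bpm
#' @export
itr <- function(n_targets, p, stim, cue = 0.5,
                mode = c("actual", "theoretical")) {
  mode <- match.arg(mode)
  if (n_targets < 2) stop("need at least 2 targets", call. = FALSE)
  if (p < 0 || p > 1) stop("accuracy must be in [0, 1]", call. = FALSE)
  if (stim <= 0) stop("stimulation time must be positive", call. = FALSE)
  plog <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_targets) + plog(p) +
    (if (p < 1) (1 - p) * log2((1 - p) / (n_targets - 1)) else 0)
  below <- p < 1 / n_targets
  if (below) warning("accuracy below chance (1/N); ITR is not meaningful")
  if (mode == "actual") {
    t_sel <- stim + cue
    list(bits = bits, rate = bits * 60 / t_sel, unit = "bpm",
         t_select = t_sel, below_chance = below)
  } else {
    list(bits = bits, rate = bits / stim, unit = "bps",
         t_select = stim, below_chance = below)
  }
}

# zero-padding target length: next multiple of fs samples, at least fs,
# so the FFT bin spacing is exactly 1 Hz
zero_pad_length <- function(ns, fs) {
  as.integer(fs * max(1, ceiling(ns / fs)))
}

#' Narrow-band SNR of an amplitude spectrum
#'
#' The epoch (averaged across trials beforehand) is zero-padded to a whole
#' number of seconds so the FFT bin spacing is exactly 1 Hz, and the SNR at
#' frequency `f` is `20*log10(10*y(f) / sum_k(y(f-k) + y(f+k)))` over the
#' k = 1..5 neighbouring 1-Hz bins on each side: the ratio of the target bin
#' to the mean of its 10 neighbours, in dB.
#'
#' @param mean_epoch Numeric matrix `[n_channels, n_samples]` (or a vector).
#' @param f Target frequency in Hz; `f - 5` must stay above 0 and `f + 5`
#'   below the Nyquist rate.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of per-channel SNR in dB, with the per-channel
#'   amplitude at the target bin in attribute `"amplitude"`.
#' @export
snr_spectrum <- function(mean_epoch, f, fs) {
  if (is.vector(mean_epoch)) mean_epoch <- matrix(mean_epoch, nrow = 1L)
  ns <- ncol(mean_epoch)
  if (f - 5 <= 0 || f + 5 >= fs / 2) {
    stop("target frequency too close to 0 Hz or the Nyquist rate",
         call. = FALSE)
  }
  nfft <- zero_pad_length(ns, fs)
  padded <- cbind(mean_epoch, matrix(0, nrow(mean_epoch), nfft - ns))
  spec <- Mod(t(stats::mvfft(t(padded))))
  step <- round(nfft / fs)          # bins per Hz (= 1 Hz spacing)
  bin <- round(f * nfft / fs) + 1L
  nb <- bin + c(-(5:1), 1:5) * step
  y <- spec[, bin]
  denom <- rowSums(spec[, nb, drop = FALSE])
  out <- 20 * log10(10 * y / denom)
  attr(out, "amplitude") <- y
  out
}

#' Leave-one-block-out cross-validated accuracy
#'
#' Every block serves once as the test set while the remaining blocks train
#' the decoder; the decoder is refit per (fold, window) and test epochs are
#' cropped from their start to the window length. Accuracies are averaged
#' over folds.
#'
#' @param es An [epoch_set()] with at least 2 blocks.
#' @param code_table Code table for the labels present.
#' @param windows Numeric vector of window lengths in seconds. The default
#'   grid runs 0.02..0.1 s in 0.02-s steps then 0.1..0.5 s in 0.1-s steps.
#' @param method `"tdca"` or `"trca"`.
#' @param bank Optional pre-built filter bank (defaults to the standard
#'   bank at `es$fs`).
#' @param ... Passed to the fitting function.
#' @return Data frame `window_s, accuracy` with per-fold accuracies in
#'   attribute `"folds"` (windows x folds).
#' @export
crossvalidate <- function(es, code_table,
                          windows = c(seq(0.02, 0.1, by = 0.02),
                                      seq(0.2, 0.5, by = 0.1)),
                          method = c("tdca", "trca"), bank = NULL, ...) {
  method <- match.arg(method)
  blocks <- sort(unique(es$blocks))
  if (length(blocks) < 2L) stop("need at least 2 blocks", call. = FALSE)
  if (is.null(bank)) bank <- build_filterbank(filterbank_spec(), es$fs)
  subbands <- apply_filterbank(es, bank)
  classes <- sort(unique(es$labels))
  acc <- matrix(NA_real_, length(windows), length(blocks))
  for (bi in seq_along(blocks)) {
    test_idx <- es$blocks == blocks[bi]
    train_sub <- lapply(subbands, select_trials, idx = !test_idx)
    test_sub <- lapply(subbands, select_trials, idx = test_idx)
    if (!setequal(unique(train_sub[[1]]$labels), classes)) {
      stop("a class is missing from the training folds", call. = FALSE)
    }
    truth <- test_sub[[1]]$labels
    for (wi in seq_along(windows)) {
      if (method == "tdca") {
        fit <- fit_tdca(train_sub, code_table, window = windows[wi],
                        bank = bank, ...)
        pred <- tdca_predict(fit, test_sub, window = windows[wi])
      } else {
        fit <- fit_trca(train_sub, code_table, window = windows[wi],
                        bank = bank, ...)
        pred <- trca_predict(fit, test_sub, window = windows[wi])
      }
      acc[wi, bi] <- mean(pred == truth)
    }
  }
  out <- data.frame(window_s = windows, accuracy = rowMeans(acc))
  attr(out, "folds") <- acc
  out
}

#' Interchannel Pearson correlation matrix
#'
#' Trials are concatenated along time per channel and all channel pairs are
#' correlated. A constant channel gets correlation 0 (with a warning) so the
#' matrix stays computable on degenerate inputs.
#'
#' @param es An [epoch_set()].
#' @return A list: `matrix` (channels x channels, unit diagonal),
#'   `mean_offdiag` (scalar summary).
#' @export
channel_correlation <- function(es) {
  d <- dim(es$data)
  flat <- t(matrix(aperm(es$data, c(3, 1, 2)), nrow = d[3] * d[1]))
  if (ncol(flat) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(flat, 1L, stats::sd)
  zero <- sds < 1e-300
  if (any(zero)) {
    warning("constant channel(s): ",
            paste(es$channels[zero], collapse = ", "),
            "; their correlations were set to 0")
  }
  cm <- matrix(0, d[2], d[2], dimnames = list(es$channels, es$channels))
  ok <- !zero
  if (sum(ok) >= 2L) cm[ok, ok] <- stats::cor(t(flat[ok, , drop = FALSE]))
  diag(cm) <- 1
  list(matrix = cm,
       mean_offdiag = mean(cm[upper.tri(cm)]))
}

#' Complex spectral feature of trials after spatiotemporal filtering
#'
#' Each trial is delay-embedded, projected onto the first TDCA component of
#' the first subband, zero-padded to 1-Hz resolution, and the complex FFT
#' bin at the trial's fundamental frequency is returned: amplitude and phase
#' of the stimulus-locked response after spatial denoising.
#'
#' @param es An [epoch_set()] with labeled trials.
#' @param model A fitted `tdca_model`.
#' @param code_table Code table resolving each label's frequency.
#' @return Complex vector, one value per trial.
#' @export
complex_feature <- function(es, model, code_table) {
  row <- match(es$labels, code_table$target_id)
  if (anyNA(row)) {
    stop("unknown label(s): ",
         paste(unique(es$labels[is.na(row)]), collapse = ", "),
         call. = FALSE)
  }
  freqs <- code_table$frequency_hz[row]
  subbands <- as_subband_list(es, model$bank)
  dat <- subbands[[1]]$data
  w1 <- model$filters[[1]][, 1]
  np <- min(n_samples(es), model$np_train)
  navail <- min(np + model$l, n_samples(es))
  nfft <- zero_pad_length(np, es$fs)
  vapply(seq_len(n_trials(es)), function(i) {
    emb <- delay_embed(matrix(dat[i, , seq_len(navail)], nrow = dim(dat)[2]), model$l,
                       np_out = np, test_mode = TRUE)
    y <- as.numeric(crossprod(emb, w1))
    sp <- stats::fft(c(y, rep(0, nfft - np)))
    sp[round(freqs[i] * nfft / es$fs) + 1L]
  }, complex(1))
}

#' Select the personalized configuration by actual ITR
#'
#' Given an accuracy table over target numbers, fixation combinations and
#' window lengths, computes the actual ITR of every cell and returns the
#' argmax; ties prefer the smaller target number, then the shorter window.
#'
#' @param tab Data frame with columns `n_targets`, `combo`, `window_s`,
#'   `accuracy`.
#' @param cue Cue time in seconds (0.5).
#' @return The winning row of `tab` with `itr_actual_bpm` appended.
#' @export
select_personalized_config <- function(tab, cue = 0.5) {
  need <- c("n_targets", "combo", "window_s", "accuracy")
  if (!is.data.frame(tab) || nrow(tab) == 0L || !all(need %in% names(tab))) {
    stop("need a non-empty table with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab$itr_actual_bpm <- vapply(seq_len(nrow(tab)), function(i) {
    suppressWarnings(itr(tab$n_targets[i], tab$accuracy[i],
                         stim = tab$window_s[i], cue = cue)$rate)
  }, 0)
  # ITRs equal to 1e-4 bpm count as tied (beyond meaningful precision)
  ord <- order(-round(tab$itr_actual_bpm, 4), tab$n_targets, tab$window_s)
  tab[ord[1L], , drop = FALSE]
}
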