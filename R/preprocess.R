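#' Filter-bank specification
#'
#' Subband m spans `m * f_min - 2` Hz to `f_high` Hz: with the default
#' `f_min = 8` and five subbands, the passbands are \[6, 90\], \[14, 90\],
#' \[22, 90\], \[30, 90\] and \[38, 90\] Hz. Harmonic-rich subbands are later
#' fused with the weights `f_m = m^-1.25 + 0.25`.
#'
#' @param f_min Minimum stimulus frequency in Hz (8).
#' @param n_subbands Number of subbands Nm (5).
#' @param f_high Common upper passband edge in Hz (90).
#' @param order Chebyshev type-I order per direction (4).
#' @param ripple_db Passband ripple per direction in dB (0.5).
#' @return A `filterbank_spec` with a `bands` matrix (`low`, `high`).
#' @export
filterbank_spec <- function(f_min = 8, n_subbands = 5L, f_high = 90,
                            order = 4L, ripple_db = 0.5) {
  m <- seq_len(n_subbands)
  bands <- cbind(low = m * f_min - 2, high = rep(f_high, n_subbands))
  if (any(bands[, "low"] >= bands[, "high"])) {
    stop("subband lower edge reaches the upper edge; reduce n_subbands",
         call. = FALSE)
  }
  structure(list(f_min = f_min, n_subbands = as.integer(n_subbands),
                 f_high = f_high, bands = bands,
                 order = as.integer(order), ripple_db = ripple_db),
            class = "filterbank_spec")
}

#' Write / read a filter-bank specification as JSON
#'
#' @param spec A [filterbank_spec()].
#' @param path File path.
#' @export
write_filterbank_spec <- function(spec, path) {
  jsonlite::write_json(list(f_min = spec$f_min,
                            n_subbands = spec$n_subbands,
                            f_high = spec$f_high, order = spec$order,
                            ripple_db = spec$ripple_db),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filterbank_spec
#' @export
read_filterbank_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  filterbank_spec(f_min = x$f_min, n_subbands = x$n_subbands,
                  f_high = x$f_high, order = x$order,
                  ripple_db = x$ripple_db)
}

#' Build the zero-phase band-pass operators of a filter bank
#'
#' Each subband is a Chebyshev type-I band-pass design whose squared
#' magnitude response (the transfer function of one forward and one backward
#' pass) is applied in the frequency domain, giving an exactly zero-phase,
#' exactly linear operator.
#'
#' @param spec A [filterbank_spec()].
#' @param fs Sampling rate in Hz; must exceed twice the upper edge.
#' @return A `filterbank` object holding the designed coefficients.
#' @export
build_filterbank <- function(spec = filterbank_spec(), fs) {
  if (fs / 2 <= spec$f_high) {
    stop(sprintf("sampling rate %g Hz too low for the %g-Hz upper edge",
                 fs, spec$f_high), call. = FALSE)
  }
  filts <- lapply(seq_len(spec$n_subbands), function(m) {
    signal::cheby1(spec$order, spec$ripple_db,
                   spec$bands[m, ] / (fs / 2), type = "pass")
  })
  structure(list(spec = spec, fs = fs, filters = filts),
            class = "filterbank")
}

# magnitude response of an IIR design at the FFT bin frequencies of an
# n-point transform; squared = the forward-backward (two-pass) response
iir_gain <- function(filt, n, squared = TRUE) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  h <- polyval_rev(filt$b, z) / polyval_rev(filt$a, z)
  Mod(h)^(if (squared) 2 else 1)
}

fb_gain <- function(filt, n) iir_gain(filt, n, squared = TRUE)

# evaluate sum(coef[k] * z^-(k-1)) (filter polynomial in z^-1)
polyval_rev <- function(coef, z) {
  acc <- rep(0 + 0i, length(z))
  for (k in rev(seq_along(coef))) acc <- acc * z + coef[k]
  acc
}

# zero-phase filter a samples x series matrix in the frequency domain
fft_filter_mat <- function(x, gain) {
  n <- nrow(x)
  stopifnot(length(gain) == n)
  Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
}

#' Apply a filter bank to an epoch set
#'
#' @param es An [epoch_set()].
#' @param bank A [build_filterbank()] result built for `es$fs`.
#' @return A list of `n_subbands` filtered `epoch_set`s, same shapes.
#' @export
apply_filterbank <- function(es, bank) {
  stopifnot(inherits(es, "epoch_set"), inherits(bank, "filterbank"))
  if (abs(bank$fs - es$fs) > 1e-9) {
    stop("filter bank was built for ", bank$fs, " Hz, data are ", es$fs,
         " Hz", call. = FALSE)
  }
  d <- dim(es$data)
  # samples in rows: one FFT across all trials x channels
  flat <- matrix(aperm(es$data, c(3, 1, 2)), nrow = d[3])
  lapply(bank$filters, function(filt) {
    g <- fb_gain(filt, d[3])
    out <- fft_filter_mat(flat, g)
    arr <- aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    es2 <- es
    es2$data <- arr
    es2
  })
}

#' Extract epochs from a continuous recording
#'
#' Epochs span `[onset + latency, onset + latency + window)` and are then
#' resampled to `fs_out` (anti-aliased integer-factor decimation).
#'
#' @param cont Numeric matrix `[n_channels, n_samples]` of continuous data.
#' @param fs_in Sampling rate of `cont` in Hz.
#' @param onsets Event (stimulus onset) times in seconds.
#' @param latency Visual latency offset in seconds (default 0.140).
#' @param window Epoch length in seconds.
#' @param fs_out Output sampling rate in Hz (must divide `fs_in`).
#' @param labels,blocks Optional per-event metadata.
#' @param channels Optional channel names.
#' @return An [epoch_set()] with `latency_corrected = TRUE`.
#' @export
extract_epochs <- function(cont, fs_in, onsets, latency = 0.140, window,
                           fs_out = fs_in, labels = seq_along(onsets),
                           blocks = rep(1L, length(onsets)),
                           channels = NULL) {
  stopifnot(is.matrix(cont))
  n_in <- ncol(cont)
  np_in <- round(window * fs_in)
  start <- round((onsets + latency) * fs_in)  # 0-based sample offsets
  bad <- start < 0 | (start + np_in) > n_in
  if (any(bad)) {
    stop("event(s) ", paste(which(bad), collapse = ", "),
         " extend beyond the recording", call. = FALSE)
  }
  epochs <- array(0, dim = c(length(onsets), nrow(cont), np_in))
  for (i in seq_along(onsets)) {
    epochs[i, , ] <- cont[, (start[i] + 1):(start[i] + np_in), drop = FALSE]
  }
  es <- epoch_set(epochs, fs_in, labels, blocks, channels,
                  latency_corrected = TRUE)
  if (fs_out != fs_in) es <- resample_epochs(es, fs_out)
  es
}

#' Resample an epoch set by an integer decimation factor
#'
#' Anti-alias low-pass (zero-phase Chebyshev type-I, order 8, cutoff at 80%
#' of the output Nyquist) followed by point decimation.
#'
#' @param es An [epoch_set()].
#' @param fs_out Target rate; `es$fs / fs_out` must be a whole number.
#' @return The resampled `epoch_set`.
#' @export
resample_epochs <- function(es, fs_out) {
  r <- es$fs / fs_out
  if (abs(r - round(r)) > 1e-9) {
    stop("resampling factor ", r, " is not an integer", call. = FALSE)
  }
  r <- round(r)
  if (r == 1L) return(es)
  d <- dim(es$data)
  lp <- signal::cheby1(8, 0.05, 0.8 / r)
  flat <- matrix(aperm(es$data, c(3, 1, 2)), nrow = d[3])
  flat <- fft_filter_mat(flat, iir_gain(lp, d[3], squared = FALSE))
  keep <- seq(1L, d[3], by = r)
  arr <- aperm(array(flat, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  out <- es
  out$data <- arr[, , keep, drop = FALSE]
  out$fs <- fs_out
  out
}
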