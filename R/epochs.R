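#' Epoched multichannel EEG
#'
#' Container for a trials x channels x samples tensor plus metadata. Values
#' are in microvolts; `labels` holds the target id of each trial, `blocks`
#' the acquisition block, and `latency_corrected` says whether the epochs
#' were extracted with the visual-latency offset already applied.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`.
#' @param fs Sampling rate in Hz.
#' @param labels Integer vector of target ids, one per trial.
#' @param blocks Integer vector of block ids, one per trial.
#' @param channels Character vector of channel names.
#' @param latency_corrected Logical flag.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, fs, labels, blocks = rep(1L, dim(data)[1]),
                      channels = NULL, latency_corrected = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n[2]))
  if (length(labels) != n[1] || length(blocks) != n[1]) {
    stop("labels/blocks must have one entry per trial", call. = FALSE)
  }
  if (length(channels) != n[2] || anyDuplicated(channels)) {
    stop("channels must be ", n[2], " unique names", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("epoch data contain NaN/Inf", call. = FALSE)
  structure(list(data = data, fs = fs,
                 labels = as.integer(labels), blocks = as.integer(blocks),
                 channels = as.character(channels),
                 latency_corrected = isTRUE(latency_corrected)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz (%d classes, %d blocks)\n",
              d[1], d[2], d[3], x$fs, length(unique(x$labels)),
              length(unique(x$blocks))))
  invisible(x)
}

#' Epoch set dimensions
#'
#' @param es An [epoch_set()].
#' @return Trial, channel or sample count.
#' @export
n_trials <- function(es) dim(es$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(es) dim(es$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(es) dim(es$data)[3]

#' Subset an epoch set to a montage or channel list
#'
#' Slices the channel axis; trial and sample axes and all metadata are
#' preserved. Channels are returned in the requested order.
#'
#' @param es An [epoch_set()].
#' @param m An `eeg_montage` or character vector of channel names, all of
#'   which must be present in `es`.
#' @return The channel-sliced `epoch_set`.
#' @export
subset_channels <- function(es, m) {
  want <- if (inherits(m, "eeg_montage") || is.data.frame(m)) m$name else as.character(m)
  miss <- setdiff(want, es$channels)
  if (length(miss) > 0L) {
    stop("channel(s) not in the epoch set: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(want, es$channels)
  out <- es
  out$data <- es$data[, idx, , drop = FALSE]
  out$channels <- es$channels[idx]
  out
}

#' Select trials of an epoch set
#'
#' @param es An [epoch_set()].
#' @param idx Integer or logical trial index.
#' @return The trial-sliced `epoch_set`.
#' @export
select_trials <- function(es, idx) {
  out <- es
  out$data <- es$data[idx, , , drop = FALSE]
  out$labels <- es$labels[idx]
  out$blocks <- es$blocks[idx]
  out
}

#' Crop epochs to a time window from the epoch start
#'
#' Half-open sample window `[0, round(window * fs))`; used to evaluate
#' decoders at shorter data lengths than were recorded.
#'
#' @param es An [epoch_set()].
#' @param window Window length in seconds (or `n_samp` directly).
#' @param n_samp Optional explicit sample count.
#' @return The cropped `epoch_set`.
#' @export
crop_epochs <- function(es, window, n_samp = NULL) {
  if (is.null(n_samp)) n_samp <- round(window * es$fs)
  if (n_samp < 1L || n_samp > n_samples(es)) {
    stop("window of ", n_samp, " samples outside the recorded epoch (",
         n_samples(es), " samples)", call. = FALSE)
  }
  out <- es
  out$data <- es$data[, , seq_len(n_samp), drop = FALSE]
  out
}

#' Write / read an epoch set container
#'
#' The container is a single RDS file holding the `data`, `labels` and
#' `blocks` datasets, accompanied by a JSON sidecar (same path with
#' `.json` appended) mirroring the scalar attributes `fs`, `channels` and
#' `latency_corrected` for language-agnostic inspection.
#'
#' @param es An [epoch_set()].
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly (`read_epoch_set` returns the `epoch_set`).
#' @export
write_epoch_set <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  saveRDS(list(data = es$data, labels = es$labels, blocks = es$blocks,
               fs = es$fs, channels = es$channels,
               latency_corrected = es$latency_corrected),
          path, version = 2L)
  sidecar <- list(fs = es$fs, channels = es$channels,
                  latency_corrected = es$latency_corrected,
                  n_trials = n_trials(es), n_channels = n_channels(es),
                  n_samples = n_samples(es))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read epoch container '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  need <- c("data", "labels", "blocks", "fs", "channels", "latency_corrected")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("corrupt epoch container '", path, "': missing dataset(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  epoch_set(x$data, x$fs, x$labels, x$blocks, x$channels,
            x$latency_corrected)
}
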