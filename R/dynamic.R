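#' Dynamic-window classification configuration
#'
#' Decisions are emitted at the first window whose confidence-weighted score
#' gap clears a (negative) threshold. The confidence factor of window k is
#' `c_k = (k / 50)^2` (k indexes the window list, 1-based; the denominator
#' is fixed at 50). The threshold grid is `Ts_s = -s * 1e-5 / 2` for
#' s = 1..n_thresholds, spanning -0.5e-5 .. -2.5e-4 at the default 50.
#'
#' @param windows Increasing window lengths in seconds (0.1..0.5 by 0.1).
#' @param threshold Single threshold Ts (negative) for
#'   [dynamic_classify()]; default is the most lenient grid point.
#' @param n_thresholds Grid size Ns (50).
#' @param confidence_denominator Denominator of the confidence factor (50).
#' @return A `dynamic_config`.
#' @export
dynamic_config <- function(windows = seq(0.1, 0.5, by = 0.1),
                           threshold = NULL, n_thresholds = 50L,
                           confidence_denominator = 50) {
  if (any(diff(windows) <= 0)) {
    stop("windows must be strictly increasing", call. = FALSE)
  }
  grid <- -seq_len(n_thresholds) * 1e-5 / 2
  threshold <- threshold %||% grid[1]
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  structure(list(windows = windows, threshold = threshold,
                 threshold_grid = grid,
                 confidence_denominator = confidence_denominator,
                 fallback_window = windows[length(windows)]),
            class = "dynamic_config")
}

confidence_factors <- function(cfg) {
  (seq_along(cfg$windows) / cfg$confidence_denominator)^2
}

# confidence-weighted features for every (trial, window): returns a list
# with rho_t [trials x classes x windows], gaps [trials x windows] and
# argmax labels [trials x windows]
dynamic_features <- function(model, es, cfg) {
  ck <- confidence_factors(cfg)
  nt <- n_trials(es)
  ncls <- length(model$classes)
  nk <- length(cfg$windows)
  np <- round(cfg$windows * model$fs)
  if (max(np) > n_samples(es)) {
    stop("windows exceed the available trial data", call. = FALSE)
  }
  subbands <- as_subband_list(es, model$bank)
  rho_t <- array(NA_real_, dim = c(nt, ncls, nk))
  for (k in seq_len(nk)) {
    rho_t[, , k] <- ck[k] * tdca_rho(model, subbands, np_test = np[k])
  }
  top2 <- function(v) {
    o <- order(v, decreasing = TRUE)[1:2]
    c(v[o[1]] - v[o[2]], o[1])
  }
  gaps <- matrix(NA_real_, nt, nk)
  labs <- matrix(NA_integer_, nt, nk)
  for (k in seq_len(nk)) {
    tg <- apply(rho_t[, , k, drop = FALSE], 1L, function(v) top2(v))
    gaps[, k] <- tg[1, ]
    labs[, k] <- model$classes[tg[2, ]]
  }
  list(rho_t = rho_t, gaps = gaps, labels = labs)
}

# emission window index per trial for a threshold Ts: first window whose
# risk cost satisfies Ts > -(gap); fallback = last window
emission_index <- function(gaps, ts) {
  nk <- ncol(gaps)
  apply(gaps, 1L, function(g) {
    k <- which(ts > -g)
    if (length(k) > 0L) k[1] else nk
  })
}

#' Classify a single trial with dynamic stopping
#'
#' Evaluates the confidence-weighted fused features at each window in turn
#' and emits the argmax label at the first window where the risk cost
#' `-(rho_max - rho_2max)` falls below the threshold; if no window
#' qualifies, the fallback (longest-window) result is adopted.
#'
#' @param trial Numeric matrix `[n_channels, n_samples]` covering the
#'   longest window.
#' @param model A fitted `tdca_model`.
#' @param cfg A [dynamic_config()].
#' @return A `decision_trace` list: per-window data frame (`window_s`,
#'   `gap`, `emitted`), `label`, `output_time`, `fallback_used`.
#' @export
dynamic_classify <- function(trial, model, cfg = dynamic_config()) {
  stopifnot(is.matrix(trial))
  es <- epoch_set(array(trial, dim = c(1L, nrow(trial), ncol(trial))),
                  model$fs, labels = model$classes[1],
                  channels = model$channels)
  ft <- dynamic_features(model, es, cfg)
  k <- emission_index(ft$gaps, cfg$threshold)[1]
  fallback <- !any(cfg$threshold > -ft$gaps[1, ])
  trace <- data.frame(window_s = cfg$windows,
                      gap = ft$gaps[1, ],
                      emitted = seq_along(cfg$windows) == k)
  structure(list(trace = trace,
                 label = ft$labels[1, k],
                 output_time = cfg$windows[k],
                 fallback_used = fallback),
            class = "decision_trace")
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf("decision_trace: label %d at %.2f s%s\n", x$label,
              x$output_time, if (x$fallback_used) " (fallback)" else ""))
  invisible(x)
}

#' Sweep the dynamic-stopping threshold grid
#'
#' For every threshold in the grid, classifies all trials dynamically and
#' reports the mean output time, accuracy, and the actual ITR computed from
#' the mean output time plus the cue time.
#'
#' @param es Labeled test [epoch_set()].
#' @param model A fitted `tdca_model`.
#' @param cfg A [dynamic_config()].
#' @param cue Cue time in seconds (0.5).
#' @return Data frame `threshold, mean_time_s, accuracy, actual_itr_bpm`,
#'   one row per grid point.
#' @export
sweep_thresholds <- function(es, model, cfg = dynamic_config(), cue = 0.5) {
  if (length(cfg$threshold_grid) == 0L) stop("empty threshold grid", call. = FALSE)
  ft <- dynamic_features(model, es, cfg)
  n <- length(model$classes)
  out <- lapply(cfg$threshold_grid, function(ts) {
    k <- emission_index(ft$gaps, ts)
    lab <- ft$labels[cbind(seq_len(nrow(ft$labels)), k)]
    acc <- mean(lab == es$labels)
    mt <- mean(cfg$windows[k])
    rate <- suppressWarnings(itr(n, acc, stim = mt, cue = cue)$rate)
    data.frame(threshold = ts, mean_time_s = mt, accuracy = acc,
               actual_itr_bpm = rate)
  })
  do.call(rbind, out)
}
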