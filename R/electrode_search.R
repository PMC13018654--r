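#' Greedy backward electrode elimination
#'
#' Starting from the full initial electrode set, each iteration evaluates
#' every subset obtained by removing exactly one electrode, keeps the subset
#' with the highest mean accuracy across the supplied datasets, and repeats
#' until only 2 electrodes remain. The best subset and its accuracy are
#' recorded at every size. Ties are broken by removing the
#' lexicographically-last channel name, making the search deterministic for
#' a deterministic evaluator. Evaluations are cached by sorted channel
#' subset.
#'
#' @param datasets A list of [epoch_set()]s (or any objects the evaluator
#'   accepts); the optimized quantity is the mean accuracy over them.
#' @param init Initial channel set: an `eeg_montage` or character vector
#'   (at least 3 channels).
#' @param evaluator `function(dataset, channels) -> accuracy in [0, 1]`,
#'   deterministic given its arguments.
#' @return A `greedy_path`: data frame `size, mean_accuracy` with the
#'   channel sets in attribute `"channels"` (list) and the per-step
#'   candidate evaluations in attribute `"steps"`.
#' @export
greedy_backward <- function(datasets, init, evaluator) {
  chans <- if (inherits(init, "eeg_montage") || is.data.frame(init)) init$name else as.character(init)
  if (length(chans) < 3L) stop("need at least 3 initial channels", call. = FALSE)
  if (!is.list(datasets)) datasets <- list(datasets)
  cache <- new.env(parent = emptyenv())
  mean_acc <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    acc <- vapply(datasets, function(ds) {
      a <- tryCatch(evaluator(ds, subset), error = function(e) {
        stop("evaluator failed on subset {",
             paste(subset, collapse = ", "), "}: ", conditionMessage(e),
             call. = FALSE)
      })
      as.numeric(a)
    }, 0)
    cache[[key]] <- mean(acc)
    cache[[key]]
  }
  sizes <- integer()
  accs <- numeric()
  sets <- list()
  steps <- list()
  cur <- chans
  record <- function(size, acc, set) {
    sizes <<- c(sizes, size)
    accs <<- c(accs, acc)
    sets[[length(sets) + 1L]] <<- set
  }
  record(length(cur), mean_acc(cur), cur)
  while (length(cur) > 2L) {
    cand_acc <- vapply(cur, function(drop) mean_acc(setdiff(cur, drop)), 0)
    best <- max(cand_acc)
    tied <- cur[cand_acc >= best - 1e-15]
    drop <- sort(tied)[length(tied)]  # lexicographically-last channel
    steps[[length(steps) + 1L]] <-
      data.frame(size_before = length(cur), removed = cur,
                 accuracy = unname(cand_acc), chosen = cur == drop)
    cur <- setdiff(cur, drop)
    record(length(cur), best, cur)
  }
  out <- data.frame(size = sizes, mean_accuracy = accs)
  attr(out, "channels") <- sets
  attr(out, "steps") <- do.call(rbind, steps)
  class(out) <- c("greedy_path", "data.frame")
  out
}

#' TDCA accuracy evaluator for electrode search
#'
#' Builds the evaluator used by [greedy_backward()]: leave-one-block-out
#' TDCA accuracy on the channel subset at a fixed window length.
#'
#' @param code_table Code table for the dataset labels.
#' @param window Decoding window in seconds (0.2).
#' @param ... Passed to [fit_tdca()].
#' @return `function(es, channels) -> accuracy`.
#' @export
make_tdca_evaluator <- function(code_table, window = 0.2, ...) {
  args <- list(...)
  function(es, channels) {
    sub <- subset_channels(es, channels)
    cv <- do.call(crossvalidate,
                  c(list(es = sub, code_table = code_table,
                         windows = window, method = "tdca"), args))
    cv$accuracy[1]
  }
}

#' Export a greedy path as JSON and its step log as CSV
#'
#' @param path A `greedy_path`.
#' @param json_file,csv_file Output paths (either may be `NULL` to skip).
#' @export
write_greedy_path <- function(path, json_file = NULL, csv_file = NULL) {
  if (!is.null(json_file)) {
    sets <- attr(path, "channels")
    rec <- lapply(seq_len(nrow(path)), function(i) {
      list(size = path$size[i], channels = sets[[i]],
           mean_accuracy = path$mean_accuracy[i])
    })
    jsonlite::write_json(rec, json_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_file)) {
    utils::write.csv(attr(path, "steps"), csv_file, row.names = FALSE)
  }
  invisible(path)
}
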