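#' Fit the ensemble TRCA baseline decoder
#'
#' Task-related component analysis: for each class, the spatial filter
#' maximizes the covariance reproduced across training trials,
#' `max_w (w' S w) / (w' Q w)` with `S = sum_{i != j} X_i X_j'` and
#' `Q = sum_i X_i X_i'` (trials centered per channel). The per-class
#' filters are concatenated into an ensemble and correlation against the
#' class-mean templates is fused over subbands with the same harmonic-decay
#' weights as TDCA.
#'
#' @inheritParams fit_tdca
#' @return A `trca_model`.
#' @export
fit_trca <- function(train, code_table = NULL, window = NULL, bank = NULL,
                     ridge = 1e-6) {
  if (inherits(train, "epoch_set") && is.null(bank)) {
    bank <- build_filterbank(filterbank_spec(), train$fs)
  }
  subbands <- as_subband_list(train, bank)
  es1 <- subbands[[1]]
  fs <- es1$fs
  np <- if (is.null(window)) n_samples(es1) else round(window * fs)
  if (np > n_samples(es1)) stop("epochs shorter than the window", call. = FALSE)
  classes <- sort(unique(es1$labels))
  cnt <- table(factor(es1$labels, levels = classes))
  if (any(cnt < 2L)) {
    stop("TRCA needs at least 2 trials per class (inter-trial covariance ",
         "is undefined otherwise)", call. = FALSE)
  }
  nc <- n_channels(es1)
  n_sub <- length(subbands)
  W <- vector("list", n_sub)
  templates <- vector("list", n_sub)
  for (m in seq_len(n_sub)) {
    dat <- subbands[[m]]$data
    Wm <- matrix(0, nc, length(classes))
    tmpl <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      trials <- which(es1$labels == classes[ci])
      xs <- lapply(trials, function(i) {
        x <- dat[i, , seq_len(np), drop = FALSE]
        x <- matrix(x, nrow = nc)
        x - rowMeans(x)
      })
      xsum <- Reduce(`+`, xs)
      Q <- Reduce(`+`, lapply(xs, tcrossprod))
      S <- tcrossprod(xsum) - Q
      eps <- ridge * sum(diag(Q)) / nc
      Ck <- tryCatch(chol(Q + eps * diag(nc)), error = function(e) {
        stop("trial covariance is singular despite the ridge", call. = FALSE)
      })
      Mw <- forwardsolve(t(Ck), S)
      Mw <- t(forwardsolve(t(Ck), t(Mw)))
      eg <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
      w <- backsolve(Ck, eg$vectors[, 1])
      Wm[, ci] <- w / sqrt(sum(w^2))
      tmpl[[ci]] <- xsum / length(xs)
    }
    W[[m]] <- Wm
    # projected, standardized templates: vec(X_bar' W_ens) per class
    TM <- vapply(tmpl, function(mn) as.vector(crossprod(mn, Wm)),
                 numeric(np * length(classes)))
    templates[[m]] <- TM
  }
  structure(list(filters = W, templates = templates, classes = classes,
                 fs = fs, np_train = np, n_subbands = n_sub,
                 channels = es1$channels, bank = bank),
            class = "trca_model")
}

#' @export
print.trca_model <- function(x, ...) {
  cat(sprintf("trca_model: %d classes, %d subbands, %d channels, Np=%d @ %g Hz\n",
              length(x$classes), x$n_subbands, length(x$channels),
              x$np_train, x$fs))
  invisible(x)
}

trca_rho <- function(model, test, np_test = NULL) {
  subbands <- as_subband_list(test, model$bank)
  es1 <- subbands[[1]]
  if (!identical(es1$channels, model$channels)) {
    stop("test channels do not match the model", call. = FALSE)
  }
  np_test <- np_test %||% min(n_samples(es1), model$np_train)
  np_test <- min(np_test, model$np_train)
  nt <- n_trials(es1)
  ncls <- length(model$classes)
  fw <- subband_weights(model$n_subbands)
  rho <- matrix(0, nt, ncls)
  for (m in seq_len(model$n_subbands)) {
    dat <- subbands[[m]]$data
    Wm <- model$filters[[m]]
    # crop both templates and test data to the evaluation window
    TMfull <- array(model$templates[[m]], dim = c(model$np_train, ncls, ncls))
    TM <- matrix(TMfull[seq_len(np_test), , ], ncol = ncls)
    TMs <- std_cols(TM)
    for (i in seq_len(nt)) {
      x <- matrix(dat[i, , seq_len(np_test)], nrow = n_channels(es1))
      Z <- as.vector(crossprod(x, Wm))
      Zs <- std_cols(matrix(Z, ncol = 1L))
      r <- as.numeric(crossprod(TMs, Zs))
      rho[i, ] <- rho[i, ] + fw[m] * r^2
    }
  }
  rho
}

#' Classify epochs with a fitted TRCA model
#'
#' @param model A `trca_model`.
#' @param test An [epoch_set()] or pre-filtered subband list.
#' @param window Optional test window in seconds (epochs and templates are
#'   cropped to it).
#' @return Integer vector of predicted target ids with attribute `"rho"`.
#' @export
trca_predict <- function(model, test, window = NULL) {
  np_test <- if (is.null(window)) NULL else round(window * model$fs)
  rho <- trca_rho(model, test, np_test)
  pred <- model$classes[max.col(rho, ties.method = "first")]
  attr(pred, "rho") <- rho
  pred
}

#' @rdname trca_predict
#' @param trial Numeric matrix `[n_channels, n_samples]`.
#' @export
score_trca <- function(model, trial, window = NULL) {
  stopifnot(is.matrix(trial))
  es <- epoch_set(array(trial, dim = c(1L, nrow(trial), ncol(trial))),
                  model$fs, labels = model$classes[1],
                  channels = model$channels)
  np_test <- if (is.null(window)) NULL else round(window * model$fs)
  rho <- trca_rho(model, es, np_test)[1, ]
  list(rho = rho, predicted = model$classes[which.max(rho)])
}
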