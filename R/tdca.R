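#' Delay-embed multichannel EEG
#'
#' Stacks the signal at lags 0..l along the channel axis: row block j holds
#' the data in the time window shifted by j samples. For training data the
#' source must extend l samples past the requested output length; for test
#' data (`test_mode = TRUE`) the unavailable trailing samples are
#' zero-padded.
#'
#' @param X Numeric matrix `[n_channels, n_avail]`.
#' @param l Delay order (non-negative integer).
#' @param np_out Output sample count Np (default `ncol(X)`).
#' @param test_mode Zero-pad samples beyond `ncol(X)` instead of erroring.
#' @return Matrix `[(l + 1) * n_channels, np_out]`.
#' @export
delay_embed <- function(X, l, np_out = ncol(X), test_mode = FALSE) {
  if (length(l) != 1L || is.na(l) || l < 0 || l != as.integer(l)) {
    stop("delay order l must be a non-negative integer", call. = FALSE)
  }
  l <- as.integer(l)
  nc <- nrow(X)
  avail <- ncol(X)
  if (!test_mode && np_out + l > avail) {
    stop("training embedding needs ", np_out + l,
         " samples but only ", avail, " are available; ",
         "use test_mode = TRUE to zero-pad", call. = FALSE)
  }
  out <- matrix(0, nrow = (l + 1L) * nc, ncol = np_out)
  for (j in 0:l) {
    t_max <- min(np_out, avail - j)
    if (t_max >= 1L) {
      out[(j * nc + 1L):((j + 1L) * nc), seq_len(t_max)] <-
        X[, (1L + j):(t_max + j), drop = FALSE]
    }
  }
  out
}

#' Projection onto the sine-cosine reference subspace of a frequency
#'
#' `P_f = Y' (Y Y')^-1 Y` where the rows of Y are `sin(2 pi h f t)` and
#' `cos(2 pi h f t)` for harmonics h = 1..Nh at the sampling grid
#' `t = (0:(Np-1))/fs`. Applied on the right (`X %*% P_f`), it projects each
#' row of a time series onto the stimulus-locked subspace. The operator is
#' symmetric and idempotent.
#'
#' @param f Stimulus frequency in Hz.
#' @param n_harmonics Number of harmonics Nh.
#' @param fs Sampling rate in Hz; `n_harmonics * f` must stay below `fs/2`.
#' @param np Number of samples Np.
#' @return Matrix `[np, np]`.
#' @export
reference_projection <- function(f, n_harmonics, fs, np) {
  if (n_harmonics * f >= fs / 2) {
    stop("reference harmonics reach the Nyquist rate", call. = FALSE)
  }
  t <- (seq_len(np) - 1) / fs
  Y <- do.call(rbind, lapply(seq_len(n_harmonics), function(h) {
    rbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t))
  }))
  G <- tcrossprod(Y)
  sol <- tryCatch(solve(G, Y), error = function(e) NULL)
  if (is.null(sol)) {
    # rank-deficient reference set: P is the projector onto the row space
    warning("rank-deficient reference set (Np too short); using pseudo-inverse")
    s <- svd(Y)
    pos <- s$d > max(s$d) * 1e-10
    V <- s$v[, pos, drop = FALSE]
    return(tcrossprod(V))
  }
  crossprod(Y, sol)
}

# orthonormal basis of the sine-cosine reference row space: P_f = Q'Q,
# applied in factored form for speed (2*Nh x np instead of np x np)
ref_basis <- function(f, n_harmonics, fs, np) {
  t <- (seq_len(np) - 1) / fs
  Y <- do.call(rbind, lapply(seq_len(n_harmonics), function(h) {
    rbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t))
  }))
  qr_y <- qr(t(Y))
  t(qr.Q(qr_y)[, seq_len(qr_y$rank), drop = FALSE])
}

# subband fusion weights f_m = m^-1.25 + 0.25
subband_weights <- function(n_subbands) {
  m <- seq_len(n_subbands)
  m^(-1.25) + 0.25
}

# standardize columns to zero mean / unit norm for fast Pearson correlation
std_cols <- function(M) {
  M <- sweep(M, 2L, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  zero <- nrm < 1e-300
  nrm[zero] <- 1
  M <- sweep(M, 2L, nrm, "/")
  attr(M, "zero_var") <- zero
  M
}

as_subband_list <- function(x, bank) {
  if (inherits(x, "epoch_set")) {
    if (is.null(bank)) stop("a filter bank is required to filter raw epochs",
                            call. = FALSE)
    apply_filterbank(x, bank)
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "epoch_set")))
    x
  }
}

#' Fit the filter-bank TDCA decoder
#'
#' Task-discriminant component analysis: every training trial is
#' delay-embedded (lags 0..l), augmented along the time axis with its
#' projection onto the class's sine-cosine reference subspace, and the
#' common spatiotemporal filter of each subband is the solution of the
#' Fisher eigenproblem `max_W tr(W' Hb Hb' W) / tr(W' Hw Hw' W)` where Hb
#' stacks the class means around the grand mean and Hw the trials around
#' their class means. Class templates are the augmented class means, stored
#' in projected form.
#'
#' @param train An [epoch_set()] (filtered internally with `bank`) or a list
#'   of pre-filtered per-subband epoch sets. Epochs must carry at least
#'   `round(window * fs) + l` samples.
#' @param code_table Code table giving each target id its frequency.
#' @param window Decoding window length in seconds (default: longest
#'   window the epochs support, `n_samples/fs - l/fs`).
#' @param bank A [build_filterbank()]; default builds the standard 5-subband
#'   bank at the data rate.
#' @param l Delay order (4).
#' @param n_components Number of retained filter columns D (8).
#' @param n_harmonics Harmonics Nh of the reference subspace (5).
#' @param ridge Relative ridge added to the within-class scatter (1e-6).
#' @return A `tdca_model`.
#' @export
fit_tdca <- function(train, code_table, window = NULL, bank = NULL,
                     l = 4L, n_components = 8L, n_harmonics = 5L,
                     ridge = 1e-6) {
  if (inherits(train, "epoch_set") && is.null(bank)) {
    bank <- build_filterbank(filterbank_spec(), train$fs)
  }
  subbands <- as_subband_list(train, bank)
  es1 <- subbands[[1]]
  fs <- es1$fs
  np <- if (is.null(window)) n_samples(es1) - l else round(window * fs)
  if (np + l > n_samples(es1)) {
    stop("epochs too short: need ", np + l, " samples (window + delay order), have ",
         n_samples(es1), call. = FALSE)
  }
  classes <- sort(unique(es1$labels))
  row <- match(classes, code_table$target_id)
  if (anyNA(row)) stop("labels missing from the code table", call. = FALSE)
  freq <- code_table$frequency_hz[row]
  cnt <- table(factor(es1$labels, levels = classes))
  if (any(cnt < 2L)) stop("need at least 2 trials per class", call. = FALSE)

  ufreq <- sort(unique(freq))
  Q <- lapply(ufreq, ref_basis, n_harmonics = n_harmonics, fs = fs, np = np)
  names(Q) <- sprintf("%.9g", ufreq)
  fidx <- match(sprintf("%.9g", freq), names(Q))

  nc <- n_channels(es1)
  rows <- (l + 1L) * nc
  D <- min(n_components, rows)
  n_sub <- length(subbands)
  W <- vector("list", n_sub)
  templates <- vector("list", n_sub)

  for (m in seq_len(n_sub)) {
    dat <- subbands[[m]]$data
    Sw <- matrix(0, rows, rows)
    means <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      trials <- which(es1$labels == classes[ci])
      Qn <- Q[[fidx[ci]]]
      xa <- lapply(trials, function(i) {
        emb <- delay_embed(dat[i, , ], l, np_out = np)
        cbind(emb, tcrossprod(emb, Qn) %*% Qn)
      })
      xbar <- Reduce(`+`, xa) / length(xa)
      centered <- do.call(cbind, lapply(xa, function(a) a - xbar))
      Sw <- Sw + tcrossprod(centered)
      means[[ci]] <- xbar
    }
    gm <- Reduce(`+`, means) / length(means)
    Hb <- do.call(cbind, lapply(means, function(mn) mn - gm))
    Sb <- tcrossprod(Hb)
    eps <- ridge * sum(diag(Sw)) / rows
    if (eps <= 0) {
      # exactly reproducible (noise-free) trials: fall back to an absolute
      # floor so the eigenproblem reduces to the between-class scatter
      eps <- 1e-10 * (sum(diag(Sb)) / rows + 1e-300)
    }
    Ck <- tryCatch(chol(Sw + eps * diag(rows)), error = function(e) NULL)
    if (is.null(Ck)) {
      stop("within-class scatter is singular despite the ridge; ",
           "increase trials or the ridge", call. = FALSE)
    }
    Mw <- forwardsolve(t(Ck), Sb)
    Mw <- t(forwardsolve(t(Ck), t(Mw)))
    eg <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
    Wm <- backsolve(Ck, eg$vectors[, seq_len(D), drop = FALSE])
    Wm <- sweep(Wm, 2L, sqrt(colSums(Wm^2)), "/")
    W[[m]] <- Wm
    # projected templates, standardized for fast correlation
    TM <- vapply(means, function(mn) as.vector(crossprod(mn, Wm)),
                 numeric(2 * np * D))
    templates[[m]] <- std_cols(TM)
  }

  structure(list(filters = W, templates = templates,
                 classes = classes, freq = freq, fidx = fidx,
                 ref_bases = Q, fs = fs, np_train = np, l = l,
                 n_components = D, n_harmonics = n_harmonics,
                 n_subbands = n_sub, channels = es1$channels,
                 bank = bank),
            class = "tdca_model")
}

#' @export
print.tdca_model <- function(x, ...) {
  cat(sprintf("tdca_model: %d classes, %d subbands, %d channels, l=%d, D=%d, Np=%d @ %g Hz\n",
              length(x$classes), x$n_subbands, length(x$channels),
              x$l, x$n_components, x$np_train, x$fs))
  invisible(x)
}

# fused feature matrix rho [n_trials x n_classes] for an epoch set, scored
# at `np_test` samples (<= np_train; shorter windows are zero-padded through
# the test-mode embedding)
tdca_rho <- function(model, test, np_test = NULL, warn_zero_var = TRUE) {
  subbands <- as_subband_list(test, model$bank)
  es1 <- subbands[[1]]
  if (!identical(es1$channels, model$channels)) {
    stop("test channels do not match the model", call. = FALSE)
  }
  np_test <- np_test %||% min(n_samples(es1), model$np_train)
  if (np_test > model$np_train) {
    stop("test window exceeds the trained window", call. = FALSE)
  }
  nt <- n_trials(es1)
  ncls <- length(model$classes)
  np <- model$np_train
  D <- ncol(model$filters[[1]])
  L <- 2 * np * D
  # row indices of the lag-embedded (idx_z) and reference-projected (idx_p)
  # halves inside the flattened augmented feature vec(rbind(Z, QZ))
  idx_z <- as.vector(outer(seq_len(np), (seq_len(D) - 1) * 2 * np, `+`))
  idx_p <- idx_z + np
  fw <- subband_weights(model$n_subbands)
  rho <- matrix(0, nt, ncls)
  saw_zero <- FALSE
  groups <- split(seq_len(ncls), model$fidx)
  for (m in seq_len(model$n_subbands)) {
    dat <- subbands[[m]]$data
    Wm <- model$filters[[m]]
    TM <- model$templates[[m]]
    t_zero <- attr(TM, "zero_var")
    Ttop <- TM[idx_z, , drop = FALSE]
    Tbot <- TM[idx_p, , drop = FALSE]
    navail <- min(np_test + model$l, dim(dat)[3])
    Zall <- matrix(0, np * D, nt)
    for (i in seq_len(nt)) {
      emb <- delay_embed(matrix(dat[i, , seq_len(navail)], nrow = dim(dat)[2]),
                         model$l, np_out = np, test_mode = TRUE)
      Zall[, i] <- crossprod(emb, Wm)
    }
    s1 <- colSums(Zall)
    q1 <- colSums(Zall^2)
    dot_top <- crossprod(Zall, Ttop)          # nt x ncls
    Zflat <- matrix(Zall, nrow = np)          # np x (D * nt)
    for (g in seq_along(groups)) {
      cls <- groups[[g]]
      Qf <- model$ref_bases[[as.integer(names(groups)[g])]]
      PZflat <- crossprod(Qf, Qf %*% Zflat)
      per_col <- matrix(colSums(PZflat), nrow = D)   # D x nt sums
      s2 <- colSums(per_col)
      q2 <- colSums(matrix(colSums(PZflat^2), nrow = D))
      dot_bot <- crossprod(matrix(PZflat, nrow = np * D),
                           Tbot[, cls, drop = FALSE])  # nt x |cls|
      bbar <- (s1 + s2) / L
      denom2 <- q1 + q2 - L * bbar^2
      bad <- denom2 <= 1e-300
      if (any(bad)) saw_zero <- TRUE
      inv <- ifelse(bad, 0, 1 / sqrt(pmax(denom2, 1e-300)))
      r <- (dot_top[, cls, drop = FALSE] + dot_bot) * inv
      r[, t_zero[cls]] <- 0
      rho[, cls] <- rho[, cls] + fw[m] * r^2
    }
  }
  if (saw_zero && warn_zero_var) {
    warning("zero-variance projection in at least one trial; its correlations were set to 0")
  }
  rho
}

#' Classify epochs with a fitted TDCA model
#'
#' Computes the fused feature `rho_n = sum_m f_m r_nm^2` for every class and
#' returns the argmax labels (ties broken toward the lowest target id).
#'
#' @param model A `tdca_model`.
#' @param test An [epoch_set()] or pre-filtered subband list.
#' @param window Optional test window in seconds (must not exceed the
#'   trained window; shorter windows are zero-padded via the test-mode
#'   delay embedding).
#' @return Integer vector of predicted target ids, with the fused feature
#'   matrix in attribute `"rho"`.
#' @export
tdca_predict <- function(model, test, window = NULL) {
  np_test <- if (is.null(window)) NULL else round(window * model$fs)
  rho <- tdca_rho(model, test, np_test)
  pred <- model$classes[max.col(rho, ties.method = "first")]
  attr(pred, "rho") <- rho
  pred
}

#' Score a single trial against a TDCA model
#'
#' @param model A `tdca_model`.
#' @param trial Numeric matrix `[n_channels, n_samples]` (raw; the model's
#'   filter bank is applied).
#' @param window Optional test window in seconds.
#' @return A `ScoreVector`-style list: `rho` (per class), `r` (class x
#'   subband correlations, via `sqrt(rho parts)` is not retained; `r` holds
#'   the per-subband correlations), `predicted`.
#' @export
score_tdca <- function(model, trial, window = NULL) {
  stopifnot(is.matrix(trial))
  es <- epoch_set(array(trial, dim = c(1L, nrow(trial), ncol(trial))),
                  model$fs, labels = model$classes[1],
                  channels = model$channels)
  np_test <- if (is.null(window)) NULL else round(window * model$fs)
  subbands <- as_subband_list(es, model$bank)
  ncls <- length(model$classes)
  fw <- subband_weights(model$n_subbands)
  r <- matrix(0, ncls, model$n_subbands)
  np_test <- np_test %||% min(ncol(trial), model$np_train)
  for (m in seq_len(model$n_subbands)) {
    dat <- subbands[[m]]$data
    Wm <- model$filters[[m]]
    TM <- model$templates[[m]]
    navail <- min(np_test + model$l, dim(dat)[3])
    emb <- delay_embed(matrix(dat[1, , seq_len(navail)], nrow = dim(dat)[2]), model$l,
                       np_out = model$np_train, test_mode = TRUE)
    Z <- crossprod(emb, Wm)
    B <- vapply(model$ref_bases, function(Qf) {
      as.vector(rbind(Z, crossprod(Qf, Qf %*% Z)))
    }, numeric(2 * model$np_train * ncol(Wm)))
    Bs <- std_cols(B)
    r[, m] <- colSums(Bs[, model$fidx, drop = FALSE] * TM)
  }
  rho <- as.numeric(r^2 %*% subband_weights(model$n_subbands))
  list(rho = rho, r = r,
       predicted = model$classes[which.max(rho)])
}

#' Persist / load a TDCA model
#'
#' RDS container with a JSON sidecar mirroring the scalar attributes
#' (l, D, Nh, fs, Np, classes, channels).
#'
#' @param model A `tdca_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  saveRDS(unclass(model), path, version = 2L)
  jsonlite::write_json(list(l = model$l, n_components = model$n_components,
                            n_harmonics = model$n_harmonics, fs = model$fs,
                            np_train = model$np_train,
                            n_subbands = model$n_subbands,
                            classes = model$classes,
                            channels = model$channels),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  structure(readRDS(path), class = "tdca_model")
}
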