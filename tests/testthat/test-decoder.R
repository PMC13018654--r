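test_that("delay embedding matches a brute-force index oracle", {
  # oracle: out[j*nc + c, t] = X[c, t + j] or 0 when t + j exceeds the data
  embed_oracle <- function(X, l, np_out, test_mode) {
    nc <- nrow(X)
    out <- matrix(0, (l + 1) * nc, np_out)
    for (j in 0:l) for (c in seq_len(nc)) for (t in seq_len(np_out)) {
      if (t + j <= ncol(X)) out[j * nc + c, t] <- X[c, t + j]
    }
    out
  }
  set.seed(42)
  for (rep in 1:20) {
    nc <- sample(1:4, 1); ns <- sample(5:12, 1); l <- sample(0:3, 1)
    X <- matrix(rnorm(nc * ns), nc, ns)
    np <- ns - l
    expect_identical(delay_embed(X, l, np_out = np),
                     embed_oracle(X, l, np, FALSE))
    expect_identical(delay_embed(X, l, np_out = ns, test_mode = TRUE),
                     embed_oracle(X, l, ns, TRUE))
  }
  X <- matrix(rnorm(10), 2, 5)
  expect_identical(delay_embed(X, 0), X)
  expect_equal(dim(delay_embed(X, 2, test_mode = TRUE)), c(6L, 5L))
  # test-mode zero padding: last column of the lag-1 block is zero
  e <- delay_embed(X, 1, test_mode = TRUE)
  expect_true(all(e[3:4, 5] == 0))
  expect_error(delay_embed(X, -1), "non-negative")
  expect_error(delay_embed(X, 3, np_out = 5), "test_mode")
})

test_that("reference projections are symmetric idempotent projectors", {
  P <- reference_projection(11, n_harmonics = 5, fs = 250, np = 100)
  expect_lt(max(abs(P - t(P))), 1e-8)
  expect_lt(max(abs(P %*% P - P)), 1e-8)
  expect_equal(sum(diag(P)), 10, tolerance = 1e-8)  # rank = 2*Nh
  # a pure in-subspace vector is returned unchanged
  t_ <- (0:99) / 250
  v <- sin(2 * pi * 11 * t_)
  expect_lt(max(abs(as.numeric(v %*% P) - v)) / max(abs(v)), 1e-6)
  expect_error(reference_projection(30, 5, 250, 50), "Nyquist")
  expect_warning(reference_projection(11, 5, 250, 6), "pseudo-inverse")
})

test_that("subband fusion weights follow m^-1.25 + 0.25", {
  w <- hdssvep:::subband_weights(5)
  expect_equal(w[1], 1.25)
  expect_equal(w[5], 5^(-1.25) + 0.25, tolerance = 1e-12)
  expect_equal(w[5], 0.383748, tolerance = 1e-6)
})

test_that("TDCA is perfect on noiseless data and dimensioned as expected", {
  codes <- tiny_codes()
  es <- clean_dataset(n_blocks = 2, codes = codes)
  fit <- fit_tdca(es, codes, window = 0.5)
  expect_equal(dim(fit$filters[[1]]), c(45L, 8L))  # (l+1)*Nc x D
  for (w in c(0.1, 0.3, 0.5)) {
    expect_equal(mean(tdca_predict(fit, es, window = w) == es$labels), 1)
  }
  # scoring a training trial at the full window: true-class r ~ 1
  sc <- score_tdca(fit, matrix(es$data[1, , ], nrow = 9))
  ci <- match(es$labels[1], fit$classes)
  expect_gt(min(sc$r[ci, ]), 0.999)
  expect_equal(sc$predicted, es$labels[1])
  # positive scaling leaves the prediction unchanged
  sc2 <- score_tdca(fit, 7.3 * matrix(es$data[1, , ], nrow = 9))
  expect_equal(sc2$predicted, sc$predicted)
  expect_equal(sc2$rho, sc$rho, tolerance = 1e-9)
})

test_that("40-class filters have (l+1)*Nc rows", {
  codes <- build_code_table("center")
  cfg <- tiny_cfg(codes = codes, noise_scale = 0)
  es <- synth_dataset(2, codes, 0.22, cfg)
  fit <- fit_tdca(es, codes, window = 0.2)
  expect_equal(nrow(fit$filters[[1]]), (4 + 1) * 9)
  expect_equal(length(fit$classes), 40L)
})

test_that("duplicating training trials leaves the filter subspace unchanged", {
  codes <- tiny_codes()
  es <- noisy_dataset(n_blocks = 2, codes = codes, seed = 5)
  dup <- es
  dup$data <- es$data[rep(seq_len(n_trials(es)), 2), , ]
  dup$labels <- rep(es$labels, 2)
  dup$blocks <- c(es$blocks, es$blocks + 2L)
  f1 <- fit_tdca(es, codes, window = 0.3)
  f2 <- fit_tdca(dup, codes, window = 0.3)
  for (m in 1:5) {
    q1 <- qr.Q(qr(f1$filters[[m]]))
    q2 <- qr.Q(qr(f2$filters[[m]]))
    # largest principal angle between the column spaces
    sv <- svd(crossprod(q1, q2))$d
    expect_lt(max(abs(sv - 1)), 1e-6)
  }
})

test_that("predictions are invariant to training label permutation", {
  codes <- tiny_codes()
  es <- noisy_dataset(n_blocks = 3, codes = codes, seed = 9)
  tr <- select_trials(es, es$blocks < 3)
  te <- select_trials(es, es$blocks == 3)
  set.seed(1)
  perm <- sample(n_trials(tr))
  tr2 <- tr
  tr2$data <- tr$data[perm, , ]
  tr2$labels <- tr$labels[perm]
  tr2$blocks <- tr$blocks[perm]
  f1 <- fit_tdca(tr, codes, window = 0.3)
  f2 <- fit_tdca(tr2, codes, window = 0.3)
  expect_equal(as.integer(tdca_predict(f1, te, window = 0.3)),
               as.integer(tdca_predict(f2, te, window = 0.3)))
})

test_that("TRCA is perfect on noiseless data and guards its preconditions", {
  codes <- tiny_codes()
  es <- clean_dataset(n_blocks = 2, codes = codes)
  fit <- fit_trca(es, codes, window = 0.5)
  for (w in c(0.1, 0.3, 0.5)) {
    expect_equal(mean(trca_predict(fit, es, window = w) == es$labels), 1)
  }
  sc <- score_trca(fit, matrix(es$data[1, , ], nrow = 9))
  expect_equal(sc$predicted, es$labels[1])
  one <- select_trials(es, es$blocks == 1)
  expect_error(fit_trca(one, codes, window = 0.3), "2 trials per class")
})

test_that("TDCA is at least as accurate as the TRCA baseline on short windows", {
  codes <- tiny_codes()
  acc <- vapply(1:10, function(seed) {
    es <- noisy_dataset(n_blocks = 5, codes = codes, seed = seed)
    tr <- select_trials(es, es$blocks < 5)
    te <- select_trials(es, es$blocks == 5)
    truth <- te$labels
    ft <- fit_tdca(tr, codes, window = 0.2)
    fr <- fit_trca(tr, codes, window = 0.2)
    c(mean(tdca_predict(ft, te, window = 0.2) == truth),
      mean(trca_predict(fr, te, window = 0.2) == truth))
  }, numeric(2))
  expect_gte(mean(acc[1, ]), mean(acc[2, ]) - 0.02)
})

test_that("zero-variance trials score with a warning, not an error", {
  codes <- tiny_codes()
  es <- clean_dataset(n_blocks = 2, codes = codes)
  fit <- fit_tdca(es, codes, window = 0.3)
  expect_warning(score_zero <- tdca_predict(fit, epoch_set(
    array(0, dim = c(1, 9, 125)), 250, labels = codes$target_id[1],
    channels = es$channels)), "zero-variance")
  expect_length(score_zero, 1L)
})

test_that("models persist to disk with a JSON sidecar", {
  codes <- tiny_codes()
  es <- clean_dataset(n_blocks = 2, codes = codes)
  fit <- fit_tdca(es, codes, window = 0.3)
  f <- tempfile(fileext = ".rds")
  write_model(fit, f)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$l, 4L)
  expect_equal(side$n_subbands, 5L)
  back <- read_model(f)
  expect_equal(as.integer(tdca_predict(back, es, window = 0.3)),
               as.integer(tdca_predict(fit, es, window = 0.3)))
})
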