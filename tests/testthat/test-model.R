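ns <- asNamespace("acuityssm")

test_that("sinusoidal positional encoding matches its closed form", {
  D <- 8
  P <- positional_encoding(5, D)
  for (p in 0:4) {
    for (i in 0:(D / 2 - 1)) {
      expect_equal(P[p + 1, 2 * i + 1], sin(p / 10000^(2 * i / D)))
      expect_equal(P[p + 1, 2 * i + 2], cos(p / 10000^(2 * i / D)))
    }
  }
})

test_that("embedding handles padding degeneracy and canonical ordering", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 6)
  N <- 3; T_len <- 5
  pad_batch <- list(times = matrix(0, N, T_len), values = matrix(0, N, T_len),
                    codes = matrix(0L, N, T_len), mask = matrix(0L, N, T_len))
  emb <- embed_triplets(params, pad_batch, cfg)
  # all-padding input: conv-of-zeros (bias only) + positional encoding,
  # identical across samples
  P <- positional_encoding(T_len, cfg$D)
  expected <- P[rep(seq_len(T_len), each = N), ] +
    rep(params$b_time + params$b_val, each = N * T_len)
  expect_equal(emb$U, expected, ignore_attr = TRUE)
  U1 <- matrix(emb$U[seq(1, N * T_len, by = N), ], T_len, cfg$D)
  U2 <- matrix(emb$U[seq(2, N * T_len, by = N), ], T_len, cfg$D)
  expect_equal(U1, U2)
  # the padding code row of the lookup is fixed at zero
  expect_true(all(params$E_code[1, ] == 0))
  # out-of-vocabulary code errors
  bad <- random_batch(cfg, N = 2, T_len = 4, n_codes = 6)
  bad$codes[1, 1] <- 99L
  expect_error(embed_triplets(params, bad, cfg), "code")
})

test_that("simultaneous events produce identical tensors after canonical sort", {
  # permuting tied events before encoding leaves the embedding unchanged
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 6)
  tied <- tibble::tibble(time_scaled = c(0.1, 0.1, 0.2),
                         value_scaled = c(0.3, 0.6, 0.9),
                         code = c(3L, 1L, 2L))
  t1 <- encode_observation(tied, L = 6)
  t2 <- encode_observation(tied[c(2, 3, 1), ], L = 6)
  b1 <- list(times = matrix(t1$times, 1), values = matrix(t1$values, 1),
             codes = matrix(t1$codes, 1), mask = matrix(t1$mask, 1))
  b2 <- list(times = matrix(t2$times, 1), values = matrix(t2$values, 1),
             codes = matrix(t2$codes, 1), mask = matrix(t2$mask, 1))
  expect_identical(embed_triplets(params, b1, cfg)$U,
                   embed_triplets(params, b2, cfg)$U)
})

test_that("compiled scan equals the sequential pure-R reference", {
  set.seed(41)
  for (rep in 1:5) {
    d <- sample(3:8, 1); S <- sample(2:5, 1)
    N <- sample(2:4, 1); T_len <- sample(3:9, 1)
    tok <- N * T_len
    x <- matrix(rnorm(tok * d), tok, d)
    dt <- matrix(abs(rnorm(tok * d, 0.05, 0.03)) + 1e-4, tok, d)
    B <- matrix(rnorm(tok * S), tok, S)
    C <- matrix(rnorm(tok * S), tok, S)
    A <- -matrix(runif(d * S, 0.2, 4), d, S)
    yc <- ns$ssm_scan_forward(x, dt, B, C, A, N, T_len)$y
    yr <- ns$.ssm_scan_reference(x, dt, B, C, A, N, T_len)
    expect_lt(max(abs(yc - yr)), 1e-5)
  }
})

test_that("the scan is causal and reduces to LTI convolution when frozen", {
  set.seed(42)
  d <- 4; S <- 3; N <- 2; T_len <- 8; tok <- N * T_len
  x <- matrix(rnorm(tok * d), tok, d)
  dt <- matrix(0.07, tok, d)                       # input-independent step
  B <- matrix(rep(rnorm(S), each = tok), tok, S)   # frozen B, C
  C <- matrix(rep(rnorm(S), each = tok), tok, S)
  A <- -matrix(runif(d * S, 0.2, 3), d, S)
  y <- ns$ssm_scan_forward(x, dt, B, C, A, N, T_len)$y
  # impulse response of the implied LTI system:
  # k_j(tau) = sum_s C_s * abar_{js}^(tau+1) * dt * B_s
  for (n in 1:N) {
    for (j in 1:d) {
      ab <- 1 / (1 - dt[1, j] * A[j, ])
      conv <- numeric(T_len)
      for (t in 1:T_len) {
        for (tau in 0:(t - 1)) {
          k <- sum(C[1, ] * ab^(tau + 1) * dt[1, j] * B[1, ])
          conv[t] <- conv[t] + k * x[(t - tau - 1) * N + n, j]
        }
      }
      got <- y[(seq_len(T_len) - 1) * N + n, j]
      expect_lt(max(abs(got - conv)), 1e-5)
    }
  }
  # causality: perturbing the final position leaves earlier outputs unchanged
  x2 <- x
  x2[(T_len - 1) * N + 1, ] <- x2[(T_len - 1) * N + 1, ] + 10
  y2 <- ns$ssm_scan_forward(x2, dt, B, C, A, N, T_len)$y
  early <- seq_len((T_len - 1) * N)
  expect_identical(y[early, ], y2[early, ])
})

test_that("the full trunk up to pooling is causal in masked-future inputs", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 6)
  b <- random_batch(cfg, N = 3, T_len = 7, pad_tail = FALSE, seed = 9)
  emb1 <- embed_triplets(params, b, cfg)
  Y1 <- ns$.trunk_forward(params, emb1$U, b$static, b$mask, cfg, 3, 7)$cache$Y
  b2 <- b
  b2$times[, 7] <- 0.9; b2$values[, 7] <- 0.99; b2$codes[, 7] <- 5L
  emb2 <- embed_triplets(params, b2, cfg)
  Y2 <- ns$.trunk_forward(params, emb2$U, b2$static, b2$mask, cfg, 3, 7)$cache$Y
  early_tokens <- seq_len(3 * 6)   # positions 1..6 of all samples
  expect_equal(Y1[early_tokens, ], Y2[early_tokens, ], tolerance = 1e-12)
})

test_that("top-k pooling selects by norm, respects masks and degenerate k", {
  set.seed(43)
  Y <- matrix(rnorm(12 * 4), 12, 4)   # N = 3, T = 4 token layout
  mask <- matrix(1L, 3, 4)
  # brute force oracle
  pool <- ns$.topk_pool(Y, mask, 3, 4, k = 2)
  for (n in 1:3) {
    toks <- n + (0:3) * 3
    nr <- sqrt(rowSums(Y[toks, ]^2))
    top <- toks[order(nr, decreasing = TRUE)[1:2]]
    expect_equal(pool$pooled[n, ], colMeans(Y[top, ]))
  }
  # k = number of real positions equals the masked mean
  pool_all <- ns$.topk_pool(Y, mask, 3, 4, k = 4)
  for (n in 1:3) {
    expect_equal(pool_all$pooled[n, ], colMeans(Y[n + (0:3) * 3, ]))
  }
  # one dominant position with k = 1 returns that vector
  Y2 <- matrix(0, 12, 4); Y2[5, ] <- c(100, 1, 2, 3)
  p1 <- ns$.topk_pool(Y2, mask, 3, 4, k = 1)
  expect_equal(p1$pooled[2, ], c(100, 1, 2, 3))
  # padded positions are never selected
  mask2 <- mask; mask2[1, 3:4] <- 0L
  p2 <- ns$.topk_pool(Y, mask2, 3, 4, k = 4)
  expect_equal(p2$pooled[1, ], colMeans(Y[c(1, 4), ]))
  # fully masked input pools to zero with a warning
  mask3 <- mask; mask3[2, ] <- 0L
  expect_warning(p3 <- ns$.topk_pool(Y, mask3, 3, 4, k = 2))
  expect_equal(p3$pooled[2, ], rep(0, 4))
})

test_that("forward pass is deterministic, in (0,1), and uses the statics", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 6)
  b <- random_batch(cfg, N = 4, T_len = 8, seed = 10)
  f1 <- forward_pass(params, b, cfg)
  f2 <- forward_pass(params, b, cfg)
  expect_identical(f1$probs, f2$probs)
  expect_true(all(f1$probs > 0 & f1$probs < 1))
  b2 <- b; b2$static <- b2$static * 0
  f3 <- forward_pass(params, b2, cfg)
  expect_false(isTRUE(all.equal(f1$probs, f3$probs)))
  b3 <- b; b3$static <- b3$static[, 1:2]
  expect_error(forward_pass(params, b3, cfg), "static")
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 4)
  set.seed(11)
  b <- random_batch(cfg, N = 3, T_len = 6, n_codes = 4, seed = 11)
  labels <- matrix(rbinom(27, 1, 0.5), 3, 9)
  labels[1, 6] <- NA
  head_w <- stats::setNames(runif(9, 0.5, 3), acuityssm:::HEAD_NAMES)
  loss_fn <- function(p) {
    emb <- embed_triplets(p, b, cfg)
    tf <- ns$.trunk_forward(p, emb$U, b$static, b$mask, cfg, 3, 6)
    ns$.loss_and_dlogits(tf$probs, tf$logits, labels, head_w)$loss
  }
  emb <- embed_triplets(params, b, cfg)
  tf <- ns$.trunk_forward(params, emb$U, b$static, b$mask, cfg, 3, 6)
  ld <- ns$.loss_and_dlogits(tf$probs, tf$logits, labels, head_w)
  tb <- ns$.trunk_backward(params, tf$cache, ld$dlogits, cfg)
  grads <- c(tb$grads, ns$.embed_backward(params, emb$cache, tb$dU0))
  eps <- 1e-5
  set.seed(12)
  for (nm in names(grads)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      if (nm == "E_code" && (i - 1) %% nrow(params$E_code) == 0) next
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      fd <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_lt(abs(fd - grads[[nm]][i]),
                1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("gradient flows to every parameter group", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, n_codes = 4)
  b <- random_batch(cfg, N = 4, T_len = 6, n_codes = 4, seed = 13)
  labels <- matrix(rbinom(36, 1, 0.4), 4, 9)
  head_w <- stats::setNames(rep(1, 9), acuityssm:::HEAD_NAMES)
  emb <- embed_triplets(params, b, cfg)
  tf <- ns$.trunk_forward(params, emb$U, b$static, b$mask, cfg, 4, 6)
  ld <- ns$.loss_and_dlogits(tf$probs, tf$logits, labels, head_w)
  tb <- ns$.trunk_backward(params, tf$cache, ld$dlogits, cfg)
  grads <- c(tb$grads, ns$.embed_backward(params, emb$cache, tb$dU0))
  for (nm in names(params)) {
    g <- grads[[nm]]
    expect_false(is.null(g), info = nm)
    expect_true(all(is.finite(g)), info = nm)
    if (!nm %in% c("E_code")) {
      expect_gt(max(abs(g)), 0, label = paste("grad", nm))
    }
  }
})

test_that("class weights are N_neg/N_pos, capped, frozen when degenerate", {
  labs <- cbind(matrix(rep(c(0, 1), each = 6), 12, 8), rep(0, 12))
  colnames(labs) <- acuityssm:::LABEL_COLS
  expect_warning(w <- class_weights(labs), "frozen")
  expect_equal(unname(w[1]), 1)     # balanced head
  expect_equal(unname(w[9]), 0)     # no positives: frozen
  labs2 <- matrix(c(rep(1, 2), rep(0, 10)), 12, 9)
  w2 <- class_weights(labs2, cap = 3)
  expect_equal(unname(w2[1]), 3)    # capped below 10/2
})

test_that("training is reproducible and learns a strong planted signal", {
  coh <- simulate_cohort(synth_params(60, seed = 31, signal_strength = 3))
  win <- label_windows(coh)
  v <- build_vocabulary(coh$events, coh$static)
  ev <- scale_events(filter_outliers(coh$events, v), v)
  ds <- encode_windows(ev, win, v, coh$static, L = 64)
  sp <- split_by_stay(ds, 0.25, seed = 2)
  cfg <- model_config(L = 64, D = 16, state_dim = 4, k = 4, mlp_hidden = 32,
                      dt_rank = 4, seed = 3, epochs = 2, batch_size = 64)
  m1 <- suppressWarnings(train_model(sp$train, sp$val, cfg))
  m2 <- suppressWarnings(train_model(sp$train, sp$val, cfg))
  # bit-for-bit reproducibility under a fixed seed
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  p1 <- predict(m1, sp$val)
  expect_identical(p1, predict(m2, sp$val))
  expect_true(all(vapply(p1[, -(1:2)], function(x) all(x > 0 & x < 1),
                         logical(1))))
  # split is by stay, never by window
  expect_length(intersect(unique(sp$train$windows$stay_id),
                          unique(sp$val$windows$stay_id)), 0)
})

test_that("Youden threshold maximizes J with lowest-threshold tie-break", {
  # worked example: probs/labels with exhaustive-search verification
  p <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  yt <- youden_threshold(p, y)
  expect_equal(yt$threshold, 0.35)
  expect_equal(yt$J, 0.5)
  # perfectly separated: J = 1 at the lowest positive score
  ys <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(ys$J, 1)
  expect_equal(ys$threshold, 0.8)
  expect_error(youden_threshold(c(0.2, 0.3), c(1, 1)), "degenerate")
  # exhaustive-search oracle on random data
  set.seed(44)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    p <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    yt <- youden_threshold(p, y)
    cand <- sort(unique(p))
    J <- vapply(cand, function(cc) {
      mean(p[y == 1] >= cc) + mean(p[y == 0] < cc) - 1
    }, numeric(1))
    expect_equal(yt$J, max(J))
    expect_equal(yt$threshold, cand[which(J >= max(J) - 1e-15)[1]])
  }
  # null scores give J near 0
  set.seed(45)
  p <- runif(10000); y <- rbinom(10000, 1, 0.5)
  expect_lt(youden_threshold(p, y)$J, 0.06)
})

test_that("default configuration lands near the 1M-parameter scale", {
  cfg <- model_config()
  params <- init_params(cfg, n_codes = 12)
  np <- n_params(params)
  expect_gte(np, 5e5)
  expect_lte(np, 2e6)
})
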