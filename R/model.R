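# Selective state-space sequence classifier.
#
# Architecture: triplet embedding (causal 1-D convolutions on time and value,
# look-up embedding on the variable code, sinusoidal positional encoding),
# two gated selective state-space blocks, top-k pooling over unmasked
# positions, an MLP back to model width, additive fusion with a two-layer
# static embedding, and nine independent sigmoid heads. Trained by
# class-weighted binary cross-entropy with Adam; all gradients are
# hand-derived (the sequential scan kernel lives in src/scan.cpp).

HEAD_NAMES <- c("discharge", "stable", "unstable", "deceased",
                "unstable_to_stable", "stable_to_unstable",
                "mv", "vp", "crrt")
LABEL_COLS <- c("y_discharge", "y_stable", "y_unstable", "y_deceased",
                "y_unstable_to_stable", "y_stable_to_unstable",
                "y_mv_onset", "y_vp_onset", "y_crrt_onset")

#' Model configuration
#'
#' Sizes not reported by the underlying architecture description get explicit
#' defaults here: `D = 64`, `state_dim = 16`, `k = 8`, `L = 256`, two blocks,
#' expansion factor 2 inside each block, and a 4096-wide post-pooling MLP
#' (which is where most of the roughly-a-million parameters of the default
#' model live).
#'
#' @param L Maximum triplet sequence length.
#' @param D Model (embedding) width.
#' @param n_blocks Number of state-space blocks.
#' @param state_dim Hidden-state size per channel of the scan.
#' @param k Top-k pool size (`k <= L`).
#' @param f Number of static features.
#' @param conv_kernel Odd causal convolution width.
#' @param expand Channel expansion factor inside each block.
#' @param dt_rank Rank of the low-rank step-size projection.
#' @param mlp_hidden Hidden width of the post-pooling MLP.
#' @param seed Integer seed for initialization and batching.
#' @param lr,epochs,batch_size,weight_decay Adam training hyperparameters.
#' @param class_weight_cap Upper cap on the per-head positive-class weight.
#' @return Object of class `model_config`.
#' @export
model_config <- function(L = 256L, D = 64L, n_blocks = 2L, state_dim = 16L,
                         k = 8L, f = 8L, conv_kernel = 3L, expand = 2L,
                         dt_rank = 8L, mlp_hidden = 4096L, seed = 1L,
                         lr = 1e-3, epochs = 5L, batch_size = 128L,
                         weight_decay = 0, class_weight_cap = 100) {
  stopifnot(k <= L, D >= 1, state_dim >= 1, n_blocks >= 1,
            conv_kernel %% 2 == 1)
  structure(list(L = as.integer(L), D = as.integer(D),
                 n_blocks = as.integer(n_blocks),
                 state_dim = as.integer(state_dim), k = as.integer(k),
                 f = as.integer(f), conv_kernel = as.integer(conv_kernel),
                 expand = as.integer(expand), dt_rank = as.integer(dt_rank),
                 mlp_hidden = as.integer(mlp_hidden), seed = as.integer(seed),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 class_weight_cap = class_weight_cap,
                 n_heads = 9L),
            class = "model_config")
}

.silu <- function(x) x * plogis(x)
.dsilu <- function(x) { s <- plogis(x); s * (1 + x * (1 - s)) }
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# shift a token matrix (time-major blocks of n rows) back by `steps` time
# steps, zero-filling the start
.shift_tokens <- function(m, n, steps) {
  if (steps == 0) return(m)
  k <- steps * n
  out <- matrix(0, nrow(m), ncol(m))
  out[(k + 1):nrow(m), ] <- m[seq_len(nrow(m) - k), ]
  out
}
.unshift_tokens <- function(m, n, steps) {
  if (steps == 0) return(m)
  k <- steps * n
  out <- matrix(0, nrow(m), ncol(m))
  out[seq_len(nrow(m) - k), ] <- m[(k + 1):nrow(m), ]
  out
}

# add a row vector to every row without sweep()/aperm
.addrow <- function(X, v) X + rep(v, each = nrow(X))

#' Sinusoidal positional encoding
#'
#' Channel pairs follow the standard construction: for 0-based position `p`
#' and channel `2i`, `sin(p / 10000^(2i/D))`; channel `2i+1` the matching
#' cosine.
#'
#' @param T_len Number of positions.
#' @param D Embedding width.
#' @return A `T_len x D` matrix.
#' @export
positional_encoding <- function(T_len, D) {
  p <- seq_len(T_len) - 1
  P <- matrix(0, T_len, D)
  for (i in seq_len(ceiling(D / 2)) - 1L) {
    freq <- 1 / 10000^(2 * i / D)
    P[, 2 * i + 1] <- sin(p * freq)
    if (2 * i + 2 <= D) P[, 2 * i + 2] <- cos(p * freq)
  }
  P
}

.rnormm <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize model parameters
#'
#' @param cfg A [model_config()].
#' @param n_codes Number of variable codes in the vocabulary (excluding the
#'   padding code 0, whose embedding row is fixed at zero).
#' @return Named list of parameter arrays.
#' @export
init_params <- function(cfg, n_codes) {
  set.seed(cfg$seed)
  D <- cfg$D; d <- cfg$D * cfg$expand; S <- cfg$state_dim
  ck <- cfg$conv_kernel; r <- cfg$dt_rank
  p <- list(
    wt_time = .rnormm(ck, D, 1 / sqrt(ck)),
    b_time = numeric(D),
    wt_val = .rnormm(ck, D, 1 / sqrt(ck)),
    b_val = numeric(D),
    E_code = rbind(0, .rnormm(n_codes, D, 0.5))
  )
  for (b in seq_len(cfg$n_blocks)) {
    dt0 <- exp(runif(d, log(1e-3), log(1e-1)))
    blk <- list(
      g_rms = rep(1, D),
      W_in = .rnormm(D, 2 * d, 1 / sqrt(D)),
      conv_w = .rnormm(ck, d, 1 / sqrt(ck)),
      conv_b = numeric(d),
      W_dt1 = .rnormm(d, r, 1 / sqrt(d)),
      W_dt2 = .rnormm(r, d, 1 / sqrt(r)),
      b_dt = log(expm1(dt0)),           # softplus inverse of the target step
      W_B = .rnormm(d, S, 1 / sqrt(d)),
      W_C = .rnormm(d, S, 1 / sqrt(d)),
      A_log = matrix(log(seq_len(S)), d, S, byrow = TRUE),
      D_skip = rep(1, d),
      W_out = .rnormm(d, D, 1 / sqrt(d))
    )
    names(blk) <- paste0("blk", b, "_", names(blk))
    p <- c(p, blk)
  }
  Hm <- cfg$mlp_hidden
  p <- c(p, list(
    W_m1 = .rnormm(D, Hm, 1 / sqrt(D)), b_m1 = numeric(Hm),
    W_m2 = .rnormm(Hm, D, 1 / sqrt(Hm)), b_m2 = numeric(D),
    W_s1 = .rnormm(cfg$f, D, 1 / sqrt(cfg$f)), b_s1 = numeric(D),
    W_s2 = .rnormm(D, D, 1 / sqrt(D)), b_s2 = numeric(D),
    W_h = .rnormm(D, cfg$n_heads, 1 / sqrt(D)), b_h = numeric(cfg$n_heads)
  ))
  p
}

#' Count model parameters
#' @param params Parameter list from [init_params()] or a fitted model.
#' @return Integer total number of scalar parameters.
#' @export
n_params <- function(params) {
  if (inherits(params, "acuity_model")) params <- params$params
  sum(vapply(params, length, integer(1)))
}

#' Embed a batch of triplet sequences
#'
#' `embedding = conv(time) + conv(value) + lookup(code) + positional
#' encoding`, with causal (left-padded) convolutions so a position never sees
#' later events, and the padding code 0 mapping through a zero lookup row.
#'
#' @param params Parameter list.
#' @param batch List with `N x T` matrices `times`, `values`, `codes`, `mask`.
#' @param cfg A [model_config()].
#' @return List: `U` (tokens x D embedding, time-major blocks of N rows) and
#'   a cache for the backward pass.
#' @export
embed_triplets <- function(params, batch, cfg) {
  N <- nrow(batch$times); T_len <- ncol(batch$times)
  ck <- cfg$conv_kernel
  cv <- as.integer(as.vector(batch$codes))
  if (any(cv < 0) || any(cv > nrow(params$E_code) - 1L)) {
    abort("variable code outside vocabulary")
  }
  tv <- as.vector(batch$times); vv <- as.vector(batch$values)
  Xt <- vapply(seq_len(ck) - 1L,
               function(j) .shift_tokens(matrix(tv), N, j)[, 1], tv)
  Xv <- vapply(seq_len(ck) - 1L,
               function(j) .shift_tokens(matrix(vv), N, j)[, 1], vv)
  P <- positional_encoding(T_len, cfg$D)
  U <- Xt %*% params$wt_time + Xv %*% params$wt_val +
    params$E_code[cv + 1L, , drop = FALSE] +
    P[rep(seq_len(T_len), each = N), , drop = FALSE]
  U <- .addrow(U, params$b_time + params$b_val)
  list(U = U, cache = list(Xt = Xt, Xv = Xv, cv = cv, N = N, T_len = T_len))
}

.embed_backward <- function(params, cache, dU) {
  g <- list(
    wt_time = crossprod(cache$Xt, dU),
    wt_val = crossprod(cache$Xv, dU),
    b_time = colSums(dU),
    b_val = colSums(dU),
    E_code = matrix(0, nrow(params$E_code), ncol(params$E_code))
  )
  rs <- rowsum(dU, group = cache$cv, reorder = FALSE)
  g$E_code[as.integer(rownames(rs)) + 1L, ] <- rs
  g$E_code[1, ] <- 0  # padding row is fixed at zero
  g
}

# One gated selective state-space block: RMSNorm -> in-projection ->
# causal depthwise conv -> SiLU -> input-conditioned scan (+ skip) ->
# multiplicative SiLU gate -> out-projection -> residual.
.block_forward <- function(bp, U, N, T_len, cfg, H_buf = NULL) {
  d <- cfg$D * cfg$expand
  eps <- 1e-6
  ms <- sqrt(rowMeans(U^2) + eps)
  Un <- (U / ms) * rep(bp$g_rms, each = nrow(U))
  xz <- Un %*% bp$W_in
  xt <- xz[, seq_len(d), drop = FALSE]
  z <- xz[, d + seq_len(d), drop = FALSE]
  xc <- matrix(0, nrow(xt), d)
  for (j in seq_len(cfg$conv_kernel) - 1L) {
    xc <- xc + .shift_tokens(xt, N, j) *
      rep(bp$conv_w[j + 1, ], each = nrow(xt))
  }
  xc <- .addrow(xc, bp$conv_b)
  pxc <- plogis(xc)
  xs <- xc * pxc
  Hd <- xs %*% bp$W_dt1
  dt_pre <- .addrow(Hd %*% bp$W_dt2, bp$b_dt)
  dt <- .softplus(dt_pre)
  Bm <- xs %*% bp$W_B
  Cm <- xs %*% bp$W_C
  A <- -exp(bp$A_log)
  sc <- ssm_scan_forward(xs, dt, Bm, Cm, A, N, T_len, H_buf)
  y <- sc$y + xs * rep(bp$D_skip, each = nrow(xs))
  pz <- plogis(z)
  sz <- z * pz
  yg <- y * sz
  out <- yg %*% bp$W_out
  list(O = U + out,
       cache = list(U = U, ms = ms, Un = Un, xt = xt, z = z, xc = xc,
                    xs = xs, pxc = pxc, pz = pz, Hd = Hd, dt_pre = dt_pre,
                    dt = dt, Bm = Bm, Cm = Cm, A = A, H = sc$H, y = y,
                    sz = sz, yg = yg, N = N, T_len = T_len))
}

.block_backward <- function(bp, cache, dO, cfg) {
  d <- cfg$D * cfg$expand
  N <- cache$N; T_len <- cache$T_len
  g <- list()
  # residual: dO flows both into `out` and straight through
  dyg <- dO %*% t(bp$W_out)
  g$W_out <- crossprod(cache$yg, dO)
  dy <- dyg * cache$sz
  dz <- dyg * cache$y *
    (cache$pz * (1 + cache$z * (1 - cache$pz)))
  g$D_skip <- colSums(dy * cache$xs)
  dxs <- dy * rep(bp$D_skip, each = nrow(dy))
  sb <- ssm_scan_backward(dy, cache$xs, cache$dt, cache$Bm, cache$Cm,
                          cache$A, cache$H, N, T_len)
  dxs <- dxs + sb$dx
  g$A_log <- sb$dA * cache$A          # A = -exp(A_log) => dA_log = dA * A
  g$W_B <- crossprod(cache$xs, sb$dB)
  g$W_C <- crossprod(cache$xs, sb$dC)
  dxs <- dxs + sb$dB %*% t(bp$W_B) + sb$dC %*% t(bp$W_C)
  ddt_pre <- sb$ddt * plogis(cache$dt_pre)
  g$b_dt <- colSums(ddt_pre)
  g$W_dt2 <- crossprod(cache$Hd, ddt_pre)
  dHd <- ddt_pre %*% t(bp$W_dt2)
  g$W_dt1 <- crossprod(cache$xs, dHd)
  dxs <- dxs + dHd %*% t(bp$W_dt1)
  dxc <- dxs *
    (cache$pxc * (1 + cache$xc * (1 - cache$pxc)))
  g$conv_b <- colSums(dxc)
  g$conv_w <- matrix(0, cfg$conv_kernel, d)
  dxt <- matrix(0, nrow(dxc), d)
  for (j in seq_len(cfg$conv_kernel) - 1L) {
    sh <- .shift_tokens(cache$xt, N, j)
    g$conv_w[j + 1, ] <- colSums(sh * dxc)
    dxt <- dxt + .unshift_tokens(dxc * rep(bp$conv_w[j + 1, ],
                                           each = nrow(dxc)), N, j)
  }
  dxz <- cbind(dxt, dz)
  g$W_in <- crossprod(cache$Un, dxz)
  dUn <- dxz %*% t(bp$W_in)
  # RMSNorm backward
  r <- 1 / cache$ms
  gvec <- bp$g_rms
  g$g_rms <- colSums(dUn * cache$U * r)
  inner <- rowSums(dUn * rep(gvec, each = nrow(dUn)) * cache$U)
  dU <- dUn * rep(gvec, each = nrow(dUn)) * r -
    cache$U * (r^3 / ncol(cache$U)) * inner
  dU <- dU + dO                        # residual path
  list(dU = dU, grads = g)
}

# Top-k pooling: among unmasked positions, average the k position vectors
# with the largest L2 norm (k reduced to the number of real positions when
# needed). Returns pooled rows and the selected token indices for backprop.
.topk_pool <- function(Y, mask, N, T_len, k, sel_fixed = NULL) {
  pooled <- matrix(0, N, ncol(Y))
  sel <- vector("list", N)
  nr <- if (is.null(sel_fixed)) sqrt(rowSums(Y^2)) else NULL
  any_empty <- FALSE
  for (n in seq_len(N)) {
    if (is.null(sel_fixed)) {
      toks <- n + (which(mask[n, seq_len(T_len)] == 1L) - 1L) * N
      if (length(toks) == 0) { any_empty <- TRUE; next }
      ke <- min(k, length(toks))
      top <- toks[order(nr[toks], decreasing = TRUE)[seq_len(ke)]]
    } else {
      top <- sel_fixed[[n]]
      if (is.null(top)) { any_empty <- TRUE; next }
    }
    sel[[n]] <- top
    pooled[n, ] <- colMeans(Y[top, , drop = FALSE])
  }
  if (any_empty) warn("fully masked window: pooled to zero vector")
  list(pooled = pooled, sel = sel)
}

# Full forward pass from the (mask-zeroed) embedding to head probabilities.
.trunk_forward <- function(params, U0, static, mask, cfg, N, T_len,
                           buffers = NULL, pool_sel = NULL) {
  mtok <- as.vector(mask[, seq_len(T_len), drop = FALSE])
  U <- U0 * mtok
  caches <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    bp <- params[paste0("blk", b, "_",
                        c("g_rms", "W_in", "conv_w", "conv_b", "W_dt1",
                          "W_dt2", "b_dt", "W_B", "W_C", "A_log", "D_skip",
                          "W_out"))]
    names(bp) <- sub(paste0("^blk", b, "_"), "", names(bp))
    fb <- .block_forward(bp, U, N, T_len, cfg,
                         if (!is.null(buffers)) buffers[[b]] else NULL)
    U <- fb$O
    caches[[b]] <- fb$cache
  }
  pool <- .topk_pool(U, mask, N, T_len, cfg$k, sel_fixed = pool_sel)
  h1 <- .addrow(pool$pooled %*% params$W_m1, params$b_m1)
  a1 <- .silu(h1)
  temb <- .addrow(a1 %*% params$W_m2, params$b_m2)
  s1 <- .addrow(static %*% params$W_s1, params$b_s1)
  sa <- .silu(s1)
  semb <- .addrow(sa %*% params$W_s2, params$b_s2)
  fv <- temb + semb
  logits <- .addrow(fv %*% params$W_h, params$b_h)
  probs <- plogis(logits)
  list(probs = probs, logits = logits,
       cache = list(blocks = caches, pool = pool, Y = U, h1 = h1, a1 = a1,
                    s1 = s1, sa = sa, fv = fv, static = static, mtok = mtok,
                    N = N, T_len = T_len))
}

# Backward from dL/dlogits; returns parameter grads plus dU0 and dstatic.
.trunk_backward <- function(params, cache, dlogits, cfg) {
  g <- list()
  fv_grad <- dlogits %*% t(params$W_h)
  g$W_h <- crossprod(cache$fv, dlogits)
  g$b_h <- colSums(dlogits)
  # static pathway
  dsemb <- fv_grad
  g$W_s2 <- crossprod(cache$sa, dsemb)
  g$b_s2 <- colSums(dsemb)
  dsa <- dsemb %*% t(params$W_s2)
  ds1 <- dsa * .dsilu(cache$s1)
  g$W_s1 <- crossprod(cache$static, ds1)
  g$b_s1 <- colSums(ds1)
  dstatic <- ds1 %*% t(params$W_s1)
  # temporal MLP
  dtemb <- fv_grad
  g$W_m2 <- crossprod(cache$a1, dtemb)
  g$b_m2 <- colSums(dtemb)
  da1 <- dtemb %*% t(params$W_m2)
  dh1 <- da1 * .dsilu(cache$h1)
  g$W_m1 <- crossprod(cache$pool$pooled, dh1)
  g$b_m1 <- colSums(dh1)
  dpooled <- dh1 %*% t(params$W_m1)
  # pooling backward
  dY <- matrix(0, nrow(cache$Y), ncol(cache$Y))
  for (n in seq_len(cache$N)) {
    top <- cache$pool$sel[[n]]
    if (is.null(top)) next
    dY[top, ] <- dY[top, , drop = FALSE] +
      matrix(dpooled[n, ] / length(top), length(top), ncol(dY), byrow = TRUE)
  }
  # blocks in reverse
  dU <- dY
  for (b in rev(seq_len(cfg$n_blocks))) {
    bp <- params[paste0("blk", b, "_",
                        c("g_rms", "W_in", "conv_w", "conv_b", "W_dt1",
                          "W_dt2", "b_dt", "W_B", "W_C", "A_log", "D_skip",
                          "W_out"))]
    names(bp) <- sub(paste0("^blk", b, "_"), "", names(bp))
    bb <- .block_backward(bp, cache$blocks[[b]], dU, cfg)
    dU <- bb$dU
    names(bb$grads) <- paste0("blk", b, "_", names(bb$grads))
    g <- c(g, bb$grads)
  }
  dU0 <- dU * cache$mtok
  list(grads = g, dU0 = dU0, dstatic = dstatic)
}

#' Forward pass: head probabilities for a batch
#'
#' @param params Parameter list.
#' @param batch List of `N x T` matrices `times`, `values`, `codes`, `mask`
#'   and an `N x f` `static` matrix.
#' @param cfg A [model_config()].
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `probs` (`N x 9`, columns [HEAD_NAMES]) and optionally
#'   `cache`.
#' @export
forward_pass <- function(params, batch, cfg, keep_cache = FALSE) {
  if (ncol(batch$static) != cfg$f) abort("static dimension mismatch")
  N <- nrow(batch$times); T_len <- ncol(batch$times)
  emb <- embed_triplets(params, batch, cfg)
  tf <- .trunk_forward(params, emb$U, batch$static, batch$mask, cfg, N, T_len)
  colnames(tf$probs) <- HEAD_NAMES
  out <- list(probs = tf$probs, logits = tf$logits)
  if (keep_cache) out$cache <- list(emb = emb, trunk = tf$cache)
  out
}

# weighted BCE over heads; labels N x 9 possibly NA (masked). Returns loss
# and dlogits (already normalized by batch size).
.loss_and_dlogits <- function(probs, logits, labels, head_w) {
  maskl <- !is.na(labels)
  y <- ifelse(maskl, labels, 0)
  w <- sweep(ifelse(maskl, y, 0), 2, head_w, "*") + ifelse(maskl, 1 - y, 0)
  w[, head_w == 0] <- 0  # frozen heads contribute nothing
  eps <- 1e-12
  ll <- -(y * log(pmax(probs, eps)) + (1 - y) * log(pmax(1 - probs, eps)))
  loss <- sum(w * ll) / nrow(probs)
  dlogits <- w * (probs - y) / nrow(probs)
  list(loss = loss, dlogits = dlogits)
}

#' Per-head positive class weights
#'
#' `N_neg / N_pos` per head, computed on the training labels and capped.
#' Heads without a single positive label get weight 0 (frozen) with a
#' warning.
#'
#' @param labels Matrix or tibble of the nine label columns (NA = masked).
#' @param cap Upper cap on the weight.
#' @return Named numeric vector of length 9.
#' @export
class_weights <- function(labels, cap = 100) {
  labels <- as.matrix(labels)
  w <- vapply(seq_len(ncol(labels)), function(j) {
    y <- labels[, j]; y <- y[!is.na(y)]
    np <- sum(y == 1); nn <- sum(y == 0)
    if (np == 0) return(0)
    min(cap, nn / np)
  }, numeric(1))
  names(w) <- HEAD_NAMES
  if (any(w == 0)) {
    warn(paste("heads frozen (no positive training labels):",
               paste(HEAD_NAMES[w == 0], collapse = ", ")))
  }
  w
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    if (weight_decay > 0) gmat <- gmat + weight_decay * params[[nm]]
    state$m[[nm]] <- 0.9 * (state$m[[nm]] %||% 0) + 0.1 * gmat
    state$v[[nm]] <- beta2 * (state$v[[nm]] %||% 0) + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$E_code[1, ] <- 0  # padding embedding stays zero
  list(params = params, state = state)
}

# Length-bucketed minibatches: windows are ordered by event count so batches
# have homogeneous sequence lengths; batch order is reshuffled each epoch.
.make_batches <- function(n_events, batch_size) {
  ord <- order(n_events)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

.slice_batch <- function(ds, idx) {
  mask <- ds$mask[idx, , drop = FALSE]
  T_eff <- max(1L, max(which(colSums(mask) > 0), 0L))
  list(times = ds$times[idx, seq_len(T_eff), drop = FALSE],
       values = ds$values[idx, seq_len(T_eff), drop = FALSE],
       codes = ds$codes[idx, seq_len(T_eff), drop = FALSE],
       mask = mask[, seq_len(T_eff), drop = FALSE],
       static = ds$static[idx, , drop = FALSE])
}

.dataset_labels <- function(ds) {
  as.matrix(ds$windows[, LABEL_COLS])
}

#' Train the acuity model
#'
#' Minimizes the sum over heads of class-weighted binary cross-entropy
#' (masked labels contribute nothing) with Adam on length-bucketed
#' minibatches. The split between `train` and `val` must be by stay; see
#' [split_by_stay()]. Training is deterministic given `cfg$seed`. The
#' parameters of the epoch with the lowest validation loss are returned.
#'
#' @param train,val `acuity_dataset` objects ([encode_windows()]).
#' @param cfg A [model_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `acuity_model`: `params`, `cfg`, `head_weights`,
#'   `history` (per-epoch train/val loss), `best_epoch`, `vocab`.
#' @export
train_model <- function(train, val, cfg = model_config(), verbose = FALSE) {
  stopifnot(inherits(train, "acuity_dataset"))
  if (cfg$f != ncol(train$static)) {
    cfg$f <- ncol(train$static)
  }
  set.seed(cfg$seed)
  params <- init_params(cfg, n_codes = nrow(train$vocab$table))
  head_w <- class_weights(.dataset_labels(train), cfg$class_weight_cap)
  labs_tr <- .dataset_labels(train)
  labs_va <- .dataset_labels(val)
  n_ev <- rowSums(train$mask)
  batches <- .make_batches(n_ev, cfg$batch_size)
  # scratch hidden-state buffers reused across batches (one per block)
  max_tokens <- max(vapply(batches, function(ix) {
    length(ix) * max(1L, max(n_ev[ix]))
  }, numeric(1)))
  buffers <- lapply(seq_len(cfg$n_blocks), function(b) {
    numeric(max_tokens * cfg$D * cfg$expand * cfg$state_dim)
  })
  state <- list(m = list(), v = list())
  hist <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(batches))
    tr_loss <- 0
    for (bi in ord) {
      idx <- batches[[bi]]
      bt <- .slice_batch(train, idx)
      emb <- embed_triplets(params, bt, cfg)
      tf <- .trunk_forward(params, emb$U, bt$static, bt$mask, cfg,
                           nrow(bt$times), ncol(bt$times), buffers = buffers)
      ld <- .loss_and_dlogits(tf$probs, tf$logits,
                              labs_tr[idx, , drop = FALSE], head_w)
      tb <- .trunk_backward(params, tf$cache, ld$dlogits, cfg)
      ge <- .embed_backward(params, emb$cache, tb$dU0)
      grads <- c(tb$grads, ge)
      step <- step + 1L
      up <- .adam_step(params, grads, state, cfg$lr, step,
                       weight_decay = cfg$weight_decay)
      params <- up$params; state <- up$state
      tr_loss <- tr_loss + ld$loss * length(idx)
    }
    tr_loss <- tr_loss / nrow(train$windows)
    va_loss <- .eval_loss(params, val, labs_va, head_w, cfg)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss,
                                 val_loss = va_loss)
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f", ep, tr_loss, va_loss))
    }
    if (va_loss < best$loss) {
      best <- list(loss = va_loss, params = params, epoch = ep)
    }
  }
  structure(list(params = best$params, cfg = cfg, head_weights = head_w,
                 history = dplyr::bind_rows(hist), best_epoch = best$epoch,
                 vocab = train$vocab),
            class = "acuity_model")
}

.eval_loss <- function(params, ds, labs, head_w, cfg) {
  batches <- .make_batches(rowSums(ds$mask), cfg$batch_size)
  tot <- 0
  for (idx in batches) {
    bt <- .slice_batch(ds, idx)
    fp <- forward_pass(params, bt, cfg)
    ld <- .loss_and_dlogits(fp$probs, fp$logits, labs[idx, , drop = FALSE],
                            head_w)
    tot <- tot + ld$loss * length(idx)
  }
  tot / nrow(ds$windows)
}

#' @export
print.acuity_model <- function(x, ...) {
  cat("<acuity_model>", format(n_params(x$params), big.mark = ","),
      "parameters |", x$cfg$n_blocks, "SSM blocks, D =", x$cfg$D,
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict head probabilities for every window of a dataset
#'
#' @param object A fitted `acuity_model`.
#' @param dataset An `acuity_dataset`.
#' @param ... Unused.
#' @return Tibble: `stay_id`, `window_index`, and `p_<head>` for the nine
#'   heads.
#' @export
predict.acuity_model <- function(object, dataset, ...) {
  cfg <- object$cfg
  batches <- .make_batches(rowSums(dataset$mask), cfg$batch_size)
  out <- matrix(NA_real_, nrow(dataset$windows), cfg$n_heads)
  for (idx in batches) {
    bt <- .slice_batch(dataset, idx)
    fp <- forward_pass(object$params, bt, cfg)
    out[idx, ] <- fp$probs
  }
  colnames(out) <- paste0("p_", HEAD_NAMES)
  dplyr::bind_cols(dataset$windows[, c("stay_id", "window_index")],
                   tibble::as_tibble(out))
}

#' Split a dataset into train/validation by stay
#'
#' @param dataset An `acuity_dataset`.
#' @param val_fraction Fraction of stays assigned to validation.
#' @param seed Seed for the stay-level draw.
#' @return List of two `acuity_dataset`s: `train`, `val`.
#' @export
split_by_stay <- function(dataset, val_fraction = 0.2, seed = 1L) {
  stays <- unique(dataset$windows$stay_id)
  set.seed(seed)
  n_val <- max(1L, round(length(stays) * val_fraction))
  val_stays <- sample(stays, n_val)
  in_val <- dataset$windows$stay_id %in% val_stays
  list(train = .subset_dataset(dataset, !in_val),
       val = .subset_dataset(dataset, in_val))
}

.subset_dataset <- function(ds, keep) {
  structure(list(windows = ds$windows[keep, , drop = FALSE],
                 times = ds$times[keep, , drop = FALSE],
                 values = ds$values[keep, , drop = FALSE],
                 codes = ds$codes[keep, , drop = FALSE],
                 mask = ds$mask[keep, , drop = FALSE],
                 static = ds$static[keep, , drop = FALSE],
                 vocab = ds$vocab, L = ds$L),
            class = "acuity_dataset")
}

#' Youden-optimal decision threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over all observed probability
#' values as candidate thresholds (predict positive iff `p >= threshold`);
#' ties are broken toward the lower threshold.
#'
#' @param probs Numeric vector of probabilities.
#' @param labels Binary labels (NA allowed; dropped).
#' @return List: `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(probs, labels) {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("degenerate label set: need at least one positive and one negative")
  }
  cand <- sort(unique(p))
  # counts of pos/neg below each candidate (predict + iff p >= c)
  sens <- vapply(cand, function(cc) sum(y == 1 & p >= cc) / n_pos, numeric(1))
  spec <- vapply(cand, function(cc) sum(y == 0 & p < cc) / n_neg, numeric(1))
  J <- sens + spec - 1
  i <- which(J >= max(J) - 1e-15)[1]   # lowest threshold among ties
  list(threshold = cand[i], J = J[i], sensitivity = sens[i],
       specificity = spec[i])
}

#' Select Youden thresholds for all nine heads
#'
#' @param probs Prediction tibble from [predict.acuity_model()].
#' @param windows Labeled windows aligned with `probs`.
#' @return Named numeric vector of thresholds (NA for heads whose validation
#'   labels are degenerate).
#' @export
select_thresholds <- function(probs, windows) {
  out <- setNames(rep(NA_real_, length(HEAD_NAMES)), HEAD_NAMES)
  for (i in seq_along(HEAD_NAMES)) {
    p <- probs[[paste0("p_", HEAD_NAMES[i])]]
    y <- windows[[LABEL_COLS[i]]]
    ok <- !is.na(y)
    if (sum(y[ok] == 1) == 0 || sum(y[ok] == 0) == 0) next
    out[i] <- youden_threshold(p[ok], y[ok])$threshold
  }
  out
}

#' @method tidy acuity_model
#' @export
tidy.acuity_model <- function(x, ...) {
  x$history
}

#' @method glance acuity_model
#' @export
glance.acuity_model <- function(x, ...) {
  tibble::tibble(n_params = n_params(x$params),
                 n_blocks = x$cfg$n_blocks, D = x$cfg$D,
                 L = x$cfg$L, k = x$cfg$k,
                 epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss))
}

# Pure-R sequential reference scan (oracle for the compiled kernel).
.ssm_scan_reference <- function(x, dt, B, C, A, n_batch, n_time) {
  d <- ncol(x); S <- ncol(B)
  y <- matrix(0, nrow(x), d)
  for (n in seq_len(n_batch)) {
    h <- matrix(0, d, S)
    for (t in seq_len(n_time)) {
      tok <- (t - 1) * n_batch + n
      # elementwise: ab[j,s] = 1/(1 - dt[tok,j]*A[j,s])
      ab <- 1 / (1 - sweep(A, 1, dt[tok, ], "*"))
      u <- h + outer(dt[tok, ] * x[tok, ], B[tok, ])
      h <- ab * u
      y[tok, ] <- h %*% C[tok, ]
    }
  }
  y
}
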