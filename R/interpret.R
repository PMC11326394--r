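# Integrated-gradients attribution over the temporal and static embeddings.
#
# The baseline is the "no information" input of this imputation-free encoder:
# an all-padding triplet sequence and a zero static vector. Attributions are
# computed at the embedding layer (midpoint Riemann approximation of the
# path integral) and projected back to events by summing over embedding
# channels; padded positions receive exactly zero attribution.

# Generic path-integral attribution for any differentiable f.
# `f_grad(x)` must return list(value = scalar, grad = like x).
.ig_generic <- function(f_grad, x, x0, n_steps) {
  if (n_steps < 2) abort("n_steps must be >= 2")
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  acc <- x * 0
  for (a in alphas) {
    acc <- acc + f_grad(x0 + a * (x - x0))$grad
  }
  (x - x0) * acc / n_steps
}

#' Integrated-gradients attributions for one prediction head
#'
#' Interpolates the temporal embedding between the all-padding baseline and
#' the actual window (the padding mask held fixed) and the static features
#' between zero and their values, averaging head-probability gradients over
#' `n_steps` midpoints. Per-event attributions are channel sums of the
#' embedding attributions; completeness
#' (`sum(attr) ~= F(x) - F(baseline)`) holds up to the Riemann error.
#'
#' @param model A fitted `acuity_model`.
#' @param dataset An `acuity_dataset`.
#' @param head One of [HEAD_NAMES].
#' @param rows Window rows to attribute (default: all).
#' @param n_steps Interpolation points (>= 2; default 128).
#' @param chunk Windows per processing chunk.
#' @return Object of class `attribution_map`: `event_attr` (N x L, zero at
#'   padding), `static_attr` (N x f), `codes`, `mask`, `F_x`, `F_x0`,
#'   `completeness_gap` (relative), `head`, `n_steps`.
#' @export
integrated_gradients <- function(model, dataset, head, rows = NULL,
                                 n_steps = 128L, chunk = 64L) {
  stopifnot(inherits(model, "acuity_model"), head %in% HEAD_NAMES)
  if (n_steps < 2) abort("n_steps must be >= 2")
  cfg <- model$cfg; params <- model$params
  h_idx <- match(head, HEAD_NAMES)
  if (is.null(rows)) rows <- seq_len(nrow(dataset$windows))
  n <- length(rows)
  event_attr <- matrix(0, n, dataset$L)
  static_attr <- matrix(0, n, ncol(dataset$static),
                        dimnames = list(NULL, colnames(dataset$static)))
  F_x <- numeric(n); F_x0 <- numeric(n)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps

  for (start in seq(1, n, by = chunk)) {
    sub <- rows[start:min(start + chunk - 1, n)]
    bt <- .slice_batch(dataset, sub)
    N <- nrow(bt$times); T_len <- ncol(bt$times)
    Ux <- embed_triplets(params, bt, cfg)$U
    bt0 <- bt
    bt0$times[] <- 0; bt0$values[] <- 0; bt0$codes[] <- 0L
    U0 <- embed_triplets(params, bt0, cfg)$U
    dU <- Ux - U0
    s_x <- bt$static
    # freeze the top-k pooling selection at the actual input for the whole
    # interpolation path: the attributed function is then smooth and the
    # completeness axiom holds up to Riemann error (the standard treatment
    # of max/top-k pooling switches in path attributions)
    sel_x <- .trunk_forward(params, Ux, s_x, bt$mask, cfg,
                            N, T_len)$cache$pool$sel
    grad_U <- Ux * 0; grad_s <- s_x * 0
    for (a in alphas) {
      tf <- .trunk_forward(params, U0 + a * dU, a * s_x, bt$mask, cfg,
                           N, T_len, pool_sel = sel_x)
      dlog <- matrix(0, N, cfg$n_heads)
      pr <- tf$probs[, h_idx]
      dlog[, h_idx] <- pr * (1 - pr)   # d prob / d logit
      tb <- .trunk_backward(params, tf$cache, dlog, cfg)
      grad_U <- grad_U + tb$dU0
      grad_s <- grad_s + tb$dstatic
    }
    attr_U <- dU * grad_U / n_steps
    attr_s <- s_x * grad_s / n_steps
    # channel-summed, reshaped to N x T, zeroed at padding
    ev <- matrix(rowSums(attr_U), N, T_len) * bt$mask
    out_rows <- start:(start + N - 1)
    event_attr[out_rows, seq_len(T_len)] <- ev
    static_attr[out_rows, ] <- attr_s
    F_x[out_rows] <- .trunk_forward(params, Ux, s_x, bt$mask, cfg,
                                    N, T_len,
                                    pool_sel = sel_x)$probs[, h_idx]
    F_x0[out_rows] <- .trunk_forward(params, U0, 0 * s_x, bt$mask, cfg,
                                     N, T_len,
                                     pool_sel = sel_x)$probs[, h_idx]
  }
  total <- rowSums(event_attr) + rowSums(static_attr)
  delta <- F_x - F_x0
  gap <- abs(total - delta) / pmax(abs(delta), 1e-12)
  structure(list(event_attr = event_attr, static_attr = static_attr,
                 codes = dataset$codes[rows, , drop = FALSE],
                 mask = dataset$mask[rows, , drop = FALSE],
                 rows = rows, F_x = F_x, F_x0 = F_x0,
                 completeness_gap = gap, head = head,
                 n_steps = n_steps,
                 baseline = "all-padding sequence + zero static vector"),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat("<attribution_map> head:", x$head, "|", nrow(x$event_attr),
      "windows | n_steps:", x$n_steps, "| median completeness gap:",
      format(stats::median(x$completeness_gap), digits = 3), "\n")
  invisible(x)
}

#' Aggregate attributions into a ranked feature-importance table
#'
#' For each of the increased-acuity heads (unstable, stable-to-unstable
#' transition, MV, VP, CRRT, deceased by default), a variable's attributions
#' are first summed over its events within each window -- a predictive
#' variable contributes with a coherent sign, so its events accumulate,
#' while noise cancels -- and the per-window totals are then averaged (as
#' magnitudes by default) over the windows in which the variable occurs.
#' Static features aggregate the same way, one value per window. Scores are
#' finally averaged over heads and sorted descending.
#'
#' @param model A fitted `acuity_model`.
#' @param dataset An `acuity_dataset`.
#' @param heads Heads to average over.
#' @param rows Window rows to attribute (default: all; subsample for speed).
#' @param n_steps Interpolation points per head.
#' @param top_n Rows of the ranked table to return (default 15).
#' @param absolute Average magnitudes of the per-window totals (default);
#'   `FALSE` averages them with sign, which lets a variable's opposing
#'   low/high-value contributions cancel across windows.
#' @return Tibble: `feature`, `type` (temporal/static), `score`, sorted
#'   descending; at most `top_n` rows (attribute `full` holds the complete
#'   ranking).
#' @export
aggregate_importance <- function(model, dataset,
                                 heads = c("unstable", "stable_to_unstable",
                                           "mv", "vp", "crrt", "deceased"),
                                 rows = NULL, n_steps = 32L, top_n = 15L,
                                 absolute = TRUE) {
  vocab_tab <- dataset$vocab$table
  per_head <- list()
  for (h in heads) {
    am <- integrated_gradients(model, dataset, h, rows = rows,
                               n_steps = n_steps)
    ev <- am$event_attr[, seq_len(ncol(am$codes)), drop = FALSE]
    keep <- am$mask == 1L
    widx <- row(am$codes)[keep]
    key <- paste(widx, am$codes[keep])
    per_window <- tapply(ev[keep], key, sum)   # feature total per window
    code_of <- as.integer(sub("^\\d+ ", "", names(per_window)))
    if (absolute) per_window <- abs(per_window)
    by_var <- tapply(as.numeric(per_window), code_of, mean)
    tv <- tibble::tibble(
      feature = vocab_tab$variable[match(as.integer(names(by_var)),
                                         vocab_tab$code)],
      type = "temporal", score = as.numeric(by_var))
    sa <- am$static_attr
    if (absolute) sa <- abs(sa)
    st <- tibble::tibble(feature = colnames(sa), type = "static",
                         score = colMeans(sa))
    per_head[[h]] <- dplyr::bind_rows(tv, st) |>
      dplyr::mutate(head = h)
  }
  full <- dplyr::bind_rows(per_head) |>
    dplyr::group_by(.data$feature, .data$type) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  out <- head(full, top_n)
  attr(out, "full") <- full
  out
}
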