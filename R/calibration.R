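# Isotonic probability recalibration (pool-adjacent-violators), Brier score
# and reliability curves.

# PAV with tied-x pre-pooling: observations sharing a raw probability are
# pooled first, then adjacent violating blocks are merged until the fitted
# means are non-decreasing. Minimizes squared error subject to monotonicity.
.pav_fit <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(x))
  xs <- tapply(x, grp, function(v) v[1])
  sums <- tapply(y, grp, sum)
  ns <- tapply(y, grp, length)
  n <- length(xs)
  # blocks as stacks: value = sum/n
  bx <- numeric(n); bs <- numeric(n); bn <- numeric(n); top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    bx[top] <- xs[i]; bs[top] <- sums[i]; bn[top] <- ns[i]
    while (top > 1L && bs[top - 1L] / bn[top - 1L] >= bs[top] / bn[top]) {
      bs[top - 1L] <- bs[top - 1L] + bs[top]
      bn[top - 1L] <- bn[top - 1L] + bn[top]
      bx[top - 1L] <- bx[top]          # knot at the block's right edge
      top <- top - 1L
    }
  }
  # expand back to per-unique-x fitted values
  fit <- numeric(n); j <- 1L
  for (b in seq_len(top)) {
    val <- bs[b] / bn[b]
    while (j <= n && xs[j] <= bx[b] + 1e-300) {
      fit[j] <- val; j <- j + 1L
    }
  }
  list(x = as.numeric(xs), fit = fit)
}

#' Fit an isotonic calibration model
#'
#' Pool-adjacent-violators least-squares fit of outcome frequency as a
#' non-decreasing step function of the raw probability, trained on a seeded
#' stay-level subsample (default 10%) of the supplied data.
#'
#' @param probs Raw probabilities.
#' @param labels Binary labels.
#' @param stay_id Optional stay ids; when given, the calibration sample is
#'   drawn by stay.
#' @param sample_fraction Fraction of stays (or observations when `stay_id`
#'   is NULL) used for fitting (default 0.10). Use 1 to fit on everything.
#' @param seed Seed for the subsample draw.
#' @return Object of class `calibration_model`: knots `x`, fitted values `y`
#'   (both non-decreasing), and the fit-sample row indices.
#' @export
fit_isotonic <- function(probs, labels, stay_id = NULL, sample_fraction = 0.10,
                         seed = 1L) {
  keep <- !is.na(labels) & !is.na(probs)
  idx_all <- which(keep)
  set.seed(seed)
  if (!is.null(stay_id)) {
    stays <- unique(stay_id[keep])
    pick <- sample(stays, max(1L, round(length(stays) * sample_fraction)))
    idx <- idx_all[stay_id[keep] %in% pick]
  } else {
    idx <- sample(idx_all, max(1L, round(length(idx_all) * sample_fraction)))
  }
  p <- probs[idx]; y <- labels[idx]
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    abort("degenerate calibration sample: need both classes")
  }
  f <- .pav_fit(p, y)
  structure(list(x = f$x, y = f$fit, fit_idx = idx,
                 fingerprint = sum(idx) + length(idx) * 1e-9),
            class = "calibration_model")
}

#' Apply an isotonic calibration model
#'
#' Step-function interpolation between fitted knots; raw probabilities
#' outside the fitted range clamp to the nearest knot.
#'
#' @param model A `calibration_model`.
#' @param probs Raw probabilities.
#' @return Calibrated probabilities in `[0, 1]`.
#' @export
apply_calibration <- function(model, probs) {
  stopifnot(inherits(model, "calibration_model"))
  idx <- findInterval(probs, model$x)      # 0 when below the first knot
  out <- model$y[pmax(idx, 1L)]
  out[idx == 0L] <- model$y[1]
  out
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>", length(x$x), "knots, range [",
      format(min(x$y), digits = 3), ",", format(max(x$y), digits = 3), "]\n")
  invisible(x)
}

#' Brier score
#'
#' Mean squared error between predicted probability and binary outcome.
#'
#' @param probs Probabilities.
#' @param labels Binary labels.
#' @return The Brier score.
#' @export
brier <- function(probs, labels) {
  keep <- !is.na(labels) & !is.na(probs)
  mean((probs[keep] - labels[keep])^2)
}

#' Reliability (calibration) curve
#'
#' Bins predictions into `n_bins` equal-width probability bins and reports
#' mean predicted probability against observed event rate. Empty bins are
#' omitted (flagged by the `n` column of the returned tibble).
#'
#' @inheritParams brier
#' @param n_bins Number of equal-width bins (default 10).
#' @return Tibble: `bin`, `mean_pred`, `obs_rate`, `n`.
#' @export
reliability_curve <- function(probs, labels, n_bins = 10) {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  bin <- pmin(n_bins, pmax(1L, ceiling(p * n_bins)))
  bin[p == 0] <- 1L
  out <- tibble::tibble(bin = bin, p = p, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_pred = mean(.data$p), obs_rate = mean(.data$y),
                     n = dplyr::n(), .groups = "drop")
  out
}

#' Serialize / restore a calibration model as JSON step functions
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `read_calibration()` returns the restored model.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(list(x = model$x, y = model$y), path,
                       digits = I(17))  # exact double round-trip
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x = obj$x, y = obj$y, fit_idx = NULL, fingerprint = NA),
            class = "calibration_model")
}
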