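# ggplot2 graphics for evaluation, calibration and attribution results.

#' ROC curve plot for one head
#'
#' @param probs Scores.
#' @param labels Binary labels.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_roc <- function(probs, labels, title = "ROC") {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- p >= t
    tibble::tibble(fpr = sum(pred & y == 0) / max(1, sum(y == 0)),
                   tpr = sum(pred & y == 1) / max(1, sum(y == 1)))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(title = title,
                  subtitle = sprintf("AUROC = %.3f", auroc(p, y)),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Reliability-curve plot
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param n_bins Equal-width probability bins.
#' @return A ggplot object.
#' @export
plot_reliability <- function(probs, labels, n_bins = 10) {
  rc <- reliability_curve(probs, labels, n_bins)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$mean_pred, y = .data$obs_rate)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), show.legend = FALSE) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability", y = "observed rate",
                  subtitle = sprintf("Brier = %.4f", brier(probs, labels))) +
    ggplot2::theme_minimal()
}

#' Per-stay attribution heat strip over a vital's timeline
#'
#' Plots one variable's measurements for one stay, shaded by the
#' integrated-gradient attribution of each event (darker orange = larger
#' attribution), analogous to bedside vitals timelines annotated with model
#' attention.
#'
#' @param attribution An `attribution_map` ([integrated_gradients()]).
#' @param dataset The `acuity_dataset` it was computed on.
#' @param stay One stay id.
#' @param variable Variable name to plot.
#' @return A ggplot object.
#' @export
plot_attribution_strip <- function(attribution, dataset, stay, variable) {
  rows <- attribution$rows
  win <- dataset$windows[rows, ]
  sel <- which(win$stay_id == stay)
  if (length(sel) == 0) abort(paste("no attributed windows for stay", stay))
  code <- dataset$vocab$table$code[dataset$vocab$table$variable == variable]
  if (length(code) == 0) abort(paste("unknown variable", variable))
  pts <- purrr::map_dfr(sel, function(i) {
    j <- which(attribution$mask[i, ] == 1L & attribution$codes[i, ] == code)
    if (length(j) == 0) return(NULL)
    tibble::tibble(
      time_hours = dataset$times[rows[i], j] * dataset$vocab$time_scale,
      value = dataset$values[rows[i], j],
      attr = attribution$event_attr[i, j])
  })
  if (nrow(pts) == 0) abort("variable has no events in the attributed windows")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_hours, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = abs(.data$attr)), size = 2) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "darkorange",
                                   name = "|attribution|") +
    ggplot2::labs(x = "hours since admission",
                  y = paste(variable, "(scaled)"),
                  title = paste(stay, "-", attribution$head, "head")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object An `acuity_model`; plots its training history.
#' @param ... Unused.
#' @method autoplot acuity_model
#' @export
autoplot.acuity_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "class-weighted BCE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
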