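# Step- and episode-level evaluation: threshold-free ranking metrics,
# precision-targeted alert thresholds, lead-time/alert statistics,
# stay-level bootstrap confidence intervals, and model comparison tests.

#' Area under the ROC curve (midrank tie handling)
#'
#' Equivalent to the Mann-Whitney statistic: ties contribute 1/2 a
#' concordance via midranks.
#'
#' @param probs Scores.
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(probs, labels) {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("AUROC undefined: single-class labels")
  r <- rank(p)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds descend over the unique score values; tied scores enter
#' together. The curve is integrated as a right-continuous step function
#' (sum of recall increments times the precision attained at each
#' threshold).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(probs, labels) {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  n1 <- sum(y == 1)
  if (n1 == 0 || all(y == 1)) abort("AUPRC undefined: single-class labels")
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]; p <- p[ord]
  grp_end <- cumsum(rle(p)$lengths)
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Step-level metrics at a threshold
#'
#' AUROC, AUPRC, and -- at the supplied threshold (predict positive iff
#' `p >= threshold`) -- sensitivity, specificity, PPV and NPV.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @return A one-row tibble of the six metrics.
#' @export
step_metrics <- function(probs, labels, threshold = 0.5) {
  keep <- !is.na(labels) & !is.na(probs)
  p <- probs[keep]; y <- labels[keep]
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    abort("metrics undefined: single-class labels")
  }
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  tibble::tibble(
    auroc = auroc(p, y), auprc = auprc(p, y),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Episode-level records: per-stay maximum pre-onset probability
#'
#' For each stay: when the outcome occurs, the episode score is the maximum
#' predicted probability over the windows strictly before onset (the first
#' positive-label window); when it never occurs, the maximum over all
#' windows. Stays whose outcome occurs in their first eligible window have no
#' pre-onset window and are excluded (logged in attribute `excluded`).
#'
#' @param probs Numeric vector of per-window probabilities.
#' @param labels Per-window binary outcome labels (NA allowed; NA windows are
#'   not eligible onset windows but still contribute pre-onset scores).
#' @param stay_id Stay identifier per window, ordered by window within stay.
#' @return Tibble: `stay_id`, `outcome_present`, `episode_score`,
#'   `onset_window` (position within stay, NA if absent); attribute
#'   `excluded` lists stays dropped for onset-in-first-window.
#' @export
episode_scores <- function(probs, labels, stay_id) {
  d <- tibble::tibble(stay_id = stay_id, p = probs, y = labels)
  out <- list(); dropped <- character()
  for (sid in unique(d$stay_id)) {
    dd <- d[d$stay_id == sid, ]
    onset <- which(!is.na(dd$y) & dd$y == 1)[1]
    if (!is.na(onset)) {
      if (onset == 1L) { dropped <- c(dropped, sid); next }
      out[[sid]] <- tibble::tibble(stay_id = sid, outcome_present = 1L,
                                   episode_score = max(dd$p[seq_len(onset - 1)]),
                                   onset_window = onset)
    } else {
      out[[sid]] <- tibble::tibble(stay_id = sid, outcome_present = 0L,
                                   episode_score = max(dd$p),
                                   onset_window = NA_integer_)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded") <- dropped
  res
}

#' Smallest threshold achieving a target episode-level precision
#'
#' Sweeps the observed episode scores as candidate thresholds (alarm iff
#' `score >= threshold`) and returns the smallest one whose PPV reaches
#' `target_ppv`. Smaller thresholds alarm on more episodes, so this is the
#' most sensitive operating point at that precision.
#'
#' @param episodes Episode tibble from [episode_scores()].
#' @param target_ppv Target precision (default 0.33).
#' @return List: `threshold` (NA if unattainable), `ppv`, `sensitivity`,
#'   `max_ppv` (diagnostic when unattainable).
#' @export
precision_targeted_threshold <- function(episodes, target_ppv = 0.33) {
  y <- episodes$outcome_present
  s <- episodes$episode_score
  if (sum(y == 1) == 0) {
    return(list(threshold = NA_real_, ppv = NA_real_,
                sensitivity = NA_real_, max_ppv = NA_real_))
  }
  cand <- sort(unique(s))
  ppv <- vapply(cand, function(th) {
    alarm <- s >= th
    if (!any(alarm)) return(NA_real_)
    sum(y[alarm] == 1) / sum(alarm)
  }, numeric(1))
  ok <- which(!is.na(ppv) & ppv >= target_ppv)
  if (length(ok) == 0) {
    return(list(threshold = NA_real_, ppv = NA_real_, sensitivity = NA_real_,
                max_ppv = max(ppv, na.rm = TRUE)))
  }
  i <- ok[1]
  th <- cand[i]
  list(threshold = th, ppv = ppv[i],
       sensitivity = sum(y == 1 & s >= th) / sum(y == 1),
       max_ppv = max(ppv, na.rm = TRUE))
}

#' Lead time and alert count for one stay with the outcome
#'
#' Lead time is the gap, in hours, between the start of the first
#' super-threshold pre-onset window and the start of the onset window; the
#' alert count is the number of super-threshold pre-onset windows.
#'
#' @param probs Per-window probabilities of one stay, in window order.
#' @param threshold Alarm threshold.
#' @param onset_window 1-based position of the onset window within the stay.
#' @param window_hours Window length in hours (default 4).
#' @return List: `lead_hours` (NA when no alert fired), `n_alerts`.
#' @export
lead_time_and_alerts <- function(probs, threshold, onset_window,
                                 window_hours = 4) {
  stopifnot(onset_window >= 1, onset_window <= length(probs))
  pre <- seq_len(onset_window - 1)
  alerts <- which(probs[pre] >= threshold)
  if (length(alerts) == 0) return(list(lead_hours = NA_real_, n_alerts = 0L))
  list(lead_hours = (onset_window - alerts[1]) * window_hours,
       n_alerts = length(alerts))
}

#' Stay-resampled bootstrap confidence interval for a metric
#'
#' Resamples stays (not windows) with replacement, preserving within-stay
#' correlation, and reports the 2.5/50/97.5 percentiles of the metric over
#' `n_boot` iterations. Resamples on which the metric is undefined (e.g.
#' single-class) are redrawn, at most 10 times each, with a log attribute.
#'
#' @param metric_fn Function `(data_subset) -> scalar`, where `data_subset`
#'   is the row-bound resample of `data`.
#' @param data Tibble with a `stay_id` column.
#' @param n_boot Bootstrap iterations (default 100).
#' @param seed Seed.
#' @return List: `median`, `lo`, `hi`, `values` (the bootstrap draws),
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 100, seed = 1L) {
  if (nrow(data) == 0) abort("empty data")
  set.seed(seed)
  by_stay <- split(seq_len(nrow(data)), data$stay_id)
  stays <- names(by_stay)
  vals <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    v <- NA_real_
    for (try in seq_len(11L)) {
      pick <- sample(stays, length(stays), replace = TRUE)
      idx <- unlist(by_stay[pick], use.names = FALSE)
      v <- tryCatch(metric_fn(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (!is.na(v)) break
      n_redrawn <- n_redrawn + 1L
      if (try == 11L) abort("metric undefined on 10 consecutive resamples")
    }
    vals[b] <- v
  }
  q <- quantile(vals, c(0.025, 0.5, 0.975), names = FALSE)
  list(median = q[2], lo = q[1], hi = q[3], values = vals,
       n_redrawn = n_redrawn)
}

#' Compare two bootstrap metric distributions
#'
#' Two-sided Wilcoxon rank-sum test on the bootstrap metric samples of two
#' models (exact for small tie-free samples, normal approximation with tie
#' correction otherwise).
#'
#' @param a,b Numeric metric samples.
#' @return The p-value.
#' @export
compare_models <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
}

#' Step- and episode-level evaluation report
#'
#' Computes the six step-level metrics and the episode-level AUROC/AUPRC for
#' one head, with stay-resampled bootstrap confidence intervals.
#'
#' @param probs Per-window probabilities.
#' @param labels Per-window binary labels.
#' @param stay_id Stay id per window.
#' @param threshold Step-level decision threshold (e.g. the Youden
#'   threshold).
#' @param n_boot Bootstrap iterations.
#' @param seed Seed.
#' @return Tibble: one row per (level, metric) with `estimate` (bootstrap
#'   median), `lo`, `hi`.
#' @export
evaluate_head <- function(probs, labels, stay_id, threshold = 0.5,
                          n_boot = 100, seed = 1L) {
  d <- tibble::tibble(stay_id = stay_id, p = probs, y = labels)
  step_fns <- list(
    auroc = function(dd) auroc(dd$p, dd$y),
    auprc = function(dd) auprc(dd$p, dd$y),
    sensitivity = function(dd) step_metrics(dd$p, dd$y, threshold)$sensitivity,
    specificity = function(dd) step_metrics(dd$p, dd$y, threshold)$specificity,
    ppv = function(dd) step_metrics(dd$p, dd$y, threshold)$ppv,
    npv = function(dd) step_metrics(dd$p, dd$y, threshold)$npv
  )
  ep_fns <- list(
    auroc = function(dd) {
      es <- episode_scores(dd$p, dd$y, dd$stay_id)
      auroc(es$episode_score, es$outcome_present)
    },
    auprc = function(dd) {
      es <- episode_scores(dd$p, dd$y, dd$stay_id)
      auprc(es$episode_score, es$outcome_present)
    }
  )
  rows <- list()
  for (m in names(step_fns)) {
    ci <- bootstrap_ci(function(dd) step_fns[[m]](dd), d, n_boot, seed)
    rows[[paste0("step_", m)]] <- tibble::tibble(
      level = "step", metric = m, estimate = ci$median,
      lo = ci$lo, hi = ci$hi)
  }
  for (m in names(ep_fns)) {
    ci <- bootstrap_ci(function(dd) ep_fns[[m]](dd), d, n_boot, seed)
    rows[[paste0("episode_", m)]] <- tibble::tibble(
      level = "episode", metric = m, estimate = ci$median,
      lo = ci$lo, hi = ci$hi)
  }
  dplyr::bind_rows(rows)
}
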