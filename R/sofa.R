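# SOFA-score baseline predictors: the 0-1 scaled raw score and the
# >= 2-point-rise-from-baseline instability criterion. SOFA is consumed as a
# precomputed score series; organ-component computation is out of scope.

#' Scale a raw SOFA score to the unit interval
#'
#' @param raw Integer SOFA scores in `[0, 24]`.
#' @return `raw / 24`.
#' @export
scale_sofa <- function(raw) {
  if (any(is.na(raw)) || any(raw < 0) || any(raw > 24)) {
    abort("SOFA scores must lie in [0, 24]")
  }
  raw / 24
}

#' Two-or-more-point SOFA rise from baseline
#'
#' Flags a window unstable when the current SOFA score exceeds the admission
#' (baseline) score by at least 2 points; decreases never flag.
#'
#' @param current,baseline Integer SOFA scores in `[0, 24]`.
#' @return Integer 0/1 flags.
#' @export
sofa_delta_flag <- function(current, baseline) {
  if (any(c(current, baseline) < 0) || any(c(current, baseline) > 24)) {
    abort("SOFA scores must lie in [0, 24]")
  }
  as.integer(current - baseline >= 2)
}

#' Per-window SOFA series for labeled windows
#'
#' Carries the last SOFA measurement forward onto each prediction window
#' (value at the window start) and attaches the admission baseline.
#'
#' @param sofa Tibble `stay_id`, `time_hours`, `sofa` of score measurements.
#' @param windows Labeled windows ([label_windows()]).
#' @return `windows`-aligned tibble: `stay_id`, `window_index`, `sofa`,
#'   `baseline_sofa`, `sofa_scaled`, `sofa_delta_flag`.
#' @export
sofa_series <- function(sofa, windows) {
  out <- windows[, c("stay_id", "window_index", "pred_start")]
  cur <- numeric(nrow(out)); base <- numeric(nrow(out))
  by_stay <- split(sofa, sofa$stay_id)
  for (sid in unique(out$stay_id)) {
    s <- by_stay[[sid]]
    rows <- which(out$stay_id == sid)
    if (is.null(s) || nrow(s) == 0) {
      abort(paste("no SOFA series for stay", sid))
    }
    s <- s[order(s$time_hours), ]
    idx <- findInterval(out$pred_start[rows], s$time_hours)
    cur[rows] <- s$sofa[pmax(idx, 1L)]
    base[rows] <- s$sofa[1]
  }
  tibble::tibble(stay_id = out$stay_id, window_index = out$window_index,
                 sofa = cur, baseline_sofa = base,
                 sofa_scaled = scale_sofa(cur),
                 sofa_delta_flag = sofa_delta_flag(cur, base))
}
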