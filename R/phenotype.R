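# Computable acuity phenotyping.
#
# Turns therapy intervals, transfusion events and dispositions into per-window
# acuity states (discharge / stable / unstable / deceased), transition labels,
# therapy-onset labels and cohort-level transition matrices, and applies the
# admission filters. All window intervals are half-open [start, end); times
# are fractional hours since ICU admission; window indices are 0-based.

ACUITY_LEVELS <- c("discharge", "stable", "unstable", "deceased")
THERAPIES <- c("MV", "VP", "CRRT")
REQUIRED_VITALS <- c("hr", "rr", "sbp", "dbp", "temp", "spo2")
STATIC_CORE <- c("age", "sex", "race", "bmi")

#' Phenotyping configuration
#'
#' @param window_hours Length of each observation and prediction window,
#'   in hours (default 4).
#' @param bt_window_hours Trailing window for the massive-transfusion rule,
#'   in hours (default 24).
#' @param bt_unit_threshold Units of blood product within the trailing window
#'   that constitute a massive transfusion (default 10, inclusive).
#' @param min_los_hours,max_los_days Admission filter bounds: stays shorter
#'   than `min_los_hours` or longer than `max_los_days` are excluded.
#' @param required_vitals Names of the routine vitals every kept stay must
#'   have at least one measurement of.
#' @return An object of class `phenotype_config`.
#' @export
phenotype_config <- function(window_hours = 4,
                             bt_window_hours = 24,
                             bt_unit_threshold = 10,
                             min_los_hours = 8,
                             max_los_days = 30,
                             required_vitals = REQUIRED_VITALS) {
  stopifnot(window_hours > 0, bt_window_hours > 0, bt_unit_threshold >= 1,
            min_los_hours < max_los_days * 24)
  structure(list(window_hours = window_hours,
                 bt_window_hours = bt_window_hours,
                 bt_unit_threshold = bt_unit_threshold,
                 min_los_hours = min_los_hours,
                 max_los_days = max_los_days,
                 required_vitals = required_vitals),
            class = "phenotype_config")
}

#' Apply the admission filters to a cohort
#'
#' A stay is kept iff its length of stay lies in
#' `[min_los_hours, max_los_days * 24]`, every required vital has at least one
#' event, and no static field is missing. Each excluded stay carries a
#' machine-readable reason code: `los_below_min`, `los_above_max`,
#' `missing_vital_<name>`, or `missing_static_<field>` (first failing rule in
#' that order).
#'
#' @param cohort An `icu_cohort` (or any list with `events`, `static`,
#'   `dispositions` tibbles).
#' @param cfg A [phenotype_config()].
#' @return A list with `kept` (character vector of stay ids) and `excluded`
#'   (tibble `stay_id`, `reason`).
#' @export
apply_cohort_filters <- function(cohort, cfg = phenotype_config()) {
  dispo <- cohort$dispositions
  static <- cohort$static
  ev <- cohort$events
  vital_sets <- ev |>
    dplyr::filter(.data$variable %in% cfg$required_vitals) |>
    dplyr::distinct(.data$stay_id, .data$variable)
  static_fields <- setdiff(names(static), "stay_id")
  reasons <- character(nrow(dispo))
  for (i in seq_len(nrow(dispo))) {
    sid <- dispo$stay_id[i]
    los <- dispo$disposition_time_hours[i]
    if (los < cfg$min_los_hours) { reasons[i] <- "los_below_min"; next }
    if (los > cfg$max_los_days * 24) { reasons[i] <- "los_above_max"; next }
    have <- vital_sets$variable[vital_sets$stay_id == sid]
    miss <- setdiff(cfg$required_vitals, have)
    if (length(miss)) { reasons[i] <- paste0("missing_vital_", miss[1]); next }
    srow <- static[static$stay_id == sid, static_fields, drop = FALSE]
    if (nrow(srow) == 0) { reasons[i] <- "missing_static_all"; next }
    bad <- static_fields[vapply(srow[1, ], function(v) is.na(v), logical(1))]
    if (length(bad)) { reasons[i] <- paste0("missing_static_", bad[1]); next }
  }
  list(
    kept = dispo$stay_id[reasons == ""],
    excluded = tibble::tibble(stay_id = dispo$stay_id[reasons != ""],
                              reason = reasons[reasons != ""])
  )
}

#' Build the observation/prediction window grid for one stay
#'
#' Prediction windows tile `[window_hours, disposition_time]`; each prediction
#' window's observation window is the immediately preceding `window_hours`.
#' The final window may be shorter than `window_hours` and is kept (it carries
#' the terminal state). Events are assigned to windows by the half-open
#' convention `[start, end)`.
#'
#' @param disposition_time_hours Length of stay in hours.
#' @param cfg A [phenotype_config()].
#' @return A tibble `window_index` (0-based), `obs_start`, `obs_end`,
#'   `pred_start`, `pred_end`, with attribute `too_short = TRUE` (and zero
#'   rows) when the stay cannot support one observation + prediction window.
#' @export
build_window_grid <- function(disposition_time_hours, cfg = phenotype_config()) {
  w <- cfg$window_hours
  if (disposition_time_hours < 2 * w) {
    warn("stay too short for one observation + prediction window")
    out <- tibble::tibble(window_index = integer(), obs_start = numeric(),
                          obs_end = numeric(), pred_start = numeric(),
                          pred_end = numeric())
    attr(out, "too_short") <- TRUE
    return(out)
  }
  starts <- seq(w, disposition_time_hours, by = w)
  starts <- starts[starts < disposition_time_hours]
  ends <- pmin(starts + w, disposition_time_hours)
  tibble::tibble(window_index = seq_along(starts) - 1L,
                 obs_start = starts - w, obs_end = starts,
                 pred_start = starts, pred_end = ends)
}

#' Massive-transfusion flag at a time point
#'
#' Returns 1 iff the summed units over the trailing half-open interval
#' `(t - bt_window_hours, t]` reach `bt_unit_threshold`.
#'
#' @param bt_events Tibble `time_hours`, `units` for one stay, sorted by time.
#' @param t Numeric vector of evaluation times (hours).
#' @param cfg A [phenotype_config()].
#' @return Integer vector of 0/1 flags, one per element of `t`.
#' @export
rolling_bt_flag <- function(bt_events, t, cfg = phenotype_config()) {
  if (nrow(bt_events) > 0 && any(bt_events$units < 0)) {
    abort("negative transfusion units", class = "acuityssm_data_error")
  }
  vapply(t, function(ti) {
    if (nrow(bt_events) == 0) return(0L)
    inw <- bt_events$time_hours > ti - cfg$bt_window_hours &
      bt_events$time_hours <= ti
    as.integer(sum(bt_events$units[inw]) >= cfg$bt_unit_threshold)
  }, integer(1))
}

# TRUE iff the BT flag is 1 anywhere in [ws, we). The trailing sum only
# increases at event times and decreases as old events age out, so it
# suffices to evaluate the flag at ws and at every event time inside the
# window.
.bt_flag_in_window <- function(bt_events, ws, we, cfg) {
  if (nrow(bt_events) == 0) return(FALSE)
  cand <- c(ws, bt_events$time_hours[bt_events$time_hours >= ws &
                                       bt_events$time_hours < we])
  any(rolling_bt_flag(bt_events, cand, cfg) == 1L)
}

# Expand zero-length therapy intervals (one-time pushes) to their enclosing
# grid window so they mark that window unstable and can count as an onset.
.effective_intervals <- function(therapies, grid, cfg) {
  if (nrow(therapies) == 0) return(therapies)
  th <- therapies
  zl <- th$end_hours == th$start_hours
  if (any(zl)) {
    w <- cfg$window_hours
    ws <- pmax(0, floor(th$start_hours[zl] / w) * w)
    th$start_hours[zl] <- ws
    th$end_hours[zl] <- ws + w
  }
  th
}

#' Label acuity states for one stay
#'
#' A prediction window is `unstable` iff at least one MV/VP/CRRT interval
#' overlaps it or the massive-transfusion flag is raised anywhere inside it.
#' The final window carries the terminal state -- `deceased` when the stay
#' ends in death, else `discharge` -- overriding instability. All remaining
#' windows are `stable`.
#'
#' @param stay A list with tibbles `therapies`, `bt_events` and scalars
#'   `disposition` ("discharged_alive"/"deceased"), `disposition_time_hours`.
#' @param grid Window grid from [build_window_grid()].
#' @param cfg A [phenotype_config()].
#' @return Factor vector of states, levels `discharge < stable < unstable <
#'   deceased`, one per grid row.
#' @export
label_states <- function(stay, grid, cfg = phenotype_config()) {
  stopifnot(nrow(grid) > 0)
  th <- stay$therapies
  if (nrow(th) > 0) {
    if (any(th$start_hours < 0) ||
        any(th$start_hours > stay$disposition_time_hours)) {
      abort("therapy interval outside stay", class = "acuityssm_data_error")
    }
    th <- .effective_intervals(th, grid, cfg)
  }
  n <- nrow(grid)
  unstable <- logical(n)
  for (i in seq_len(n)) {
    ws <- grid$pred_start[i]; we <- grid$pred_end[i]
    if (nrow(th) > 0) {
      ov <- th$start_hours < we &
        (th$end_hours > ws | (th$end_hours == th$start_hours & th$start_hours >= ws))
      if (any(ov)) { unstable[i] <- TRUE; next }
    }
    if (.bt_flag_in_window(stay$bt_events, ws, we, cfg)) unstable[i] <- TRUE
  }
  states <- ifelse(unstable, "unstable", "stable")
  states[n] <- if (identical(stay$disposition, "deceased")) "deceased"
               else "discharge"
  factor(states, levels = ACUITY_LEVELS)
}

#' Transition labels from a state sequence
#'
#' For prediction window `t`, `stable_to_unstable = 1` iff the previous
#' window's state is `stable` and the current is `unstable`; symmetrically for
#' `unstable_to_stable`. The first prediction window has no predecessor and
#' both labels are `NA` (masked), not 0.
#'
#' @param states Factor/character vector of per-window states.
#' @return Tibble `stable_to_unstable`, `unstable_to_stable` (integer, NA on
#'   the first window).
#' @export
label_transitions <- function(states) {
  s <- as.character(states)
  n <- length(s)
  prev <- c(NA_character_, s[-n])
  tibble::tibble(
    stable_to_unstable = ifelse(is.na(prev), NA_integer_,
                                as.integer(prev == "stable" & s == "unstable")),
    unstable_to_stable = ifelse(is.na(prev), NA_integer_,
                                as.integer(prev == "unstable" & s == "stable"))
  )
}

# Was `therapy` active at any point during [a, b)?
.active_in <- function(th, a, b) {
  nrow(th) > 0 && any(th$start_hours < b &
                        (th$end_hours > a |
                           (th$end_hours == th$start_hours & th$start_hours >= a)))
}

#' Therapy-onset labels for one stay
#'
#' `mv_onset` (resp. `vp_onset`, `crrt_onset`) is 1 for prediction window `t`
#' iff an interval of that therapy starts inside the window and the therapy
#' was not active at any point during the preceding `window_hours` interval.
#' One-time pushes (zero-length intervals) count as starting in their
#' enclosing window. The massive-transfusion label has no onset head.
#'
#' @inheritParams label_states
#' @return Tibble `mv_onset`, `vp_onset`, `crrt_onset` (integer).
#' @export
label_onsets <- function(stay, grid, cfg = phenotype_config()) {
  th_all <- .effective_intervals(stay$therapies, grid, cfg)
  out <- list()
  for (nm in THERAPIES) {
    th <- th_all[th_all$therapy == nm, , drop = FALSE]
    raw <- stay$therapies[stay$therapies$therapy == nm, , drop = FALSE]
    on <- integer(nrow(grid))
    if (nrow(th) > 0) {
      for (i in seq_len(nrow(grid))) {
        ws <- grid$pred_start[i]; we <- grid$pred_end[i]
        starts_in <- any(th$start_hours >= ws & th$start_hours < we)
        if (starts_in && !.active_in(th, ws - cfg$window_hours, ws)) {
          on[i] <- 1L
        }
      }
    }
    out[[paste0(tolower(nm), "_onset")]] <- on
  }
  tibble::as_tibble(out)
}

#' Label every prediction window of a cohort
#'
#' Runs the full phenotyping pipeline -- admission filters (optional), window
#' grids, acuity states, transition labels, onset labels -- and returns one
#' row per prediction window with the nine binary outcome labels. The four
#' primary labels are one-hot; `stable` and `unstable` exclude terminal
#' windows, where `discharge`/`deceased` take over.
#'
#' @param cohort An `icu_cohort`.
#' @param cfg A [phenotype_config()].
#' @param apply_filters Apply [apply_cohort_filters()] first (default TRUE).
#' @return A tibble with columns `stay_id`, `window_index`, `obs_start`,
#'   `obs_end`, `pred_start`, `pred_end`, `state`, and labels `y_discharge`,
#'   `y_stable`, `y_unstable`, `y_deceased`, `y_stable_to_unstable`,
#'   `y_unstable_to_stable` (NA-masked on first windows), `y_mv_onset`,
#'   `y_vp_onset`, `y_crrt_onset`. Attribute `excluded` carries the filter
#'   table.
#' @export
label_windows <- function(cohort, cfg = phenotype_config(),
                          apply_filters = TRUE) {
  if (apply_filters) {
    flt <- apply_cohort_filters(cohort, cfg)
    keep <- flt$kept
  } else {
    flt <- list(kept = cohort$dispositions$stay_id,
                excluded = tibble::tibble(stay_id = character(),
                                          reason = character()))
    keep <- flt$kept
  }
  th_by <- split(cohort$therapies, cohort$therapies$stay_id)
  bt_by <- split(cohort$bt_events, cohort$bt_events$stay_id)
  empty_th <- cohort$therapies[0, c("therapy", "start_hours", "end_hours")]
  empty_bt <- cohort$bt_events[0, c("time_hours", "units")]
  dispo <- cohort$dispositions
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    sid <- keep[j]
    drow <- dispo[dispo$stay_id == sid, ]
    stay <- list(
      therapies = th_by[[sid]] %||% empty_th,
      bt_events = bt_by[[sid]] %||% empty_bt,
      disposition = drow$disposition,
      disposition_time_hours = drow$disposition_time_hours
    )
    grid <- suppressWarnings(build_window_grid(stay$disposition_time_hours, cfg))
    if (nrow(grid) == 0) next
    st <- label_states(stay, grid, cfg)
    tr <- label_transitions(st)
    on <- label_onsets(stay, grid, cfg)
    rows[[j]] <- dplyr::bind_cols(
      tibble::tibble(stay_id = sid), grid,
      tibble::tibble(
        state = st,
        y_discharge = as.integer(st == "discharge"),
        y_stable = as.integer(st == "stable"),
        y_unstable = as.integer(st == "unstable"),
        y_deceased = as.integer(st == "deceased"),
        y_stable_to_unstable = tr$stable_to_unstable,
        y_unstable_to_stable = tr$unstable_to_stable,
        y_mv_onset = on$mv_onset,
        y_vp_onset = on$vp_onset,
        y_crrt_onset = on$crrt_onset
      ))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- flt$excluded
  attr(out, "config") <- cfg
  out
}

#' Empirical acuity-state transition matrix
#'
#' Row-stochastic 2x4 matrix of the empirical probability of moving from the
#' current state (stable or unstable) to each of the four states in the next
#' window, pooled over all consecutive window pairs in the cohort.
#'
#' @param windows A labeled-window tibble from [label_windows()] (needs
#'   `stay_id`, `window_index`, `state`).
#' @return A 2x4 matrix, rows `stable`/`unstable`, columns
#'   `stable`/`unstable`/`discharge`/`deceased`; each row sums to 1.
#' @export
transition_matrix <- function(windows) {
  if (nrow(windows) == 0) abort("empty window table")
  cols <- c("stable", "unstable", "discharge", "deceased")
  w <- dplyr::arrange(windows, .data$stay_id, .data$window_index)
  s <- as.character(w$state)
  same <- w$stay_id == dplyr::lag(w$stay_id) &
    w$window_index == dplyr::lag(w$window_index) + 1L
  from <- dplyr::lag(s)[which(same)]
  to <- s[which(same)]
  ok <- from %in% c("stable", "unstable")
  from <- from[ok]; to <- to[ok]
  if (length(from) == 0) abort("no consecutive stable/unstable state pairs")
  m <- matrix(0, 2, 4, dimnames = list(c("stable", "unstable"), cols))
  tab <- table(factor(from, c("stable", "unstable")), factor(to, cols))
  m[] <- as.numeric(tab)
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}
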