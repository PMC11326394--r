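# Triplet encoding of irregular clinical event streams.
#
# Builds the variable vocabulary (rarity filter, first-appearance codes),
# removes outliers (hard physiologic bounds and 1st/99th percentile bounds
# fitted on the development cohort), min-max scales values and times, and
# encodes each observation window as a fixed-length padded sequence of
# (time, value, code) triplets. No value is ever imputed: padded positions
# are identifiable from the mask alone.

# Times (hours since admission) are scaled by a fixed horizon constant so the
# 30-day maximum stay maps to [0, 1]; the convention is invertible.
TIME_SCALE_HOURS <- 720

#' Build the variable vocabulary from a development cohort
#'
#' Variables occurring in fewer than `min_stay_fraction` of stays are removed
#' (the boundary is inclusive: a variable in exactly that fraction of stays is
#' retained). Integer codes are assigned by order of first appearance in the
#' event stream; code 0 is reserved for padding. Per-variable percentile
#' bounds (1st/99th by default) and, after outlier removal, min-max scaling
#' ranges are fitted on this cohort and frozen. Static fields get min-max
#' ranges the same way.
#'
#' @param events Event tibble (`stay_id`, `time_hours`, `variable`, `value`),
#'   ordered as the development stream (first appearance defines codes).
#' @param static Static tibble (`stay_id` + numeric fields); may be `NULL`.
#' @param min_stay_fraction Rarity threshold on the fraction of stays in
#'   which a variable must appear (default 0.05, inclusive).
#' @param hard_bounds Optional tibble (`variable`, `lo`, `hi`) of physiologic
#'   plausibility bounds; values outside are removed before the percentile
#'   fit.
#' @param p_lo,p_hi Percentile bounds for outlier removal (defaults 0.01 and
#'   0.99).
#' @return An object of class `acuity_vocab`.
#' @export
build_vocabulary <- function(events, static = NULL, min_stay_fraction = 0.05,
                             hard_bounds = NULL, p_lo = 0.01, p_hi = 0.99) {
  if (nrow(events) == 0) abort("empty cohort: no events")
  n_stays <- dplyr::n_distinct(events$stay_id)
  freq <- events |>
    dplyr::distinct(.data$stay_id, .data$variable) |>
    dplyr::count(.data$variable, name = "n_stays_with") |>
    dplyr::mutate(stay_fraction = .data$n_stays_with / n_stays)
  retained <- freq$variable[freq$stay_fraction >= min_stay_fraction]
  first_seen <- events$variable[!duplicated(events$variable)]
  ordered_vars <- first_seen[first_seen %in% retained]

  tab <- tibble::tibble(
    variable = ordered_vars,
    code = seq_along(ordered_vars),
    stay_fraction = freq$stay_fraction[match(ordered_vars, freq$variable)],
    hard_lo = -Inf, hard_hi = Inf
  )
  if (!is.null(hard_bounds)) {
    idx <- match(tab$variable, hard_bounds$variable)
    tab$hard_lo <- ifelse(is.na(idx), -Inf, hard_bounds$lo[idx])
    tab$hard_hi <- ifelse(is.na(idx), Inf, hard_bounds$hi[idx])
  }

  ev <- events[events$variable %in% tab$variable, ]
  hb <- tab[match(ev$variable, tab$variable), ]
  ev <- ev[ev$value >= hb$hard_lo & ev$value <= hb$hard_hi, ]
  pct <- ev |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(p_lo = quantile(.data$value, p_lo, names = FALSE),
                     p_hi = quantile(.data$value, p_hi, names = FALSE),
                     .groups = "drop")
  tab$p_lo <- pct$p_lo[match(tab$variable, pct$variable)]
  tab$p_hi <- pct$p_hi[match(tab$variable, pct$variable)]

  # scaling ranges on the outlier-cleaned development events
  ev2 <- ev[ev$value >= tab$p_lo[match(ev$variable, tab$variable)] &
              ev$value <= tab$p_hi[match(ev$variable, tab$variable)], ]
  rng <- ev2 |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(scale_min = min(.data$value),
                     scale_max = max(.data$value), .groups = "drop")
  tab$scale_min <- rng$scale_min[match(tab$variable, rng$variable)]
  tab$scale_max <- rng$scale_max[match(tab$variable, rng$variable)]
  tab$constant <- tab$scale_max <= tab$scale_min

  static_ranges <- NULL
  if (!is.null(static)) {
    fields <- setdiff(names(static), "stay_id")
    static_ranges <- tibble::tibble(
      field = fields,
      min = vapply(fields, function(f) min(static[[f]], na.rm = TRUE), 0),
      max = vapply(fields, function(f) max(static[[f]], na.rm = TRUE), 0)
    )
  }
  structure(list(table = tab, static_ranges = static_ranges,
                 time_scale = TIME_SCALE_HOURS,
                 min_stay_fraction = min_stay_fraction),
            class = "acuity_vocab")
}

#' @export
print.acuity_vocab <- function(x, ...) {
  cat("<acuity_vocab>", nrow(x$table), "variables (code 0 = padding)\n")
  invisible(x)
}

#' Remove rare-variable and outlier events
#'
#' Drops events of variables absent from the vocabulary, events outside the
#' hard physiologic bounds, and events outside the fitted percentile bounds
#' (bounds are inclusive: a value exactly at the 99th percentile is kept).
#' Removal counts per variable are attached as attribute `removed`.
#'
#' @param events Event tibble.
#' @param vocab An `acuity_vocab`.
#' @return Filtered event tibble.
#' @export
filter_outliers <- function(events, vocab) {
  tab <- vocab$table
  idx <- match(events$variable, tab$variable)
  known <- !is.na(idx)
  ok <- known
  ok[known] <- events$value[known] >= tab$hard_lo[idx[known]] &
    events$value[known] <= tab$hard_hi[idx[known]] &
    events$value[known] >= tab$p_lo[idx[known]] &
    events$value[known] <= tab$p_hi[idx[known]]
  out <- events[ok, ]
  removed <- events[!ok, ] |>
    dplyr::count(.data$variable, name = "n_removed")
  attr(out, "removed") <- removed
  out
}

#' Min-max scale events and static features
#'
#' Values map to `(value - min) / (max - min)` with the development-cohort
#' ranges, clipped to `[0, 1]` (so out-of-range validation values clip rather
#' than extrapolate); variables whose range collapsed to a point are flagged
#' constant and scaled to 0.5. Event times are divided by the fixed horizon
#' constant (720 h). Adds `code`, `time_scaled`, `value_scaled` columns.
#'
#' @param events Event tibble (after [filter_outliers()]).
#' @param vocab An `acuity_vocab`.
#' @return The events with encoding columns added.
#' @export
scale_events <- function(events, vocab) {
  tab <- vocab$table
  idx <- match(events$variable, tab$variable)
  if (anyNA(idx)) abort("events contain variables outside the vocabulary")
  den <- tab$scale_max[idx] - tab$scale_min[idx]
  v <- (events$value - tab$scale_min[idx]) / ifelse(den > 0, den, 1)
  v[tab$constant[idx]] <- 0.5
  dplyr::mutate(events,
                code = tab$code[idx],
                time_scaled = .data$time_hours / vocab$time_scale,
                value_scaled = pmin(1, pmax(0, v)))
}

#' @rdname scale_events
#' @param static Static tibble (`stay_id` + numeric fields).
#' @return `scale_static()`: a numeric matrix (one row per stay, rownames =
#'   stay_id) scaled to `[0, 1]`.
#' @export
scale_static <- function(static, vocab) {
  rngs <- vocab$static_ranges
  if (is.null(rngs)) abort("vocabulary has no static ranges")
  m <- matrix(0, nrow(static), nrow(rngs),
              dimnames = list(static$stay_id, rngs$field))
  for (j in seq_len(nrow(rngs))) {
    den <- rngs$max[j] - rngs$min[j]
    x <- (static[[rngs$field[j]]] - rngs$min[j]) / ifelse(den > 0, den, 1)
    if (den <= 0) x <- rep(0.5, length(x))
    m[, j] <- pmin(1, pmax(0, x))
  }
  m
}

#' Encode one observation window as a fixed-length triplet sequence
#'
#' Events are sorted by (scaled time, code) -- the deterministic resolution of
#' simultaneous events -- truncated to the `L` most recent when there are more
#' than `L`, and padded at the tail with zeros (mask 0, code 0). Nothing is
#' imputed.
#'
#' @param window_events Scaled events of one observation window (needs
#'   `time_scaled`, `value_scaled`, `code`).
#' @param L Maximum sequence length.
#' @return A list (`times`, `values`, `codes`, `mask`), each of length `L`;
#'   class `triplet_tensor`.
#' @export
encode_observation <- function(window_events, L) {
  ev <- window_events[order(window_events$time_scaled, window_events$code), ]
  n <- nrow(ev)
  if (n > L) ev <- ev[(n - L + 1L):n, ]
  n <- nrow(ev)
  pad <- L - n
  structure(list(
    times = c(ev$time_scaled, numeric(pad)),
    values = c(ev$value_scaled, numeric(pad)),
    codes = c(as.integer(ev$code), integer(pad)),
    mask = c(rep(1L, n), integer(pad)),
    L = L
  ), class = "triplet_tensor")
}

#' Invert a triplet encoding back to events
#'
#' Recovers the retained (unpadded) events of a [encode_observation()] tensor
#' on the original scales, using the vocabulary's ranges. Constant-range and
#' clipped values cannot be inverted exactly; all others invert to machine
#' precision.
#'
#' @param tensor A `triplet_tensor`.
#' @param vocab The `acuity_vocab` used for scaling.
#' @return Tibble `time_hours`, `variable`, `value`.
#' @export
decode_observation <- function(tensor, vocab) {
  keep <- tensor$mask == 1L
  tab <- vocab$table
  idx <- match(tensor$codes[keep], tab$code)
  tibble::tibble(
    time_hours = tensor$times[keep] * vocab$time_scale,
    variable = tab$variable[idx],
    value = tab$scale_min[idx] +
      tensor$values[keep] * (tab$scale_max[idx] - tab$scale_min[idx])
  )
}

#' Encode every labeled window of a cohort into batched triplet matrices
#'
#' Joins events to the observation window they fall in (half-open
#' `[obs_start, obs_end)`), applies the deterministic (time, code) sort and
#' most-recent-`L` truncation, and fills `N x L` matrices. Windows without a
#' single retained event are legal (all padding).
#'
#' @param events Scaled events ([scale_events()]).
#' @param windows Labeled windows ([label_windows()]).
#' @param vocab The `acuity_vocab`.
#' @param static Static tibble; scaled via [scale_static()].
#' @param L Maximum sequence length (default 256).
#' @return An `acuity_dataset`: list with `windows` (the labeled tibble),
#'   matrices `times`, `values`, `codes`, `mask` (N x L), `static` (N x f),
#'   `vocab`, `L`.
#' @export
encode_windows <- function(events, windows, vocab, static, L = 256L) {
  cfg_w <- windows$obs_end - windows$obs_start
  w <- max(cfg_w)
  key <- paste(windows$stay_id, windows$window_index)
  ev <- events |>
    dplyr::mutate(window_index = floor(.data$time_hours / w)) |>
    dplyr::mutate(row = match(paste(.data$stay_id, .data$window_index), key)) |>
    dplyr::filter(!is.na(.data$row)) |>
    dplyr::arrange(.data$row, .data$time_scaled, .data$code) |>
    dplyr::group_by(.data$row) |>
    dplyr::mutate(.n = dplyr::n(), .pos = dplyr::row_number()) |>
    dplyr::filter(.data$.pos > .data$.n - L) |>
    dplyr::mutate(slot = .data$.pos - pmax(0L, .data$.n - as.integer(L))) |>
    dplyr::ungroup()

  n <- nrow(windows)
  times <- matrix(0, n, L); values <- matrix(0, n, L)
  codes <- matrix(0L, n, L); mask <- matrix(0L, n, L)
  ij <- cbind(ev$row, ev$slot)
  times[ij] <- ev$time_scaled
  values[ij] <- ev$value_scaled
  codes[ij] <- as.integer(ev$code)
  mask[ij] <- 1L
  sm <- scale_static(static, vocab)
  srow <- match(windows$stay_id, rownames(sm))
  if (anyNA(srow)) abort("static table is missing stays present in windows")
  structure(list(windows = windows, times = times, values = values,
                 codes = codes, mask = mask,
                 static = sm[srow, , drop = FALSE],
                 vocab = vocab, L = as.integer(L)),
            class = "acuity_dataset")
}

#' @export
print.acuity_dataset <- function(x, ...) {
  cat("<acuity_dataset>", nrow(x$windows), "windows,",
      dplyr::n_distinct(x$windows$stay_id), "stays, L =", x$L,
      ", f =", ncol(x$static), "\n")
  invisible(x)
}

#' Serialize / restore a vocabulary as JSON
#'
#' @param vocab An `acuity_vocab`.
#' @param path File path.
#' @return `read_vocabulary()` returns the restored `acuity_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  tab <- vocab$table
  tab$hard_lo[!is.finite(tab$hard_lo)] <- NA
  tab$hard_hi[!is.finite(tab$hard_hi)] <- NA
  jsonlite::write_json(
    list(table = tab, static_ranges = vocab$static_ranges,
         time_scale = vocab$time_scale,
         min_stay_fraction = vocab$min_stay_fraction),
    path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::as_tibble(x$table)
  tab$hard_lo[is.na(tab$hard_lo)] <- -Inf
  tab$hard_hi[is.na(tab$hard_hi)] <- Inf
  structure(list(table = tab,
                 static_ranges = if (!is.null(x$static_ranges))
                   tibble::as_tibble(x$static_ranges) else NULL,
                 time_scale = x$time_scale,
                 min_stay_fraction = x$min_stay_fraction),
            class = "acuity_vocab")
}
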