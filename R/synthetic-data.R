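# Synthetic ICU cohort generator.
#
# Emulates the statistical shape of ICU event streams: irregularly sampled
# vitals/labs, static covariates, a latent deterioration process that drives
# initiation of life-sustaining therapies (MV, VP, CRRT, blood transfusion)
# and death, and a SOFA score series correlated with the latent risk.
# No attempt is made at realistic physiology beyond the planted signal.

# Catalogue of temporal variables: charting rate (events/hour), marginal
# distribution, hard physiologic bounds, and the direction in which the
# variable moves as a patient deteriorates.
.var_catalogue <- function(n_temporal_vars) {
  base <- tibble::tribble(
    ~variable,    ~mean, ~sd,  ~lo,  ~hi,  ~rate, ~direction,
    "hr",          85,    15,   20,   300,  1.0,   1,
    "rr",          18,     5,    4,    80,  1.0,   1,
    "sbp",        120,    20,   30,   300,  1.0,  -1,
    "dbp",         65,    12,   15,   200,  1.0,  -1,
    "temp",        37,   0.6,   30,    43,  0.5,   1,
    "spo2",        97,   2.5,   50,   100,  1.0,  -1,
    "gcs",         13,   2.5,    3,    15,  0.25, -1,
    "lactate",    1.8,   1.0,    0,    30,  0.15,  1,
    "sodium",     139,     4,  100,   180,  0.15,  0,
    "inr",        1.2,   0.4,  0.3,    12,  0.15,  1,
    "creatinine", 1.1,   0.6,    0,    25,  0.2,   1,
    "wbc",          9,   3.5,    0,   100,  0.2,   0
  )
  if (n_temporal_vars <= nrow(base)) return(base[seq_len(n_temporal_vars), ])
  extra <- tibble::tibble(
    variable = paste0("lab_", seq_len(n_temporal_vars - nrow(base))),
    mean = 10, sd = 3, lo = -50, hi = 150, rate = 0.15, direction = 0
  )
  dplyr::bind_rows(base, extra)
}

#' Parameters for the synthetic ICU cohort generator
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' plausible mixed ICU population: log-normal lengths of stay with median
#' `mean_los_hours` truncated to the 8-hour/30-day admission window, vitals
#' charted about hourly and labs a few times a day, roughly 6% ICU mortality
#' and MV/VP/CRRT therapy incidences of order 25/20/6% at unit hazard scales.
#'
#' @param n_stays Number of ICU stays to generate (>= 1).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the parameters including this seed.
#' @param mean_los_hours Median of the log-normal length-of-stay distribution,
#'   in hours.
#' @param los_sdlog Log-scale standard deviation of the length of stay.
#' @param truncate_los If `TRUE` (default) lengths of stay are redrawn until
#'   they fall in `[8, 720]` hours, so the whole cohort passes the
#'   length-of-stay admission filter; set `FALSE` to retain out-of-range stays
#'   (useful for exercising the filter).
#' @param n_temporal_vars Number of temporal variables; the first 12 are named
#'   clinical variables (six routine vitals plus common labs/scores), any
#'   excess are generic noise labs.
#' @param n_static_vars Number of binary comorbidity indicators appended to
#'   the four demographic fields (age, sex, race, BMI).
#' @param event_rate_per_hour Optional named numeric vector of per-variable
#'   charting rates (events/hour) overriding the catalogue defaults, or a
#'   single multiplier applied to all catalogue rates.
#' @param signal_strength Shift, in per-variable standard deviations per unit
#'   of latent risk, applied to the deteriorating variables. 0 decouples all
#'   measurements from the latent risk.
#' @param deteriorating_vars Character vector naming the variables whose
#'   values drift with latent risk (the "planted" predictive signal).
#' @param therapy_hazard_scale Multiplier on all therapy-initiation (and
#'   transfusion-burst) probabilities; 0 yields a therapy-free cohort.
#' @param mortality_hazard_scale Multiplier on the per-interval death hazard;
#'   0 yields an all-survivor cohort.
#' @param missingness Per-variable probability of discarding each generated
#'   event (scalar or named vector); 1 removes a variable entirely.
#' @param artifact_rate Probability that an event value is replaced by a gross
#'   recording artifact (value scaled by 10), to exercise outlier filtering.
#'
#' @return An object of class `synth_params`.
#' @seealso [simulate_cohort()]
#' @export
synth_params <- function(n_stays,
                         seed = 1L,
                         mean_los_hours = 48,
                         los_sdlog = 0.8,
                         truncate_los = TRUE,
                         n_temporal_vars = 12,
                         n_static_vars = 4,
                         event_rate_per_hour = NULL,
                         signal_strength = 1,
                         deteriorating_vars = c("hr", "rr", "sbp", "spo2",
                                                "gcs", "lactate"),
                         therapy_hazard_scale = 1,
                         mortality_hazard_scale = 1,
                         missingness = 0,
                         artifact_rate = 0.002) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg),
                   class = "acuityssm_parameter_error")
  }
  chk(is.numeric(n_stays) && length(n_stays) == 1 && n_stays >= 1,
      "n_stays", "must be a single number >= 1")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single finite number")
  chk(is.numeric(mean_los_hours) && mean_los_hours > 0,
      "mean_los_hours", "must be > 0")
  chk(is.numeric(los_sdlog) && los_sdlog > 0, "los_sdlog", "must be > 0")
  chk(n_temporal_vars >= 1, "n_temporal_vars", "must be >= 1")
  chk(n_static_vars >= 0, "n_static_vars", "must be >= 0")
  chk(is.numeric(signal_strength) && signal_strength >= 0,
      "signal_strength", "must be >= 0")
  chk(is.numeric(therapy_hazard_scale) && therapy_hazard_scale >= 0,
      "therapy_hazard_scale", "must be >= 0")
  chk(is.numeric(mortality_hazard_scale) && mortality_hazard_scale >= 0,
      "mortality_hazard_scale", "must be >= 0")
  chk(all(missingness >= 0) && all(missingness <= 1),
      "missingness", "probabilities must lie in [0, 1]")
  chk(is.numeric(artifact_rate) && artifact_rate >= 0 && artifact_rate <= 1,
      "artifact_rate", "must lie in [0, 1]")

  vars <- .var_catalogue(n_temporal_vars)
  if (!is.null(event_rate_per_hour)) {
    if (is.null(names(event_rate_per_hour))) {
      chk(length(event_rate_per_hour) == 1 && event_rate_per_hour > 0,
          "event_rate_per_hour", "unnamed value must be a single multiplier > 0")
      vars$rate <- vars$rate * event_rate_per_hour
    } else {
      chk(all(event_rate_per_hour > 0), "event_rate_per_hour",
          "all rates must be > 0")
      idx <- match(names(event_rate_per_hour), vars$variable)
      chk(!anyNA(idx), "event_rate_per_hour", "unknown variable name")
      vars$rate[idx] <- unname(event_rate_per_hour)
    }
  }
  miss <- rep(0, nrow(vars))
  if (length(missingness) == 1 && is.null(names(missingness))) {
    miss <- rep(missingness, nrow(vars))
  } else {
    idx <- match(names(missingness), vars$variable)
    chk(!anyNA(idx), "missingness", "unknown variable name")
    miss[idx] <- unname(missingness)
  }
  vars$missingness <- miss
  vars$deteriorating <- vars$variable %in% deteriorating_vars

  structure(
    list(
      n_stays = as.integer(n_stays), seed = as.integer(seed),
      mean_los_hours = mean_los_hours, los_sdlog = los_sdlog,
      truncate_los = truncate_los,
      n_temporal_vars = as.integer(n_temporal_vars),
      n_static_vars = as.integer(n_static_vars),
      signal_strength = signal_strength,
      therapy_hazard_scale = therapy_hazard_scale,
      mortality_hazard_scale = mortality_hazard_scale,
      artifact_rate = artifact_rate,
      variables = vars
    ),
    class = "synth_params"
  )
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params>", x$n_stays, "stays, seed", x$seed, "\n")
  cat("  median LOS", x$mean_los_hours, "h; signal strength",
      x$signal_strength, "\n")
  cat("  ", x$n_temporal_vars, "temporal vars (",
      sum(x$variables$deteriorating), " risk-linked), ",
      4 + x$n_static_vars, " static fields\n", sep = "")
  invisible(x)
}

# Hourly-knot latent risk walk: bounded random walk with a per-stay drift.
.simulate_risk <- function(los_hours) {
  n_knots <- ceiling(los_hours) + 1L
  r0 <- rbeta(1, 2, 6)
  u <- runif(1)
  drift <- if (u < 0.25) runif(1, 0.004, 0.03) else
    if (u < 0.40) -runif(1, 0.004, 0.02) else 0
  steps <- rnorm(n_knots - 1L, mean = drift, sd = 0.03)
  risk <- numeric(n_knots)
  risk[1L] <- r0
  for (i in seq_len(n_knots - 1L)) {  # clamp the walk at every step
    risk[i + 1L] <- min(1, max(0, risk[i] + steps[i]))
  }
  list(initial_risk = r0, drift = drift,
       knots = tibble::tibble(hour = seq_len(n_knots) - 1, risk = risk))
}

.risk_at <- function(knots, t) {
  stats::approx(knots$hour, knots$risk, xout = t, rule = 2)$y
}

#' Evaluate the latent deterioration trajectory of a synthetic stay
#'
#' The generator stores each stay's latent risk as hourly knots; the
#' trajectory is their piecewise-linear interpolation, bounded in `[0, 1]`.
#' This ground truth is a sidecar for diagnostics and tests only -- nothing in
#' the modelling pipeline consumes it.
#'
#' @param cohort An `icu_cohort` from [simulate_cohort()].
#' @param stay_id A single stay identifier present in the cohort.
#' @param t Numeric vector of times (hours since admission) within the stay.
#' @return Numeric vector of latent risks in `[0, 1]`.
#' @export
latent_risk <- function(cohort, stay_id, t) {
  stopifnot(inherits(cohort, "icu_cohort"))
  knots <- cohort$ground_truth_risk[cohort$ground_truth_risk$stay_id == stay_id, ]
  if (nrow(knots) == 0) abort(paste("unknown stay_id:", stay_id))
  dispo <- cohort$dispositions$disposition_time_hours[
    cohort$dispositions$stay_id == stay_id]
  if (any(t < 0 | t > dispo)) {
    abort("t outside the stay's [0, disposition_time] range",
          class = "acuityssm_range_error")
  }
  .risk_at(knots, t)
}

#' Sample irregular clinical events for one synthetic stay
#'
#' Each variable is charted as an independent Poisson process at its
#' per-variable rate, thinned by its missingness probability; values are the
#' variable's marginal distribution shifted along its deterioration direction
#' by `signal_strength` standard deviations per unit latent risk. Events of
#' different variables may share timestamps. Uses the current RNG state.
#'
#' @param risk_knots Tibble with columns `hour`, `risk` (the stay's latent
#'   trajectory).
#' @param los_hours Length of stay in hours; events fall in `[0, los_hours]`.
#' @param params A [synth_params()] object.
#' @return Tibble with columns `time_hours`, `variable`, `value`, sorted by
#'   time.
#' @export
sample_events <- function(risk_knots, los_hours, params) {
  stopifnot(inherits(params, "synth_params"))
  vars <- params$variables
  out <- vector("list", nrow(vars))
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    n <- rpois(1, v$rate * los_hours)
    if (n == 0) { out[[i]] <- NULL; next }
    tt <- sort(runif(n, 0, los_hours))
    keep <- if (v$missingness > 0) runif(n) >= v$missingness else rep(TRUE, n)
    tt <- tt[keep]
    if (length(tt) == 0) { out[[i]] <- NULL; next }
    shift <- if (v$deteriorating) {
      v$direction * params$signal_strength * .risk_at(risk_knots, tt)
    } else 0
    val <- v$mean + v$sd * (rnorm(length(tt)) + shift)
    if (v$variable == "gcs") val <- round(pmin(15, pmax(3, val)))
    if (v$variable == "spo2") val <- pmin(100, val)
    if (params$artifact_rate > 0) {
      art <- runif(length(tt)) < params$artifact_rate
      val[art] <- val[art] * 10
    }
    out[[i]] <- tibble::tibble(time_hours = tt, variable = v$variable,
                               value = val)
  }
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) {
    return(tibble::tibble(time_hours = numeric(), variable = character(),
                          value = numeric()))
  }
  dplyr::arrange(ev, .data$time_hours, .data$variable)
}

# Therapy initiation: per 4-h interval Bernoulli with a steep logistic link
# on the latent risk (therapies concentrate in high-risk periods); durations
# log-normal but weaned early once the patient's risk recovers below the
# weaning threshold; a fraction of VP initiations are zero-length one-time
# pushes.
.simulate_therapies <- function(risk_knots, los_hours, scale) {
  specs <- list(
    MV   = list(int = -8.6, slope = 10, med_dur = 24, sdlog = 0.7),
    VP   = list(int = -8.8, slope = 10, med_dur = 12, sdlog = 0.8),
    CRRT = list(int = -12.0, slope = 10, med_dur = 36, sdlog = 0.6)
  )
  wean_below <- 0.15
  wean_time <- function(t0) {
    # first hour >= t0 + 2 at which risk has recovered below the threshold
    kk <- risk_knots[risk_knots$hour >= t0 + 2 & risk_knots$risk < wean_below, ]
    if (nrow(kk) == 0) Inf else kk$hour[1]
  }
  rows <- list()
  starts <- seq(0, los_hours, by = 4)
  starts <- starts[starts < los_hours]
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    active_until <- -Inf
    for (ws in starts) {
      if (ws < active_until) next
      r <- .risk_at(risk_knots, ws)
      p <- min(1, scale * plogis(sp$int + sp$slope * r))
      if (runif(1) < p) {
        t0 <- ws + runif(1, 0, 2)
        if (t0 >= los_hours) next
        if (nm == "VP" && runif(1) < 0.15) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(therapy = nm, start_hours = t0, end_hours = t0)
          active_until <- t0
        } else {
          dur <- rlnorm(1, log(sp$med_dur), sp$sdlog)
          t1 <- min(t0 + dur, wean_time(t0), los_hours)
          rows[[length(rows) + 1L]] <-
            tibble::tibble(therapy = nm, start_hours = t0, end_hours = t1)
          active_until <- t1
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(therapy = character(), start_hours = numeric(),
                          end_hours = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$therapy, .data$start_hours)
}

.simulate_bt <- function(los_hours, scale) {
  p_burst <- min(1, 0.08 * scale)
  if (runif(1) >= p_burst) {
    return(tibble::tibble(time_hours = numeric(), units = numeric()))
  }
  n_bursts <- sample.int(2L, 1L)
  rows <- list()
  for (b in seq_len(n_bursts)) {
    t0 <- runif(1, 0, max(los_hours - 6, 0.5))
    n_units <- 5 + rpois(1, 8)
    tt <- sort(t0 + runif(n_units, 0, 6))
    tt <- tt[tt <= los_hours]
    if (length(tt)) {
      rows[[b]] <- tibble::tibble(time_hours = tt, units = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(time_hours = numeric(), units = numeric()))
  }
  dplyr::arrange(out, .data$time_hours)
}

.simulate_static <- function(n_static_vars) {
  out <- list(
    age = min(95, max(18, round(rnorm(1, 62, 16)))),
    sex = rbinom(1, 1, 0.45),
    race = sample(0:2, 1, prob = c(0.65, 0.2, 0.15)),
    bmi = min(60, max(12, rnorm(1, 28, 6)))
  )
  if (n_static_vars > 0) {
    for (i in seq_len(n_static_vars)) {
      out[[paste0("comorb_", i)]] <- rbinom(1, 1, 0.25)
    }
  }
  tibble::as_tibble(out)
}

#' Generate a seeded synthetic ICU cohort
#'
#' Simulates `n_stays` ICU admissions. Each stay has a latent deterioration
#' trajectory (bounded hourly random walk with per-stay drift); the
#' trajectory drives the per-interval initiation probability of MV/VP/CRRT,
#' transfusion bursts, the discrete-time death hazard, the synthetic SOFA
#' series, and (through `signal_strength`) the values of the deteriorating
#' vitals. The trajectory itself is returned as a sidecar ground-truth table
#' that no downstream pipeline stage consumes.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `icu_cohort`: a list of tibbles
#'   `events` (stay_id, time_hours, variable, value),
#'   `static` (stay_id, age, sex, race, bmi, comorb_*),
#'   `therapies` (stay_id, therapy, start_hours, end_hours),
#'   `bt_events` (stay_id, time_hours, units),
#'   `dispositions` (stay_id, disposition, disposition_time_hours),
#'   `sofa` (stay_id, time_hours, sofa),
#'   plus ground-truth sidecars `ground_truth_risk` (stay_id, hour, risk) and
#'   `ground_truth_stay` (stay_id, initial_risk, drift), and the `params`.
#' @examples
#' coh <- simulate_cohort(synth_params(5, seed = 42))
#' coh$dispositions
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- params$n_stays
  acc <- list(events = list(), static = list(), therapies = list(),
              bt = list(), dispo = list(), sofa = list(), risk = list(),
              stay = list())
  for (i in seq_len(n)) {
    sid <- sprintf("stay_%05d", i)
    los <- rlnorm(1, log(params$mean_los_hours), params$los_sdlog)
    if (params$truncate_los) {
      while (los < 8 || los > 720) {
        los <- rlnorm(1, log(params$mean_los_hours), params$los_sdlog)
      }
    }
    rk <- .simulate_risk(los)

    # discrete-time death hazard over 4-h intervals
    dispo <- "discharged_alive"; t_end <- los
    starts <- seq(0, los, by = 4); starts <- starts[starts < los]
    for (ws in starts) {
      rbar <- .risk_at(rk$knots, min(ws + 2, los))
      p_death <- min(1, params$mortality_hazard_scale * plogis(-9.5 + 6 * rbar))
      if (runif(1) < p_death) {
        dispo <- "deceased"
        t_end <- min(ws + runif(1, 0.5, 4), los)
        break
      }
    }
    rk$knots <- rk$knots[rk$knots$hour <= ceiling(t_end), ]

    ev <- sample_events(rk$knots, t_end, params)
    th <- .simulate_therapies(rk$knots, t_end, params$therapy_hazard_scale)
    bt <- .simulate_bt(t_end, params$therapy_hazard_scale)
    st <- .simulate_static(params$n_static_vars)

    sofa_t <- seq(0, t_end, by = 4)
    sofa_v <- pmin(24, pmax(0, round(
      18 * .risk_at(rk$knots, sofa_t) + rnorm(length(sofa_t), 0, 1.2))))

    acc$events[[i]] <- dplyr::mutate(ev, stay_id = sid, .before = 1)
    acc$static[[i]] <- dplyr::mutate(st, stay_id = sid, .before = 1)
    acc$therapies[[i]] <- dplyr::mutate(th, stay_id = sid, .before = 1)
    acc$bt[[i]] <- dplyr::mutate(bt, stay_id = sid, .before = 1)
    acc$dispo[[i]] <- tibble::tibble(stay_id = sid, disposition = dispo,
                                     disposition_time_hours = t_end)
    acc$sofa[[i]] <- tibble::tibble(stay_id = sid, time_hours = sofa_t,
                                    sofa = sofa_v)
    acc$risk[[i]] <- dplyr::mutate(rk$knots, stay_id = sid, .before = 1)
    acc$stay[[i]] <- tibble::tibble(stay_id = sid,
                                    initial_risk = rk$initial_risk,
                                    drift = rk$drift)
  }
  structure(
    list(
      events = dplyr::bind_rows(acc$events),
      static = dplyr::bind_rows(acc$static),
      therapies = dplyr::bind_rows(acc$therapies),
      bt_events = dplyr::bind_rows(acc$bt),
      dispositions = dplyr::bind_rows(acc$dispo),
      sofa = dplyr::bind_rows(acc$sofa),
      ground_truth_risk = dplyr::bind_rows(acc$risk),
      ground_truth_stay = dplyr::bind_rows(acc$stay),
      params = params
    ),
    class = "icu_cohort"
  )
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort>", nrow(x$dispositions), "stays,",
      nrow(x$events), "events\n")
  cat("  deceased:", sum(x$dispositions$disposition == "deceased"),
      "| therapy intervals:", nrow(x$therapies),
      "| BT units:", nrow(x$bt_events), "\n")
  invisible(x)
}

#' Write or read a cohort as plain CSV tables
#'
#' Writes the six data tables plus the two ground-truth sidecars as CSV files
#' with fixed names under `dir`. `read_cohort()` reads them back; the params
#' object is not round-tripped.
#'
#' @param cohort An `icu_cohort`.
#' @param dir Directory (created if missing).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` an
#'   `icu_cohort` (with `params = NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in .cohort_tables) {
    write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

.cohort_tables <- c("events", "static", "therapies", "bt_events",
                    "dispositions", "sofa", "ground_truth_risk",
                    "ground_truth_stay")

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- lapply(.cohort_tables, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) abort(paste("missing cohort table:", f))
    tibble::as_tibble(read.csv(f, stringsAsFactors = FALSE))
  })
  names(out) <- .cohort_tables
  out$params <- NULL
  structure(out, class = "icu_cohort")
}
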