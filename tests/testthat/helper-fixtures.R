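# Shared fixtures: hand-constructed stays, tiny model configs, and an
# independent brute-force re-derivation of the phenotype labels used as an
# oracle in several tests.

# a stay list as consumed by label_states()/label_onsets()
make_stay <- function(los, dispo = "discharged_alive",
                      therapies = NULL, bt = NULL) {
  list(
    therapies = therapies %||% tibble::tibble(
      therapy = character(), start_hours = numeric(), end_hours = numeric()),
    bt_events = bt %||% tibble::tibble(
      time_hours = numeric(), units = numeric()),
    disposition = dispo,
    disposition_time_hours = los
  )
}

tiny_model_cfg <- function(...) {
  model_config(L = 12, D = 8, n_blocks = 2, state_dim = 4, k = 3, f = 3,
               conv_kernel = 3, expand = 2, dt_rank = 2, mlp_hidden = 6,
               seed = 5, epochs = 2, batch_size = 8, ...)
}

random_batch <- function(cfg, N = 5, T_len = 9, n_codes = 6, seed = 1,
                         pad_tail = TRUE) {
  set.seed(seed)
  mask <- matrix(1L, N, T_len)
  if (pad_tail) {
    for (n in seq_len(N)) {
      k <- sample(0:(T_len - 2), 1)
      if (k > 0) mask[n, (T_len - k + 1):T_len] <- 0L
    }
  }
  codes <- matrix(sample(seq_len(n_codes), N * T_len, TRUE), N, T_len) * mask
  list(times = matrix(runif(N * T_len, 0, 0.3), N, T_len) * mask,
       values = matrix(runif(N * T_len), N, T_len) * mask,
       codes = codes,
       mask = mask,
       static = matrix(runif(N * cfg$f), N, cfg$f))
}

# Independent brute-force phenotype oracle: per-window therapy-overlap and
# BT checks recomputed directly from raw intervals with plain loops, states,
# transitions and onsets re-derived from first principles.
oracle_label_stay <- function(stay, cfg) {
  w <- cfg$window_hours
  los <- stay$disposition_time_hours
  starts <- seq(w, los, by = w)
  starts <- starts[starts < los]
  ends <- pmin(starts + w, los)
  n <- length(starts)
  th <- stay$therapies
  # expand zero-length (push) intervals to their enclosing window
  if (nrow(th) > 0) {
    for (i in seq_len(nrow(th))) {
      if (th$end_hours[i] == th$start_hours[i]) {
        ws <- floor(th$start_hours[i] / w) * w
        th$start_hours[i] <- ws
        th$end_hours[i] <- ws + w
      }
    }
  }
  overlaps <- function(a, b, s, e) s < b && e > a
  bt_flag_at <- function(t) {
    s <- sum(stay$bt_events$units[stay$bt_events$time_hours > t - cfg$bt_window_hours &
                                    stay$bt_events$time_hours <= t])
    s >= cfg$bt_unit_threshold
  }
  unstable <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(th))) {
      if (overlaps(starts[i], ends[i], th$start_hours[j], th$end_hours[j])) {
        unstable[i] <- TRUE
      }
    }
    if (!unstable[i] && nrow(stay$bt_events) > 0) {
      cand <- c(starts[i],
                stay$bt_events$time_hours[stay$bt_events$time_hours >= starts[i] &
                                            stay$bt_events$time_hours < ends[i]])
      for (tt in cand) if (bt_flag_at(tt)) unstable[i] <- TRUE
    }
  }
  states <- ifelse(unstable, "unstable", "stable")
  states[n] <- if (stay$disposition == "deceased") "deceased" else "discharge"
  s2u <- u2s <- rep(NA_integer_, n)
  if (n > 1) {
    for (i in 2:n) {
      s2u[i] <- as.integer(states[i - 1] == "stable" & states[i] == "unstable")
      u2s[i] <- as.integer(states[i - 1] == "unstable" & states[i] == "stable")
    }
  }
  onsets <- matrix(0L, n, 3, dimnames = list(NULL, c("MV", "VP", "CRRT")))
  for (nm in colnames(onsets)) {
    tt <- th[th$therapy == nm, , drop = FALSE]
    if (nrow(tt) == 0) next
    for (i in seq_len(n)) {
      starts_in <- any(tt$start_hours >= starts[i] & tt$start_hours < ends[i])
      active_prev <- FALSE
      for (j in seq_len(nrow(tt))) {
        if (overlaps(starts[i] - w, starts[i], tt$start_hours[j],
                     tt$end_hours[j])) active_prev <- TRUE
      }
      if (starts_in && !active_prev) onsets[i, nm] <- 1L
    }
  }
  list(states = states, s2u = s2u, u2s = u2s, onsets = onsets)
}
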