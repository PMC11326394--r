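test_that("window grid tiles the stay with half-open windows", {
  cfg <- phenotype_config()
  g <- build_window_grid(16, cfg)
  expect_equal(g$pred_start, c(4, 8, 12))
  expect_equal(g$pred_end, c(8, 12, 16))
  expect_equal(g$obs_start, c(0, 4, 8))
  expect_equal(g$obs_end, g$pred_start)
  # minimum stay: exactly one prediction window
  g8 <- build_window_grid(8, cfg)
  expect_equal(nrow(g8), 1L)
  expect_equal(c(g8$pred_start, g8$pred_end), c(4, 8))
  # partial final window is kept and shorter
  g14 <- build_window_grid(14, cfg)
  expect_equal(g14$pred_end, c(8, 12, 14))
  # too-short stay: empty grid with warning + flag
  expect_warning(g4 <- build_window_grid(7, cfg))
  expect_equal(nrow(g4), 0L)
  expect_true(attr(g4, "too_short"))
})

test_that("events map to observation windows by the half-open convention", {
  # an event at exactly t = 8 belongs to the window starting at 8 ([8,12)),
  # i.e. the observation window of prediction window index 2
  cfg <- phenotype_config()
  expect_identical(floor(8.0 / cfg$window_hours), 2)
  expect_identical(floor(7.9999 / cfg$window_hours), 1)
})

test_that("cohort filters exclude by LOS, missing vitals and missing statics", {
  coh <- simulate_cohort(synth_params(6, seed = 2))
  # force specific defects
  coh$dispositions$disposition_time_hours[1] <- 7.9
  coh$dispositions$disposition_time_hours[2] <- 31 * 24
  sid3 <- coh$dispositions$stay_id[3]
  coh$events <- coh$events[!(coh$events$stay_id == sid3 &
                               coh$events$variable == "spo2"), ]
  sid4 <- coh$dispositions$stay_id[4]
  coh$static$bmi[coh$static$stay_id == sid4] <- NA
  flt <- apply_cohort_filters(coh)
  ex <- flt$excluded
  expect_equal(ex$reason[ex$stay_id == coh$dispositions$stay_id[1]],
               "los_below_min")
  expect_equal(ex$reason[ex$stay_id == coh$dispositions$stay_id[2]],
               "los_above_max")
  expect_equal(ex$reason[ex$stay_id == sid3], "missing_vital_spo2")
  expect_equal(ex$reason[ex$stay_id == sid4], "missing_static_bmi")
  expect_setdiff <- setdiff(coh$dispositions$stay_id, c(ex$stay_id, flt$kept))
  expect_length(expect_setdiff, 0)
})

test_that("rolling BT flag matches its definition", {
  cfg <- phenotype_config()
  bt10 <- tibble::tibble(time_hours = 1:10, units = rep(1, 10))
  expect_identical(rolling_bt_flag(bt10, 12, cfg), 1L)
  bt0 <- tibble::tibble(time_hours = rep(0, 10), units = rep(1, 10))
  expect_identical(rolling_bt_flag(bt0, 25, cfg), 0L)   # aged out of 24 h
  # the trailing window is half-open (t-24, t]: events at exactly t-24 are out
  expect_identical(rolling_bt_flag(bt0, 24, cfg), 0L)
  expect_identical(rolling_bt_flag(bt0, 23.9, cfg), 1L)
  expect_error(rolling_bt_flag(tibble::tibble(time_hours = 1, units = -2),
                               5, cfg),
               class = "acuityssm_data_error")
})

test_that("rolling BT flag equals a brute-force trailing sum on random draws", {
  cfg <- phenotype_config()
  set.seed(31)
  for (i in 1:400) {
    n <- sample(0:25, 1)
    bt <- tibble::tibble(time_hours = sort(runif(n, 0, 72)),
                         units = sample(1:3, n, TRUE))
    tt <- runif(25, 0, 80)
    brute <- vapply(tt, function(ti) {
      as.integer(sum(bt$units[bt$time_hours > ti - 24 &
                                bt$time_hours <= ti]) >= 10)
    }, integer(1))
    expect_identical(rolling_bt_flag(bt, tt, cfg), brute)
  }
})

test_that("state labeling follows therapy overlap and terminal override", {
  cfg <- phenotype_config()
  g12 <- build_window_grid(12, cfg)
  # no therapies, discharged: stable until terminal discharge
  s <- label_states(make_stay(12), g12, cfg)
  expect_equal(as.character(s), c("stable", "discharge"))
  s16 <- label_states(make_stay(16), build_window_grid(16, cfg), cfg)
  expect_equal(as.character(s16), c("stable", "stable", "discharge"))
  # MV on [5, 9) overlaps windows [4,8) and [8,12)
  mv <- tibble::tibble(therapy = "MV", start_hours = 5, end_hours = 9)
  g16 <- build_window_grid(16, cfg)
  s2 <- label_states(make_stay(16, therapies = mv), g16, cfg)
  expect_equal(as.character(s2), c("unstable", "unstable", "discharge"))
  # VP active at death: terminal window deceased, earlier overlap unstable
  vp <- tibble::tibble(therapy = "VP", start_hours = 5, end_hours = 16)
  s3 <- label_states(make_stay(16, dispo = "deceased", therapies = vp),
                     g16, cfg)
  expect_equal(as.character(s3), c("unstable", "unstable", "deceased"))
  # zero-length VP push marks its enclosing window
  push <- tibble::tibble(therapy = "VP", start_hours = 9.5, end_hours = 9.5)
  s4 <- label_states(make_stay(16, therapies = push), g16, cfg)
  expect_equal(as.character(s4), c("stable", "unstable", "discharge"))
  # interval outside the stay is a data error
  bad <- tibble::tibble(therapy = "MV", start_hours = 20, end_hours = 24)
  expect_error(label_states(make_stay(16, therapies = bad), g16, cfg),
               class = "acuityssm_data_error")
})

test_that("transition labels are masked on the first window", {
  tr <- label_transitions(c("stable", "unstable", "unstable"))
  expect_equal(tr$stable_to_unstable, c(NA, 1L, 0L))
  tr2 <- label_transitions(c("unstable", "stable"))
  expect_equal(tr2$unstable_to_stable, c(NA, 1L))
  tr3 <- label_transitions(rep("stable", 4))
  expect_true(all(tr3$stable_to_unstable[-1] == 0L))
  expect_true(all(tr3$unstable_to_stable[-1] == 0L))
})

test_that("onset labels require a start in-window and prior inactivity", {
  cfg <- phenotype_config()
  g <- build_window_grid(16, cfg)
  mv9 <- tibble::tibble(therapy = "MV", start_hours = 9, end_hours = 14)
  on <- label_onsets(make_stay(16, therapies = mv9), g, cfg)
  expect_equal(on$mv_onset, c(0L, 1L, 0L))
  # continuous VP from admission: never newly initiated
  vp_all <- tibble::tibble(therapy = "VP", start_hours = 0, end_hours = 16)
  on2 <- label_onsets(make_stay(16, therapies = vp_all), g, cfg)
  expect_true(all(on2$vp_onset == 0L))
  # two disjoint CRRT intervals separated by > 1 window: two onsets
  crrt <- tibble::tibble(therapy = "CRRT", start_hours = c(4.5, 20.5),
                         end_hours = c(6, 22))
  g24 <- build_window_grid(26, cfg)
  on3 <- label_onsets(make_stay(26, therapies = crrt), g24, cfg)
  expect_equal(sum(on3$crrt_onset), 2L)
  expect_equal(which(on3$crrt_onset == 1L), c(1L, 5L))
})

test_that("label pipeline equals the brute-force oracle on synthetic stays", {
  coh <- simulate_cohort(synth_params(60, seed = 14))
  cfg <- phenotype_config()
  win <- label_windows(coh, cfg)
  for (sid in unique(win$stay_id)) {
    drow <- coh$dispositions[coh$dispositions$stay_id == sid, ]
    stay <- make_stay(drow$disposition_time_hours, drow$disposition,
                      therapies = coh$therapies[coh$therapies$stay_id == sid,
                                                c("therapy", "start_hours",
                                                  "end_hours")],
                      bt = coh$bt_events[coh$bt_events$stay_id == sid,
                                         c("time_hours", "units")])
    orc <- oracle_label_stay(stay, cfg)
    w <- win[win$stay_id == sid, ]
    expect_identical(as.character(w$state), orc$states)
    expect_identical(w$y_stable_to_unstable, orc$s2u)
    expect_identical(w$y_unstable_to_stable, orc$u2s)
    expect_identical(w$y_mv_onset, unname(orc$onsets[, "MV"]))
    expect_identical(w$y_vp_onset, unname(orc$onsets[, "VP"]))
    expect_identical(w$y_crrt_onset, unname(orc$onsets[, "CRRT"]))
  }
})

test_that("exactly one primary state per window; terminal states only last", {
  coh <- simulate_cohort(synth_params(80, seed = 15))
  win <- label_windows(coh)
  one_hot <- win$y_discharge + win$y_stable + win$y_unstable + win$y_deceased
  expect_true(all(one_hot == 1L))
  last <- !duplicated(win$stay_id, fromLast = TRUE)
  expect_true(all(win$state[last] %in% c("discharge", "deceased")))
  expect_false(any(win$state[!last] %in% c("discharge", "deceased")))
  first <- !duplicated(win$stay_id)
  expect_true(all(is.na(win$y_stable_to_unstable[first])))
  expect_true(all(!is.na(win$y_stable_to_unstable[!first])))
})

test_that("transition matrix is row-stochastic and recovers hand counts", {
  # constructed cohort: 8 stable->stable, 2 stable->unstable
  states <- c(rep(c("stable", "stable"), 8), rep(c("stable", "unstable"), 2))
  win <- tibble::tibble(
    stay_id = rep(sprintf("s%02d", 1:10), each = 2),
    window_index = rep(0:1, 10),
    state = states)
  m <- transition_matrix(win)
  expect_equal(unname(m["stable", ]), c(0.8, 0.2, 0, 0))
  coh <- simulate_cohort(synth_params(50, seed = 16))
  m2 <- transition_matrix(label_windows(coh))
  expect_lt(max(abs(rowSums(m2) - 1)), 1e-12)
  expect_error(transition_matrix(win[0, ]))
})
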