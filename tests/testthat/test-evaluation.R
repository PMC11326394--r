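test_that("AUROC: perfect ranking, tie convention, concordance oracle", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(runif(4), rep(1, 4)), "single-class")
  set.seed(51)
  for (i in 1:5) {
    p <- round(runif(200), 2)   # ties included
    y <- rbinom(200, 1, 0.3)
    conc <- 0
    pos <- p[y == 1]; neg <- p[y == 0]
    for (a in pos) for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(auroc(p, y), conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC: perfect ranking gives 1, step integration is stable", {
  expect_equal(auprc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # all-tied scores: single point at (recall 1, precision = base rate)
  expect_equal(auprc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(auprc(runif(4), rep(0, 4)), "single-class")
})

test_that("step metrics compute the six quantities at a threshold", {
  m <- step_metrics(c(0.1, 0.6, 0.7, 0.2), c(0, 1, 1, 0), threshold = 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  expect_equal(m$auroc, 1)
})

test_that("episode scores use the pre-onset maximum and exclusions", {
  # absent outcome: max over all windows
  es <- episode_scores(c(0.1, 0.2, 0.15), c(0, 0, 0), rep("a", 3))
  expect_equal(es$episode_score, 0.2)
  expect_equal(es$outcome_present, 0L)
  # onset at window 3: max of the first two
  es2 <- episode_scores(c(0.1, 0.6, 0.9, 0.95), c(0, 0, 1, 1), rep("b", 4))
  expect_equal(es2$episode_score, 0.6)
  expect_equal(es2$onset_window, 3L)
  # onset in the first window: excluded with a logged reason
  es3 <- episode_scores(c(0.9, 0.1), c(1, 0), rep("c", 2))
  expect_equal(nrow(es3), 0L)
  expect_equal(attr(es3, "excluded"), "c")
})

test_that("episode AUROC equals an independently built per-stay-max table", {
  set.seed(52)
  n_stay <- 40
  d <- purrr::map_dfr(seq_len(n_stay), function(i) {
    k <- sample(3:10, 1)
    y <- rep(0L, k)
    if (runif(1) < 0.4) {
      onset <- sample(2:k, 1)
      y[onset:k] <- 1L
    }
    tibble::tibble(stay_id = sprintf("s%02d", i), p = runif(k), y = y)
  })
  es <- episode_scores(d$p, d$y, d$stay_id)
  # oracle: tapply-built per-stay table
  oracle <- purrr::map_dfr(split(d, d$stay_id), function(dd) {
    onset <- which(dd$y == 1)[1]
    if (!is.na(onset)) {
      if (onset == 1) return(NULL)
      tibble::tibble(present = 1L, score = max(dd$p[seq_len(onset - 1)]))
    } else {
      tibble::tibble(present = 0L, score = max(dd$p))
    }
  })
  expect_identical(auroc(es$episode_score, es$outcome_present),
                   auroc(oracle$score, oracle$present))
  expect_identical(auprc(es$episode_score, es$outcome_present),
                   auprc(oracle$score, oracle$present))
  # every detected episode has at least one detected pre-onset step
  thr <- 0.5
  detected <- es$stay_id[es$outcome_present == 1 & es$episode_score >= thr]
  for (sid in detected) {
    dd <- d[d$stay_id == sid, ]
    onset <- which(dd$y == 1)[1]
    expect_true(any(dd$p[seq_len(onset - 1)] >= thr))
  }
})

test_that("precision-targeted threshold is the smallest achieving the PPV", {
  ep <- tibble::tibble(stay_id = letters[1:6], outcome_present = c(1, 1, 0, 0, 0, 0),
                       episode_score = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                       onset_window = c(2L, 2L, NA, NA, NA, NA))
  r <- precision_targeted_threshold(ep, 0.33)
  # sweep oracle: smallest observed score with PPV >= 1/3
  cand <- sort(unique(ep$episode_score))
  ppv <- vapply(cand, function(th) {
    a <- ep$episode_score >= th
    sum(ep$outcome_present[a]) / sum(a)
  }, numeric(1))
  expect_equal(r$threshold, cand[which(ppv >= 0.33)[1]])
  expect_gte(r$ppv, 0.33)
  # perfectly separated: sensitivity 1 at target
  ep2 <- ep; ep2$outcome_present <- c(1, 1, 1, 0, 0, 0)
  r2 <- precision_targeted_threshold(ep2, 0.33)
  expect_equal(r2$sensitivity, 1)
  # all-negative: unattainable
  ep3 <- ep; ep3$outcome_present <- rep(0, 6)
  expect_true(is.na(precision_targeted_threshold(ep3, 0.33)$threshold))
})

test_that("lead time and alert counts follow the window arithmetic", {
  # alerts at windows 1,2 (0-based within-stay positions 2,3 1-based),
  # onset at 1-based window 3: first alert one window earlier -> 4 h lead
  r <- lead_time_and_alerts(c(0.1, 0.6, 0.7), threshold = 0.5,
                            onset_window = 3, window_hours = 4)
  expect_equal(r$lead_hours, 4)
  expect_equal(r$n_alerts, 1L)
  r2 <- lead_time_and_alerts(c(0.6, 0.7, 0.9, 0.1), 0.5, 4)
  expect_equal(r2$lead_hours, 12)
  expect_equal(r2$n_alerts, 3L)
  r3 <- lead_time_and_alerts(c(0.1, 0.2, 0.9), 0.5, 3)
  expect_true(is.na(r3$lead_hours))
  expect_equal(r3$n_alerts, 0L)
})

test_that("bootstrap CI resamples stays, is seeded, covers the truth", {
  d <- tibble::tibble(stay_id = rep(sprintf("s%02d", 1:30), each = 4),
                      x = rnorm(120))
  f <- function(dd) mean(dd$x)
  a <- bootstrap_ci(f, d, n_boot = 50, seed = 9)
  b <- bootstrap_ci(f, d, n_boot = 50, seed = 9)
  expect_identical(a, b)
  expect_lte(a$lo, a$median); expect_lte(a$median, a$hi)
  # constant metric: zero-width CI
  cc <- bootstrap_ci(function(dd) 0.7, d, n_boot = 20, seed = 1)
  expect_equal(cc$lo, cc$hi)
  # coverage of the mean of N(0,1), modest replicate count
  set.seed(53)
  cover <- 0; reps <- 60
  for (r in seq_len(reps)) {
    dd <- tibble::tibble(stay_id = sprintf("t%03d", 1:200), x = rnorm(200))
    ci <- bootstrap_ci(f, dd, n_boot = 100, seed = r)
    cover <- cover + (ci$lo <= 0 && 0 <= ci$hi)
  }
  expect_gte(cover / reps, 0.85)
})

test_that("rank-sum model comparison is symmetric and enumerably exact", {
  a <- 1:10; b <- 11:20
  p <- compare_models(a, b)
  expect_equal(p, compare_models(b, a))
  # exact two-sided p for complete separation: 2 / choose(20, 10)
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  # identical samples: p at its maximum
  expect_gt(compare_models(c(1, 2, 3), c(1, 2, 3)), 0.99)
})

test_that("evaluate_head produces coherent step and episode rows", {
  set.seed(54)
  d <- purrr::map_dfr(1:25, function(i) {
    k <- sample(4:8, 1)
    risk <- runif(1)
    y <- rep(0L, k)
    if (risk > 0.5 && k > 2) y[(k - 1):k] <- 1L
    tibble::tibble(stay_id = sprintf("s%02d", i),
                   p = pmin(1, pmax(0, risk + rnorm(k, 0, 0.2))), y = y)
  })
  rep <- evaluate_head(d$p, d$y, d$stay_id, threshold = 0.5, n_boot = 20,
                       seed = 2)
  expect_setequal(unique(rep$level), c("step", "episode"))
  expect_true(all(rep$lo <= rep$estimate & rep$estimate <= rep$hi))
  expect_true(all(rep$estimate >= 0 & rep$estimate <= 1))
})
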