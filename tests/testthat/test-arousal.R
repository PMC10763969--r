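test_that("time asleep at a minute follows the causal sleep rule", {
  tr <- activity_trace("f1", rep(0L, 60))
  expect_identical(time_asleep_at(tr, 10L), 10L)
  # run of 4 before t is below the rule
  tr2 <- activity_trace("f1", c(1L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_true(is.na(time_asleep_at(tr2, 5L)))
  # the minute itself is not counted
  tr3 <- activity_trace("f1", c(0L, 0L, 0L, 0L, 0L, 0L))
  expect_identical(time_asleep_at(tr3, 5L), 5L)
  expect_true(is.na(time_asleep_at(tr3, 0L)))
  expect_error(time_asleep_at(tr3, 6L), "t must satisfy")
  expect_error(time_asleep_at(tr3, -1L), "t must satisfy")
})

test_that("time asleep agrees with a backwards-scan oracle", {
  set.seed(31)
  for (rep in 1:50) {
    tr <- random_trace(200L, p_active = stats::runif(1, 0.2, 0.8))
    for (t in sample(0:199, 25)) {
      expect_identical(time_asleep_at(tr, t),
                       oracle_time_asleep(tr$counts, t))
    }
  }
})

test_that("escalating assays score threshold as first responding level", {
  tr <- activity_trace("f1", c(rep(0L, 20), 1L))
  mk <- function(int, resp, lat) {
    stimulus_events("f1", 10L, "escalating", int, resp, lat)
  }
  # first response at 0.3 g out of 1.2 g max -> 0.25
  ev <- mk(c(0.3, 0.6), c(TRUE, FALSE), c(5, NA))
  rec <- threshold_from_assay(ev, tr)
  expect_true(rec$asleep_at_stimulus)
  expect_identical(rec$time_asleep_min, 10L)
  expect_equal(rec$threshold_prop, 0.25)
  # no response at any level -> censored
  ev2 <- mk(c(0.3, 0.6, 0.9, 1.2), rep(FALSE, 4), NA)
  rec2 <- threshold_from_assay(ev2, tr)
  expect_true(rec2$censored)
  expect_true(is.na(rec2$threshold_prop))
  # late response (outside the 15 s window) does not count
  ev3 <- mk(c(0.3, 0.6), c(TRUE, TRUE), c(20, 5))
  expect_equal(threshold_from_assay(ev3, tr)$threshold_prop, 0.5)
  # a 0 g sham response cannot define a threshold
  ev4 <- mk(c(0, 0.3), c(TRUE, TRUE), c(1, 2))
  expect_equal(threshold_from_assay(ev4, tr)$threshold_prop, 0.25)
  # awake fly (just moved): no threshold
  tr_awake <- activity_trace("f1", c(rep(0L, 20), 1L, 1L))
  ev5 <- stimulus_events("f1", 21L, "escalating", 0.3, TRUE, 1)
  rec5 <- threshold_from_assay(ev5, tr_awake)
  expect_false(rec5$asleep_at_stimulus)
  expect_true(is.na(rec5$threshold_prop))
  # duplicated intensity bypassing the sorted constructor is rejected
  ev6 <- data.frame(fly_id = "f1", zt_min = 10L, protocol = "escalating",
                    intensity_g = c(0.3, 0.3), responded = FALSE,
                    latency_s = NA_real_)
  expect_error(threshold_from_assay(ev6, tr), "strictly increasing")
})

test_that("threshold scoring is invariant to events after the first response", {
  set.seed(32)
  tr <- activity_trace("f1", c(rep(0L, 30), 1L))
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    resp <- rep(FALSE, 4); resp[k] <- TRUE
    lat <- ifelse(resp, stats::runif(4, 0, 15), NA)
    ev <- stimulus_events("f1", 20L, "escalating",
                          c(0.3, 0.6, 0.9, 1.2), resp, lat)
    full <- threshold_from_assay(ev, tr)
    truncated <- threshold_from_assay(ev[1:k, ], tr)
    expect_equal(full$threshold_prop, truncated$threshold_prop)
    expect_equal(full$threshold_prop, c(0.25, 0.5, 0.75, 1)[k])
  }
})

test_that("per-fly mean threshold respects the censoring policy", {
  tr <- activity_trace("f1", rep(0L, 1440))
  recs <- rbind(
    threshold_from_assay(
      stimulus_events("f1", 60L, "escalating", 0.6, TRUE, 2), tr),
    threshold_from_assay(
      stimulus_events("f1", 120L, "escalating", c(0.3, 0.6, 0.9, 1.2),
                      c(FALSE, FALSE, FALSE, TRUE), c(NA, NA, NA, 9)), tr),
    threshold_from_assay(
      stimulus_events("f1", 180L, "escalating", c(0.3, 0.6, 0.9, 1.2),
                      rep(FALSE, 4), NA), tr))
  m <- mean_threshold(recs, phase = "day")
  expect_equal(m$mean_threshold, mean(c(0.5, 1.0)))  # censored excluded
  expect_equal(m$censored_fraction, 1 / 3)
  m2 <- mean_threshold(recs, phase = "day", censored = "assign_max")
  expect_equal(m2$mean_threshold, mean(c(0.5, 1.0, 1.0)))
  # single record
  m3 <- mean_threshold(recs[1, ], phase = "day")
  expect_equal(m3$mean_threshold, 0.5)
})

test_that("rising thresholds produce higher night means than flat ones", {
  presets <- genotype_presets()
  rising <- presets$control_like
  flat <- fly_params(p_doze_day = rising$p_doze_day,
                     p_doze_night = rising$p_doze_night,
                     p_wake_day = rising$p_wake_day,
                     p_wake_night = rising$p_wake_night,
                     theta0 = rising$theta0, beta_theta = 0,
                     sigma_resp = rising$sigma_resp)
  mean_of <- function(params, off) {
    vals <- vapply(1:40, function(i) {
      tr <- simulate_activity(params, seed = off + i,
                              fly_id = sprintf("f%d", i))
      st <- simulate_stimuli(tr, params, "escalating", seed = off + 500 + i)
      m <- mean_threshold(score_arousal_assays(st$events, list(st$trace)),
                          phase = "night")
      m$mean_threshold
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  expect_gt(mean_of(rising, 6000), mean_of(flat, 7000))
})

test_that("reactivity tables keep only sleeping trials", {
  # always-active fly: nothing to score
  tr <- activity_trace("f1", rep(1L, 1440))
  ev <- stimulus_events("f1", c(60L, 120L), "fixed", 1.2, TRUE, 5)
  expect_identical(nrow(reactivity_table(ev, list(tr))), 0L)
  # 10-trial mixed fixture against hand-computed records
  counts <- rep(1L, 1440)
  counts[51:60] <- 0L    # 10 asleep before minute 60 (0-based)
  counts[171:180] <- 0L  # 10 asleep before minute 180
  counts[716:720] <- 0L  # 5 asleep before minute 720 (night stimulus)
  tr2 <- activity_trace("f2", counts)
  ev2 <- stimulus_events("f2", c(60L, 120L, 180L, 720L), "fixed", 1.2,
                         c(TRUE, TRUE, TRUE, TRUE), c(5, 5, 70, 30))
  tab <- reactivity_table(ev2, list(tr2))
  expect_identical(nrow(tab), 3L)  # minute 120 trial: fly awake
  expect_identical(tab$time_asleep_min, c(10L, 10L, 5L))
  expect_identical(tab$responded, c(TRUE, FALSE, TRUE))  # 70 s is too late
  expect_identical(tab$phase, c("day", "day", "night"))
})

test_that("reactivity curves bin trials and conserve pooled counts", {
  set.seed(44)
  n <- 400L
  tab <- data.frame(
    fly_id = "f1", genotype = "g", phase = "night", zt_min = 800L,
    time_asleep_min = sample(5:60, n, replace = TRUE),
    responded = stats::runif(n) < 0.6)
  cur <- reactivity_curve(tab)
  expect_identical(sum(cur$n_trials), n)
  expect_identical(sum(cur$n_responded), sum(tab$responded))
  # pooling bins then recomputing equals the weighted average
  occ <- cur[cur$n_trials > 0, ]
  expect_equal(sum(occ$reactivity_pct * occ$n_trials) / sum(occ$n_trials),
               100 * mean(tab$responded))
  # constant response probability: occupied bins near 60%
  se <- sqrt(0.6 * 0.4 / occ$n_trials) * 100
  expect_true(all(abs(occ$reactivity_pct - 60) <= 3 * se))
  # degenerate all/none cases
  tab$responded <- TRUE
  expect_true(all(reactivity_curve(tab)$reactivity_pct %in% c(100, NA)))
  tab$responded <- FALSE
  expect_true(all(reactivity_curve(tab)$reactivity_pct %in% c(0, NA)))
})

test_that("reactivity regression recovers constructed relationships", {
  # constant full response: flat line at 100
  tab <- data.frame(fly_id = "f1", genotype = "g", phase = "day",
                    zt_min = 60L, time_asleep_min = rep(5:30, 4),
                    responded = TRUE)
  fit <- reactivity_regression(tab)$fits$g
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 100)
  # noiseless linear decline in binned mode is recovered exactly
  bins <- data.frame(genotype = "g", phase = "night",
                     bin_lo_min = seq(5, 35, 5), bin_hi_min = seq(10, 40, 5),
                     n_trials = 10L, n_responded = 5L,
                     reactivity_pct = 90 - 1.5 * (seq(7.5, 37.5, 5)))
  fitb <- reactivity_regression(bins, unit = "bin")$fits$g
  expect_equal(fitb$slope, -1.5, tolerance = 1e-9)
  expect_equal(fitb$intercept, 90, tolerance = 1e-9)
  expect_error(reactivity_regression(tab[tab$time_asleep_min < 7, ]),
               "distinct")
})
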