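test_that("fly parameter validation rejects impossible models", {
  expect_error(fly_params(p_doze_day = 0), "strictly in")
  expect_error(fly_params(p_wake_night = 1), "strictly in")
  expect_error(fly_params(lambda_active = 0), "lambda_active")
  expect_error(fly_params(v_sleep0 = 2, v_wake = 1), "v_sleep0")
  expect_error(fly_params(floor_frac = 0), "floor_frac")
  expect_error(fly_params(beta_theta = -1), ">= 0")
})

test_that("activity simulation honours absorbing limits", {
  # near-zero doze probability: effectively no sleep is ever scored
  p_stay_awake <- fly_params(p_doze_day = 1e-9, p_doze_night = 1e-9,
                             p_wake_day = 0.5, p_wake_night = 0.5)
  tr <- simulate_activity(p_stay_awake, seed = 1)
  expect_identical(nrow(score_sleep(tr)), 0L)
  expect_true(all(tr$counts > 0L))
  # near-certain doze, near-zero wake: one long bout from minute 2 on
  p_sleepy <- fly_params(p_doze_day = 1 - 1e-9, p_doze_night = 1 - 1e-9,
                         p_wake_day = 1e-9, p_wake_night = 1e-9)
  tr2 <- simulate_activity(p_sleepy, seed = 1)
  b <- score_sleep(tr2)
  expect_identical(nrow(b), 1L)
  expect_identical(b$start_min, 1L)
  expect_identical(b$duration_min, 1439L)
})

test_that("activity simulation is deterministic and seed-sensitive", {
  p <- fly_params()
  t1 <- simulate_activity(p, seed = 7)
  t2 <- simulate_activity(p, seed = 7)
  t3 <- simulate_activity(p, seed = 8)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))
})

test_that("long-run active occupancy matches the stationary distribution", {
  p <- fly_params(p_doze_day = 0.05, p_doze_night = 0.05,
                  p_wake_day = 0.10, p_wake_night = 0.10)
  tr <- simulate_activity(p, days = 10, seed = 99)
  frac_active <- mean(tr$counts > 0L)
  expected <- 0.10 / (0.10 + 0.05)
  se <- sqrt(expected * (1 - expected) / (length(tr$counts) / 20))
  # conservative SE: autocorrelated chain, effective n reduced
  expect_lt(abs(frac_active - expected), 3 * se)
})

test_that("deterministic stimulus limits score as expected", {
  # threshold far below the lowest level, tiny scale: respond at level 1
  p <- fly_params(theta0 = 0.01, beta_theta = 0, sigma_resp = 1e-6,
                  p_doze_day = 0.9, p_doze_night = 0.9,
                  p_wake_day = 0.01, p_wake_night = 0.01)
  tr <- simulate_activity(p, seed = 3)
  st <- simulate_stimuli(tr, p, "escalating", seed = 4)
  recs <- score_arousal_assays(st$events, list(st$trace))
  asleep <- recs[recs$asleep_at_stimulus, ]
  expect_gt(nrow(asleep), 0L)
  expect_true(all(asleep$threshold_prop == 0.3 / 1.2))
  # threshold far above the highest level: everything censored
  p2 <- fly_params(theta0 = 50, beta_theta = 0, sigma_resp = 1e-6,
                   p_doze_day = 0.9, p_doze_night = 0.9,
                   p_wake_day = 0.01, p_wake_night = 0.01)
  tr2 <- simulate_activity(p2, seed = 3)
  st2 <- simulate_stimuli(tr2, p2, "escalating", seed = 4)
  recs2 <- score_arousal_assays(st2$events, list(st2$trace))
  expect_true(all(recs2$censored[recs2$asleep_at_stimulus]))
})

test_that("escalating threshold matches brute-force outcome enumeration", {
  # expected scored threshold proportion under the logistic response model
  p <- fly_params(p_doze_day = 0.9, p_doze_night = 0.9,
                  p_wake_day = 0.005, p_wake_night = 0.005,
                  theta0 = 0.5, beta_theta = 0, sigma_resp = 0.2)
  levels <- c(0.3, 0.6, 0.9, 1.2)
  pr <- stats::plogis((levels - 0.5) / 0.2)
  none <- cumprod(1 - pr)
  p_first <- pr * c(1, none[-4])            # P(first response at level j)
  expected <- sum(p_first * levels / 1.2) / sum(p_first)
  vals <- unlist(lapply(1:30, function(i) {
    tr <- simulate_activity(p, seed = 500 + i)
    st <- simulate_stimuli(tr, p, "escalating", seed = 900 + i)
    recs <- score_arousal_assays(st$events, list(st$trace))
    recs$threshold_prop[recs$asleep_at_stimulus & !recs$censored]
  }))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("VCO2 simulation honours its deterministic limits", {
  # noiseless, always awake
  p <- fly_params(p_doze_day = 1e-9, p_doze_night = 1e-9,
                  p_wake_day = 0.5, p_wake_night = 0.5,
                  delta = 0, cv_noise = 0, v_wake = 1.3, v_sleep0 = 0.6)
  tr <- simulate_activity(p, seed = 11)
  mt <- simulate_vco2(tr, p, seed = 12)
  expect_equal(mt$vco2, rep(1.3, 288))
  # noiseless, asleep from minute 2, delta = 0: first bin mixes one active
  # minute, later bins sit at v_sleep0
  p2 <- fly_params(p_doze_day = 1 - 1e-9, p_doze_night = 1 - 1e-9,
                   p_wake_day = 1e-9, p_wake_night = 1e-9,
                   delta = 0, cv_noise = 0, v_wake = 1.3, v_sleep0 = 0.6)
  tr2 <- simulate_activity(p2, seed = 11)
  mt2 <- simulate_vco2(tr2, p2, seed = 12)
  expect_equal(mt2$vco2[-1], rep(0.6, 287))
  expect_equal(mt2$vco2[1], 1.3 / 5 + 4 * 0.6 / 5)
  # the decline respects its floor
  p3 <- fly_params(p_doze_day = 1 - 1e-9, p_doze_night = 1 - 1e-9,
                   p_wake_day = 1e-9, p_wake_night = 1e-9,
                   delta = 0.01, floor_frac = 0.5, cv_noise = 0)
  mt3 <- simulate_vco2(simulate_activity(p3, seed = 11), p3, seed = 12)
  expect_gt(min(mt3$vco2), 0.5 * 0.8 - 1e-9)
  expect_equal(min(mt3$vco2[100:288]), 0.5 * 0.8)
})

test_that("genotype presets encode the intended contrasts", {
  pre <- genotype_presets()
  expect_gt(pre$nf1_like$p_wake_night, pre$control_like$p_wake_night)
  expect_gt(pre$nf1_like$lambda_active, pre$control_like$lambda_active)
  expect_gt(pre$nf1_like$v_wake, pre$control_like$v_wake)
  expect_identical(pre$nf1_like$beta_theta, 0)
  expect_identical(pre$nf1_like$delta, 0)
  expect_gt(pre$control_like$beta_theta, 0)
  expect_gt(pre$control_like$delta, 0)
  # scored night sleep: mutant-like cohort sleeps less (seeded, n = 30)
  night_sleep <- function(params, off) {
    vapply(1:30, function(i) {
      tr <- simulate_activity(params, seed = off + i)
      m <- sleep_metrics(tr, score_sleep(tr))
      m$total_sleep_min[m$phase == "night"]
    }, numeric(1))
  }
  expect_lt(mean(night_sleep(pre$nf1_like, 2000)),
            mean(night_sleep(pre$control_like, 3000)))
})

test_that("cohort simulation is reproducible and complete", {
  cfg <- cohort_config(n_flies = 2L, days = 1L, seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- simulate_cohort(cfg, d1)
  out2 <- simulate_cohort(cfg, d2)
  for (f in basename(out1$files)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # expected artifacts exist
  expect_true(all(c("stimuli_escalating.csv", "stimuli_fixed.csv",
                    "vco2.csv", "truth.csv", "config.yaml") %in%
                    basename(out1$files)))
  expect_identical(nrow(out1$truth), 4L)
  # adding a fly leaves existing flies untouched
  cfg3 <- cohort_config(n_flies = 3L, days = 1L, seed = 42L)
  out3 <- simulate_cohort(cfg3)
  expect_identical(out3$flies$control_like_001$trace$counts,
                   out1$flies$control_like_001$trace$counts)
  expect_identical(out3$flies$control_like_002$mtrace$vco2,
                   out1$flies$control_like_002$mtrace$vco2)
  expect_error(cohort_config(n_flies = 0L), "n_flies")
})

test_that("a full pipeline run on a small cohort emits all reports", {
  cfg <- cohort_config(n_flies = 4L, days = 1L, seed = 5L)
  co <- simulate_cohort(cfg)
  traces <- lapply(co$flies, `[[`, "trace")
  mets <- do.call(rbind, lapply(traces, function(tr)
    sleep_metrics(tr, score_sleep(tr))))
  expect_identical(nrow(mets), 16L)
  tps <- do.call(rbind, lapply(traces, transition_probs))
  expect_identical(nrow(tps), 16L)
  recs <- do.call(rbind, lapply(co$flies, function(f)
    score_arousal_assays(f$esc_events, list(f$esc_trace))))
  expect_true(any(recs$asleep_at_stimulus))
  tab <- do.call(rbind, lapply(co$flies, function(f)
    reactivity_table(f$fix_events, list(f$fix_trace))))
  expect_gt(nrow(tab), 0L)
  curve <- reactivity_curve(tab)
  expect_identical(sum(curve$n_trials), nrow(tab))
  pts <- do.call(rbind, lapply(co$flies, function(f) {
    ps <- bout_profiles(score_sleep(f$trace), f$mtrace)
    rbind(fly_pct_change_by_time(ps, "day"),
          fly_pct_change_by_time(ps, "night"))
  }))
  expect_gt(nrow(pts), 0L)
})
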