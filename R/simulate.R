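#' Generative parameters for one fly
#'
#' Parameterizes the documented generative model behind the synthetic
#' cohorts: a phase-dependent two-state (active/inactive) Markov chain at
#' 1-minute resolution with zero-truncated Poisson beam-cross emission
#' while active; a logistic arousal-response model whose threshold rises
#' with time asleep; and a VCO2 process that is lower during sleep and
#' declines proportionally with time-in-bout down to a floor.
#'
#' @param p_doze_day,p_doze_night Per-minute probability of an active
#'   minute being followed by an inactive one, per phase, in (0, 1).
#' @param p_wake_day,p_wake_night Per-minute probability of an inactive
#'   minute being followed by an active one, per phase, in (0, 1).
#' @param lambda_active Mean of the (untruncated) Poisson beam-cross
#'   emission while active (> 0); emission is zero-truncated so active
#'   minutes always register.
#' @param theta0 Baseline arousal threshold in g (> 0).
#' @param beta_theta Threshold rise per minute asleep, g/min (>= 0).
#' @param sigma_resp Logistic response scale in g (> 0): a stimulus of
#'   intensity s wakes a fly with threshold theta with probability
#'   `plogis((s - theta) / sigma_resp)`.
#' @param v_wake VCO2 per 5-min bin while awake (> 0).
#' @param v_sleep0 VCO2 per 5-min bin at sleep onset (> 0, <= v_wake).
#' @param delta Proportional VCO2 decline per minute asleep (>= 0).
#' @param floor_frac Lower bound on the decline, as a fraction of
#'   `v_sleep0` (in (0, 1]).
#' @param cv_noise Coefficient of variation of multiplicative lognormal
#'   bin noise (>= 0).
#' @return An object of class `fly_params`.
#' @export
fly_params <- function(p_doze_day = 0.04, p_doze_night = 0.07,
                       p_wake_day = 0.04, p_wake_night = 0.02,
                       lambda_active = 2, theta0 = 0.30, beta_theta = 0.02,
                       sigma_resp = 0.15, v_wake = 1.0, v_sleep0 = 0.8,
                       delta = 0.01, floor_frac = 0.5, cv_noise = 0.05) {
  p <- list(p_doze_day = p_doze_day, p_doze_night = p_doze_night,
            p_wake_day = p_wake_day, p_wake_night = p_wake_night,
            lambda_active = lambda_active, theta0 = theta0,
            beta_theta = beta_theta, sigma_resp = sigma_resp,
            v_wake = v_wake, v_sleep0 = v_sleep0, delta = delta,
            floor_frac = floor_frac, cv_noise = cv_noise)
  probs <- unlist(p[c("p_doze_day", "p_doze_night",
                      "p_wake_day", "p_wake_night")])
  if (any(probs <= 0 | probs >= 1)) {
    stop("transition probabilities must lie strictly in (0, 1)")
  }
  if (lambda_active <= 0) stop("lambda_active must be > 0")
  if (theta0 <= 0 || sigma_resp <= 0) stop("theta0 and sigma_resp must be > 0")
  if (beta_theta < 0 || delta < 0 || cv_noise < 0) {
    stop("beta_theta, delta and cv_noise must be >= 0")
  }
  if (v_wake <= 0 || v_sleep0 <= 0 || v_sleep0 > v_wake) {
    stop("need 0 < v_sleep0 <= v_wake")
  }
  if (floor_frac <= 0 || floor_frac > 1) stop("floor_frac must be in (0, 1]")
  structure(p, class = "fly_params")
}

#' Control-like and Nf1-like parameter presets
#'
#' Invented preset parameterizations emulating the qualitative genotype
#' contrasts of short-sleeping, hyperactive, metabolically elevated mutant
#' flies against consolidated-sleeping controls: the mutant-like preset has
#' a higher waking propensity (fragmented, shorter sleep), higher waking
#' activity, a lower and *flat* arousal threshold (no deepening with time
#' asleep), elevated VCO2, and no sleep-dependent metabolic decline. The
#' numbers are documented modelling choices, not measured values.
#'
#' @return Named list of two [fly_params()] objects: `control_like`,
#'   `nf1_like`.
#' @export
genotype_presets <- function() {
  list(
    control_like = fly_params(
      p_doze_day = 0.04, p_doze_night = 0.07,
      p_wake_day = 0.04, p_wake_night = 0.02,
      lambda_active = 2, theta0 = 0.30, beta_theta = 0.02,
      sigma_resp = 0.15, v_wake = 1.0, v_sleep0 = 0.8,
      delta = 0.01, floor_frac = 0.5, cv_noise = 0.05),
    nf1_like = fly_params(
      p_doze_day = 0.03, p_doze_night = 0.05,
      p_wake_day = 0.08, p_wake_night = 0.08,
      lambda_active = 3, theta0 = 0.20, beta_theta = 0,
      sigma_resp = 0.15, v_wake = 1.4, v_sleep0 = 1.2,
      delta = 0, floor_frac = 0.5, cv_noise = 0.05)
  )
}

# derive a per-fly, per-substream seed below 2^31 from a cohort seed
substream_seed <- function(seed, fly_index, stream) {
  (as.numeric(seed) + 104729 * as.numeric(fly_index) + 7919 * stream) %%
    2147483647
}

#' Simulate a per-minute activity trace
#'
#' Runs the two-state Markov chain of the generative model: the initial
#' minute is active; an active minute is followed by an inactive one with
#' probability `p_doze(phase)`, an inactive minute by an active one with
#' probability `p_wake(phase)`, where the phase is that of the earlier
#' minute of the pair. Active minutes emit zero-truncated Poisson counts;
#' inactive minutes emit 0, so the latent state is exactly recoverable from
#' the counts.
#'
#' @param params A [fly_params()] object.
#' @param days Recording length in days (>= 1).
#' @param seed Integer seed; the trace is a deterministic function of
#'   (`params`, `days`, `seed`).
#' @param fly_id,genotype,zt0_offset_min Passed to [activity_trace()].
#' @return An [activity_trace()].
#' @export
simulate_activity <- function(params, days = 1L, seed = 1L, fly_id = "sim1",
                              genotype = "unknown", zt0_offset_min = 0L) {
  stopifnot(inherits(params, "fly_params"), days >= 1L)
  n <- as.integer(days * 1440L)
  set.seed(seed)
  u <- stats::runif(n)
  day_phase <- ((zt0_offset_min + seq_len(n) - 1L) %% 1440L) < 720L
  pd <- ifelse(day_phase, params$p_doze_day, params$p_doze_night)
  pw <- ifelse(day_phase, params$p_wake_day, params$p_wake_night)
  active <- logical(n)
  active[1L] <- TRUE
  for (t in 2:n) {
    active[t] <- if (active[t - 1L]) u[t] >= pd[t - 1L] else u[t] < pw[t - 1L]
  }
  counts <- integer(n)
  na <- sum(active)
  if (na > 0L) {
    p0 <- stats::dpois(0L, params$lambda_active)
    u2 <- stats::runif(na)
    counts[active] <- stats::qpois(p0 + u2 * (1 - p0), params$lambda_active)
  }
  activity_trace(fly_id, counts, zt0_offset_min = zt0_offset_min,
                 genotype = genotype)
}

#' Default stimulus protocol settings
#'
#' Hourly assays starting at ZT0; the escalating staircase runs 0.3 to
#' 1.2 g in 0.3 g steps with a 15 s response window, reactivity uses a
#' single 1.2 g stimulus with a 60 s window.
#'
#' @param levels_g Escalating intensities (strictly increasing, > 0).
#' @param max_g Fixed-protocol (and maximal) intensity.
#' @param escalating_window_s,fixed_window_s Response windows in seconds.
#' @param every_min Assay spacing in minutes (default hourly).
#' @return A list of protocol settings.
#' @export
stimulus_protocol <- function(levels_g = c(0.3, 0.6, 0.9, 1.2), max_g = 1.2,
                              escalating_window_s = 15, fixed_window_s = 60,
                              every_min = 60L) {
  if (any(diff(levels_g) <= 0) || any(levels_g <= 0)) {
    stop("levels_g must be strictly increasing and positive")
  }
  list(levels_g = levels_g, max_g = max_g,
       escalating_window_s = escalating_window_s,
       fixed_window_s = fixed_window_s, every_min = as.integer(every_min))
}

#' Simulate mechanical-stimulus assays on a trace
#'
#' Delivers assays at regular times along the trace. At each assay the
#' fly's time asleep k is read off the trace (zero run ending at the assay
#' minute); its momentary threshold is `theta0 + beta_theta * k` (just
#' `theta0` when awake) and it responds to a stimulus of intensity s with
#' probability `plogis((s - theta) / sigma_resp)`. Escalating assays stop
#' at the first response. Responding flies are set active for the minute
#' after the assay (toggleable), truncating any ongoing sleep bout as the
#' tracking system would observe.
#'
#' @param trace An [activity_trace()] (typically from
#'   [simulate_activity()]).
#' @param params The fly's [fly_params()].
#' @param protocol `"escalating"` or `"fixed"`.
#' @param settings A [stimulus_protocol()] list.
#' @param seed Integer seed.
#' @param wake_on_response Add a beam cross at the minute after a response
#'   (default TRUE).
#' @return List with `events` (a stimulus-event `data.frame`) and `trace`
#'   (the possibly modified trace).
#' @export
simulate_stimuli <- function(trace, params, protocol = c("escalating", "fixed"),
                             settings = stimulus_protocol(), seed = 1L,
                             wake_on_response = TRUE) {
  stopifnot(inherits(trace, "activity_trace"), inherits(params, "fly_params"))
  protocol <- match.arg(protocol)
  set.seed(seed)
  n <- length(trace$counts)
  # first assay at the first ZT-hour boundary inside the recording
  first <- (settings$every_min - trace$zt0_offset_min %% settings$every_min) %%
    settings$every_min
  times <- seq.int(first, n - 1L, by = settings$every_min)
  counts <- trace$counts
  acc_zt <- integer(0); acc_int <- numeric(0)
  acc_resp <- logical(0); acc_lat <- numeric(0)
  for (j in seq_along(times)) {
    t <- times[j]
    z <- 0L
    i <- t
    while (i >= 1L && counts[i] == 0L) { z <- z + 1L; i <- i - 1L }
    asleep <- z >= 5L
    theta <- params$theta0 + if (asleep) params$beta_theta * z else 0
    zt <- trace$zt0_offset_min + t
    if (protocol == "escalating") {
      lev <- settings$levels_g
      win <- settings$escalating_window_s
      resp <- stats::runif(length(lev)) <
        stats::plogis((lev - theta) / params$sigma_resp)
      k <- if (any(resp)) which(resp)[1] else length(lev) + 1L
      used <- seq_len(min(k, length(lev)))
      responded <- used == k
      lat <- ifelse(responded, stats::runif(length(used), 0, win), NA_real_)
      acc_zt <- c(acc_zt, rep(zt, length(used)))
      acc_int <- c(acc_int, lev[used])
      acc_resp <- c(acc_resp, responded)
      acc_lat <- c(acc_lat, lat)
      hit <- any(responded)
    } else {
      win <- settings$fixed_window_s
      hit <- stats::runif(1L) <
        stats::plogis((settings$max_g - theta) / params$sigma_resp)
      acc_zt <- c(acc_zt, zt)
      acc_int <- c(acc_int, settings$max_g)
      acc_resp <- c(acc_resp, hit)
      acc_lat <- c(acc_lat, if (hit) stats::runif(1L, 0, win) else NA_real_)
    }
    if (wake_on_response && hit && t + 2L <= n) {
      counts[t + 2L] <- counts[t + 2L] + 1L   # active at minute t + 1 (0-based)
    }
  }
  events <- data.frame(
    fly_id = rep(trace$fly_id, length(acc_zt)), zt_min = acc_zt,
    protocol = rep(protocol, length(acc_zt)), intensity_g = acc_int,
    responded = acc_resp, latency_s = acc_lat, stringsAsFactors = FALSE)
  out_trace <- activity_trace(trace$fly_id, counts,
                              zt0_offset_min = trace$zt0_offset_min,
                              genotype = trace$genotype)
  list(events = events, trace = out_trace)
}

#' Simulate a VCO2 trace paired with an activity trace
#'
#' The per-minute CO2 rate is `v_wake / 5` while the fly is (latently)
#' active and `(v_sleep0 / 5) * max(1 - delta * t, floor_frac)` when it has
#' been inactive for t minutes (t = 0 at the first inactive minute). Bin
#' values are the sum over each 5-minute bin times multiplicative lognormal
#' noise with coefficient of variation `cv_noise` (mean 1).
#'
#' @param trace An [activity_trace()] whose zero minutes are the latent
#'   inactive state (true of [simulate_activity()] output).
#' @param params A [fly_params()].
#' @param seed Integer seed.
#' @param bin_min Bin width in minutes, default 5.
#' @return A [metabolic_trace()] with the same ZT anchor as `trace`.
#' @export
simulate_vco2 <- function(trace, params, seed = 1L, bin_min = 5L) {
  stopifnot(inherits(trace, "activity_trace"), inherits(params, "fly_params"))
  set.seed(seed)
  n <- length(trace$counts)
  n_bins <- n %/% bin_min
  if (n_bins < 1L) stop("trace shorter than one bin")
  tib <- zero_runlen(trace$counts) - 1L       # time-in-bout, -1 when active
  asleep <- tib >= 0L
  rate <- ifelse(asleep,
                 (params$v_sleep0 / 5) *
                   pmax(1 - params$delta * tib, params$floor_frac),
                 params$v_wake / 5)
  used <- rate[seq_len(n_bins * bin_min)]
  v <- colSums(matrix(used, nrow = bin_min))
  if (params$cv_noise > 0) {
    sdl <- sqrt(log(1 + params$cv_noise^2))
    v <- v * stats::rlnorm(n_bins, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  metabolic_trace(trace$fly_id, v, bin_min = bin_min,
                  zt0_offset_min = trace$zt0_offset_min)
}

#' Cohort configuration
#'
#' @param n_flies Flies per genotype (>= 1).
#' @param days Recording length in days.
#' @param seed Master integer seed; all per-fly randomness is derived from
#'   it through independent substreams, so a fixed seed gives
#'   byte-identical outputs and adding a fly does not perturb existing
#'   flies.
#' @param genotypes Named list of [fly_params()] (default
#'   [genotype_presets()]).
#' @param protocol A [stimulus_protocol()] list.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_flies = 30L, days = 1L, seed = 1L,
                          genotypes = genotype_presets(),
                          protocol = stimulus_protocol()) {
  if (n_flies < 1L) stop("n_flies must be >= 1")
  if (days < 1L) stop("days must be >= 1")
  if (is.null(names(genotypes)) || !all(nzchar(names(genotypes)))) {
    stop("genotypes must be a named list of fly_params")
  }
  stopifnot(all(vapply(genotypes, inherits, logical(1), "fly_params")))
  structure(list(n_flies = as.integer(n_flies), days = as.integer(days),
                 seed = as.integer(seed), genotypes = genotypes,
                 protocol = protocol),
            class = "cohort_config")
}

#' Simulate a complete synthetic experiment
#'
#' Generates, per fly, an unstimulated activity recording with its paired
#' VCO2 trace (the calorimetry arm), and separate stimulated recordings for
#' the escalating and fixed stimulus arms (each arm re-simulates the
#' stimuli on an independent copy of the fly's behaviour, since stimulus
#' feedback alters the observed trace). When `out_dir` is given, writes
#' monitor files per arm (32 channels each), the two stimulus logs, the
#' VCO2 table, a `truth.csv` ground-truth sidecar (genotype and all
#' generative parameters per fly) and a `config.yaml` run description.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `flies` (per-fly traces, logs and
#'   mtraces), `truth` (data.frame), and `files` (paths written, or
#'   `NULL`).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  idx <- 0L
  flies <- list()
  truth <- list()
  for (gen in names(config$genotypes)) {
    params <- config$genotypes[[gen]]
    for (i in seq_len(config$n_flies)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", gen, i)
      tr <- simulate_activity(params, days = config$days,
                              seed = substream_seed(config$seed, idx, 0L),
                              fly_id = id, genotype = gen)
      esc_base <- simulate_activity(params, days = config$days,
                                    seed = substream_seed(config$seed, idx, 1L),
                                    fly_id = id, genotype = gen)
      esc <- simulate_stimuli(esc_base, params, "escalating",
                              settings = config$protocol,
                              seed = substream_seed(config$seed, idx, 2L))
      fix_base <- simulate_activity(params, days = config$days,
                                    seed = substream_seed(config$seed, idx, 3L),
                                    fly_id = id, genotype = gen)
      fix <- simulate_stimuli(fix_base, params, "fixed",
                              settings = config$protocol,
                              seed = substream_seed(config$seed, idx, 4L))
      mt <- simulate_vco2(tr, params,
                          seed = substream_seed(config$seed, idx, 5L))
      flies[[id]] <- list(trace = tr, esc_trace = esc$trace,
                          esc_events = esc$events, fix_trace = fix$trace,
                          fix_events = fix$events, mtrace = mt)
      truth[[id]] <- data.frame(fly_id = id, genotype = gen,
                                as.data.frame(unclass(params)),
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    write_arm <- function(traces, stem) {
      chunks <- split(traces, (seq_along(traces) - 1L) %/% 32L)
      vapply(seq_along(chunks), function(k) {
        p <- file.path(out_dir, sprintf("%s_%02d.txt", stem, k))
        write_dam_monitor(chunks[[k]], p)
        p
      }, character(1))
    }
    files <- c(files,
               write_arm(lapply(flies, `[[`, "trace"), "monitor_dam"),
               write_arm(lapply(flies, `[[`, "esc_trace"),
                         "monitor_dart_escalating"),
               write_arm(lapply(flies, `[[`, "fix_trace"),
                         "monitor_dart_fixed"))
    p <- file.path(out_dir, "stimuli_escalating.csv")
    write_stimulus_log(do.call(rbind, lapply(flies, `[[`, "esc_events")), p)
    files <- c(files, p)
    p <- file.path(out_dir, "stimuli_fixed.csv")
    write_stimulus_log(do.call(rbind, lapply(flies, `[[`, "fix_events")), p)
    files <- c(files, p)
    p <- file.path(out_dir, "vco2.csv")
    write_vco2_table(lapply(flies, `[[`, "mtrace"), p)
    files <- c(files, p)
    p <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)
    p <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(list(
      n_flies = config$n_flies, days = config$days, seed = config$seed,
      genotypes = lapply(config$genotypes, unclass),
      protocol = config$protocol), p)
    files <- c(files, p)
  }
  invisible(list(flies = flies, truth = truth, files = files))
}
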