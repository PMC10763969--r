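#' Score sleep bouts from an activity trace
#'
#' Sleep is the standard fly criterion: a maximal run of consecutive
#' zero-count (immobile) minutes lasting at least `min_bout` minutes
#' (default 5). Runs touching either edge of the recording are returned
#' with truncation flags set, since their true extent is unobserved.
#'
#' @param trace An [activity_trace()].
#' @param min_bout Minimum bout duration in minutes (>= 1).
#' @return A `data.frame` with one row per bout: `fly_id`, `start_min`
#'   (0-based, ZT-anchored absolute minute), `duration_min`,
#'   `truncated_start`, `truncated_end`. The trace's `zt0_offset_min` is
#'   attached as an attribute so bouts can be mapped back to trace indices.
#' @examples
#' tr <- activity_trace("f1", c(1, 0, 0, 0, 0, 0, 2, 0))
#' score_sleep(tr)
#' @export
score_sleep <- function(trace, min_bout = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  min_bout <- as.integer(min_bout)
  if (is.na(min_bout) || min_bout < 1L) stop("min_bout must be >= 1")
  r <- rle(trace$counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L           # 1-based run starts
  keep <- r$values & r$lengths >= min_bout
  n <- length(trace$counts)
  bouts <- data.frame(
    fly_id = rep(trace$fly_id, sum(keep)),
    start_min = trace$zt0_offset_min + starts[keep] - 1L,
    duration_min = r$lengths[keep],
    truncated_start = starts[keep] == 1L,
    truncated_end = ends[keep] == n,
    stringsAsFactors = FALSE
  )
  rownames(bouts) <- NULL
  attr(bouts, "zt0_offset_min") <- trace$zt0_offset_min
  attr(bouts, "min_bout") <- min_bout
  bouts
}

#' Day/night phase of a ZT minute
#'
#' Under a 12:12 light:dark cycle, ZT minutes 0-719 of each day are lights-on
#' ("day") and 720-1439 lights-off ("night"); half-open boundaries, 24-h
#' periodic.
#'
#' @param zt_min Non-negative absolute ZT minute(s).
#' @return Character vector, `"day"` or `"night"`.
#' @examples
#' phase_of_minute(c(0, 719, 720, 1440))
#' @export
phase_of_minute <- function(zt_min) {
  if (any(zt_min < 0)) stop("zt_min must be non-negative")
  ifelse(zt_min %% 1440 < 720, "day", "night")
}

# logical vector: is each trace minute inside a scored bout?
sleep_minute_mask <- function(trace, bouts) {
  mask <- logical(length(trace$counts))
  if (nrow(bouts) > 0L) {
    rel <- bouts$start_min - trace$zt0_offset_min
    for (i in seq_len(nrow(bouts))) {
      mask[(rel[i] + 1L):(rel[i] + bouts$duration_min[i])] <- TRUE
    }
  }
  mask
}

#' Per-phase sleep architecture metrics
#'
#' Aggregates scored bouts into the standard per-phase summaries: total
#' sleep, bout number, mean bout length and waking activity (beam crosses
#' per waking minute). A bout spanning the day/night boundary contributes
#' its minutes to each phase by overlap and is counted in the bout number of
#' every phase it intersects; mean bout length is the ratio of the two, so
#' metrics stay mutually consistent.
#'
#' @param trace An [activity_trace()].
#' @param bouts Output of [score_sleep()] on the same trace.
#' @return A two-row `data.frame` (day, night) with columns `fly_id`,
#'   `phase`, `total_sleep_min`, `bout_number`, `mean_bout_len_min`,
#'   `waking_activity`. Ratios with zero denominators are `NA`.
#' @export
sleep_metrics <- function(trace, bouts) {
  stopifnot(inherits(trace, "activity_trace"))
  n <- length(trace$counts)
  zt <- trace$zt0_offset_min + seq_len(n) - 1L
  ph <- phase_of_minute(zt)
  asleep <- sleep_minute_mask(trace, bouts)
  res <- lapply(c("day", "night"), function(p) {
    in_p <- ph == p
    total <- sum(asleep & in_p)
    if (nrow(bouts) > 0L) {
      rel <- bouts$start_min - trace$zt0_offset_min
      nb <- sum(vapply(seq_len(nrow(bouts)), function(i) {
        any(in_p[(rel[i] + 1L):(rel[i] + bouts$duration_min[i])])
      }, logical(1)))
    } else nb <- 0L
    waking_min <- sum(in_p & !asleep)
    data.frame(
      fly_id = trace$fly_id, phase = p,
      total_sleep_min = total, bout_number = nb,
      mean_bout_len_min = if (nb > 0L) total / nb else NA_real_,
      waking_activity = if (waking_min > 0L)
        sum(trace$counts[in_p]) / waking_min else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wake/doze transition propensities
#'
#' Estimates the per-minute two-state Markov transition probabilities from
#' minute-to-minute activity: P(Doze) is the conditional frequency of an
#' active minute being followed by an inactive one, P(Wake) the reverse.
#' Each minute pair (t, t+1) is assigned to the phase of minute t; the final
#' minute starts no pair. A probability whose denominator is zero is
#' returned as `NA`, never as 0.
#'
#' @param trace An [activity_trace()] of length >= 2.
#' @param phase Phases to estimate, any subset of `c("day", "night")`.
#' @return A `data.frame` with one row per requested phase: `fly_id`,
#'   `phase`, `p_doze`, `p_wake`, `n_active_transitions`,
#'   `n_inactive_transitions`.
#' @export
transition_probs <- function(trace, phase = c("day", "night")) {
  stopifnot(inherits(trace, "activity_trace"))
  phase <- match.arg(phase, c("day", "night"), several.ok = TRUE)
  n <- length(trace$counts)
  if (n < 2L) stop("trace must have at least 2 minutes")
  act <- trace$counts > 0L
  from <- act[-n]; to <- act[-1L]
  ph <- phase_of_minute(trace$zt0_offset_min + seq_len(n - 1L) - 1L)
  out <- lapply(phase, function(p) {
    sel <- ph == p
    n_act <- sum(sel & from)
    n_inact <- sum(sel & !from)
    data.frame(
      fly_id = trace$fly_id, phase = p,
      p_doze = if (n_act > 0L) sum(sel & from & !to) / n_act else NA_real_,
      p_wake = if (n_inact > 0L) sum(sel & !from & to) / n_inact else NA_real_,
      n_active_transitions = n_act,
      n_inactive_transitions = n_inact,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hourly profile of transition propensities across flies
#'
#' Bins minute pairs by the ZT hour of their first minute, computes per-fly
#' P(Doze)/P(Wake) within each hour as in [transition_probs()], and
#' summarizes across flies (mean, SD, SEM, and the number of flies with a
#' defined estimate). Hours in which a fly has no qualifying pairs are
#' excluded from that fly's contribution rather than counted as zero.
#'
#' @param traces A list of [activity_trace()] objects.
#' @return A 24-row `data.frame`: `zt_hour`, then mean/sd/sem/n for
#'   `p_doze` and `p_wake`.
#' @export
hourly_transition_profile <- function(traces) {
  stopifnot(length(traces) >= 1L)
  per_fly <- lapply(traces, function(trace) {
    n <- length(trace$counts)
    act <- trace$counts > 0L
    from <- act[-n]; to <- act[-1L]
    hr <- ((trace$zt0_offset_min + seq_len(n - 1L) - 1L) %% 1440L) %/% 60L
    vapply(0:23, function(h) {
      sel <- hr == h
      n_act <- sum(sel & from); n_inact <- sum(sel & !from)
      c(doze = if (n_act > 0L) sum(sel & from & !to) / n_act else NA_real_,
        wake = if (n_inact > 0L) sum(sel & !from & to) / n_inact else NA_real_)
    }, numeric(2))
  })
  doze <- do.call(rbind, lapply(per_fly, function(m) m["doze", ]))
  wake <- do.call(rbind, lapply(per_fly, function(m) m["wake", ]))
  summarize <- function(mat) {
    n <- colSums(!is.na(mat))
    mu <- colMeans(mat, na.rm = TRUE)
    mu[n == 0L] <- NA_real_
    s <- apply(mat, 2L, stats::sd, na.rm = TRUE)
    s[n < 2L] <- NA_real_
    list(mean = mu, sd = s, sem = s / sqrt(n), n = n)
  }
  d <- summarize(doze); w <- summarize(wake)
  data.frame(
    zt_hour = 0:23,
    p_doze_mean = d$mean, p_doze_sd = d$sd, p_doze_sem = d$sem, p_doze_n = d$n,
    p_wake_mean = w$mean, p_wake_sd = w$sd, p_wake_sem = w$sem, p_wake_n = w$n,
    row.names = NULL
  )
}
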