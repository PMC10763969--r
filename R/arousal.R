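# run length of consecutive zero-count minutes ending at each minute
# (z[i] = length of the zero run ending at 1-based minute i)
zero_runlen <- function(counts) {
  i <- seq_along(counts)
  i - cummax(i * (counts != 0L))
}

#' Time asleep immediately before a given minute
#'
#' Causal application of the sleep rule at an assay time: the fly counts as
#' asleep at minute `t` iff the maximal run of zero-count minutes ending at
#' minute `t - 1` is at least `min_sleep` (default 5) minutes long, in which
#' case that run length is the time asleep.
#'
#' @param trace An [activity_trace()].
#' @param t 0-based minute index into the trace, `0 <= t < length(trace)`.
#' @param min_sleep Minimum immobile run (minutes) to count as sleep.
#' @return Integer minutes asleep, or `NA` if the fly is awake at `t`.
#' @examples
#' tr <- activity_trace("f1", c(1, 0, 0, 0, 0, 0, 1))
#' time_asleep_at(tr, 6)  # 5 zero minutes precede minute 6
#' @export
time_asleep_at <- function(trace, t, min_sleep = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t >= length(trace$counts)) {
    stop("t must satisfy 0 <= t < length(trace)")
  }
  if (t == 0L) return(NA_integer_)
  k <- zero_runlen(trace$counts)[t]  # run ending at 0-based minute t-1
  if (k >= min_sleep) k else NA_integer_
}

#' Arousal threshold from one escalating-intensity assay
#'
#' Scores a single staircase assay: vibration stimuli of strictly
#' increasing intensity delivered to one fly at one time. If the fly was
#' awake at assay onset no threshold is defined. Otherwise the threshold is
#' the first intensity at which the fly moved within the response window,
#' reported as a proportion of the maximum intensity. A 0 g delivery is a
#' sham level: a response to it indicates spontaneous waking and cannot
#' define a threshold. A sleeping fly that never responds is censored.
#'
#' @param events Stimulus-event rows of one assay (same `fly_id` and
#'   `zt_min`, protocol `"escalating"`, strictly increasing intensities).
#' @param trace The fly's [activity_trace()].
#' @param max_intensity_g Maximum intensity of the protocol (denominator of
#'   the reported proportion), default 1.2 g.
#' @param response_window_s Response window in seconds, default 15.
#' @param min_sleep Sleep criterion in minutes, default 5.
#' @return One-row `data.frame`: `fly_id`, `zt_min`, `asleep_at_stimulus`,
#'   `time_asleep_min`, `threshold_prop` (`NA` when awake or censored),
#'   `censored`.
#' @export
threshold_from_assay <- function(events, trace, max_intensity_g = 1.2,
                                 response_window_s = 15, min_sleep = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  if (nrow(events) == 0L) stop("no events in assay")
  if (length(unique(events$fly_id)) != 1L ||
      length(unique(events$zt_min)) != 1L) {
    stop("events of one assay must share fly_id and zt_min")
  }
  events <- events[order(events$intensity_g), , drop = FALSE]
  if (any(diff(events$intensity_g) <= 0)) {
    stop("escalating assay intensities must be strictly increasing")
  }
  rel_t <- events$zt_min[1] - trace$zt0_offset_min
  k <- time_asleep_at(trace, rel_t, min_sleep = min_sleep)
  if (is.na(k)) {
    return(data.frame(fly_id = events$fly_id[1], zt_min = events$zt_min[1],
                      asleep_at_stimulus = FALSE,
                      time_asleep_min = NA_integer_,
                      threshold_prop = NA_real_, censored = FALSE,
                      stringsAsFactors = FALSE))
  }
  hit <- events$intensity_g > 0 & events$responded &
    !is.na(events$latency_s) & events$latency_s <= response_window_s
  thr <- if (any(hit)) events$intensity_g[which(hit)[1]] / max_intensity_g
         else NA_real_
  data.frame(fly_id = events$fly_id[1], zt_min = events$zt_min[1],
             asleep_at_stimulus = TRUE, time_asleep_min = k,
             threshold_prop = thr, censored = !any(hit),
             stringsAsFactors = FALSE)
}

#' Score all escalating assays in a stimulus log
#'
#' Splits an escalating-protocol stimulus log into (fly, time) assays and
#' applies [threshold_from_assay()] to each.
#'
#' @param events Stimulus-event `data.frame` (protocol `"escalating"` rows
#'   are used).
#' @param traces Named list of [activity_trace()] objects keyed by fly id,
#'   or an unnamed list (names taken from each trace's `fly_id`).
#' @inheritParams threshold_from_assay
#' @return Row-bound [threshold_from_assay()] records.
#' @export
score_arousal_assays <- function(events, traces, max_intensity_g = 1.2,
                                 response_window_s = 15, min_sleep = 5L) {
  traces <- name_traces(traces)
  ev <- events[events$protocol == "escalating", , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(fly_id = character(), zt_min = integer(),
                      asleep_at_stimulus = logical(),
                      time_asleep_min = integer(),
                      threshold_prop = numeric(), censored = logical()))
  }
  parts <- split(ev, list(ev$fly_id, ev$zt_min), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(a) {
    threshold_from_assay(a, traces[[a$fly_id[1]]],
                         max_intensity_g = max_intensity_g,
                         response_window_s = response_window_s,
                         min_sleep = min_sleep)
  }))
  out <- out[order(out$fly_id, out$zt_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

name_traces <- function(traces) {
  if (is.null(names(traces)) || any(!nzchar(names(traces)))) {
    names(traces) <- vapply(traces, function(tr) tr$fly_id, character(1))
  }
  traces
}

#' Per-fly mean arousal threshold
#'
#' Averages threshold proportions over a fly's sleeping assays within a
#' phase. Censored assays (no response at any level) are excluded by
#' default and reported as a censored fraction; the alternative policy
#' scores them at the maximal proportion 1.0.
#'
#' @param records Output of [score_arousal_assays()] (or row-bound
#'   [threshold_from_assay()] results).
#' @param phase `"day"`, `"night"`, or both (default).
#' @param censored Censoring policy: `"exclude"` (default) or
#'   `"assign_max"`.
#' @return A `data.frame` with one row per fly x phase holding
#'   `mean_threshold`, its SD across assays, the number of sleeping assays
#'   and the censored fraction. Flies with no eligible assay get `NA`.
#' @export
mean_threshold <- function(records, phase = c("day", "night"),
                           censored = c("exclude", "assign_max")) {
  phase <- match.arg(phase, c("day", "night"), several.ok = TRUE)
  censored <- match.arg(censored)
  rec <- records[records$asleep_at_stimulus, , drop = FALSE]
  rec$phase <- phase_of_minute(rec$zt_min)
  rec <- rec[rec$phase %in% phase, , drop = FALSE]
  if (censored == "assign_max") {
    rec$threshold_prop[rec$censored] <- 1.0
  }
  grid <- expand.grid(fly_id = unique(records$fly_id), phase = phase,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r <- rec[rec$fly_id == grid$fly_id[i] & rec$phase == grid$phase[i], ,
             drop = FALSE]
    v <- r$threshold_prop[!is.na(r$threshold_prop)]
    data.frame(
      fly_id = grid$fly_id[i], phase = grid$phase[i],
      mean_threshold = if (length(v)) mean(v) else NA_real_,
      sd_threshold = if (length(v) > 1L) stats::sd(v) else NA_real_,
      n_assays = nrow(r),
      censored_fraction = if (nrow(r)) mean(r$censored) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Per-trial reactivity records from fixed-intensity assays
#'
#' Retains only trials delivered to sleeping flies and scores each as
#' responsive iff the fly moved within the response window (default 60 s).
#'
#' @param events Stimulus-event `data.frame`; protocol `"fixed"` rows are
#'   used.
#' @param traces Named list of [activity_trace()] objects (see
#'   [score_arousal_assays()]).
#' @param response_window_s Response window in seconds, default 60.
#' @param min_sleep Sleep criterion in minutes, default 5.
#' @return A `data.frame` with one row per sleeping-fly trial: `fly_id`,
#'   `genotype`, `phase`, `zt_min`, `time_asleep_min`, `responded`.
#' @export
reactivity_table <- function(events, traces, response_window_s = 60,
                             min_sleep = 5L) {
  traces <- name_traces(traces)
  ev <- events[events$protocol == "fixed", , drop = FALSE]
  rows <- lapply(split(ev, ev$fly_id), function(evf) {
    tr <- traces[[evf$fly_id[1]]]
    if (is.null(tr)) stop("no trace for fly ", evf$fly_id[1])
    rel_t <- evf$zt_min - tr$zt0_offset_min
    if (any(rel_t < 0L | rel_t >= length(tr$counts))) {
      stop("stimulus time outside trace for fly ", evf$fly_id[1])
    }
    z <- zero_runlen(tr$counts)
    k <- ifelse(rel_t > 0L, z[pmax(rel_t, 1L)], 0L)  # run ending at rel_t - 1
    keep <- k >= min_sleep
    if (!any(keep)) return(NULL)
    data.frame(
      fly_id = evf$fly_id[keep], genotype = tr$genotype,
      phase = phase_of_minute(evf$zt_min[keep]), zt_min = evf$zt_min[keep],
      time_asleep_min = as.integer(k[keep]),
      responded = evf$responded[keep] & !is.na(evf$latency_s[keep]) &
        evf$latency_s[keep] <= response_window_s,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(fly_id = character(), genotype = character(),
                      phase = character(), zt_min = integer(),
                      time_asleep_min = integer(), responded = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reactivity as a function of prior time asleep
#'
#' Bins per-trial reactivity records by time asleep (half-open bins,
#' default 5-min width from 5 to 40 min plus an overflow bin) and reports
#' the percentage of trials with a response per bin and phase. Empty bins
#' are retained with `n_trials = 0` and an undefined percentage.
#'
#' @param table Output of [reactivity_table()].
#' @param bin_width Bin width in minutes.
#' @param range_min Two-element vector giving the lower edge of the first
#'   bin and the upper edge of the last regular bin.
#' @param overflow Append a final `[range_min[2], Inf)` bin (default TRUE).
#' @return A `data.frame`: `phase`, `bin_lo_min`, `bin_hi_min`, `n_trials`,
#'   `n_responded`, `reactivity_pct`.
#' @export
reactivity_curve <- function(table, bin_width = 5, range_min = c(5, 40),
                             overflow = TRUE) {
  if (nrow(table) == 0L) stop("reactivity table is empty")
  lo <- seq(range_min[1], range_min[2] - bin_width, by = bin_width)
  hi <- lo + bin_width
  if (overflow) { lo <- c(lo, range_min[2]); hi <- c(hi, Inf) }
  out <- do.call(rbind, lapply(unique(table$phase), function(p) {
    tp <- table[table$phase == p, , drop = FALSE]
    do.call(rbind, lapply(seq_along(lo), function(b) {
      sel <- tp$time_asleep_min >= lo[b] & tp$time_asleep_min < hi[b]
      n <- sum(sel); r <- sum(tp$responded[sel])
      data.frame(phase = p, bin_lo_min = lo[b], bin_hi_min = hi[b],
                 n_trials = n, n_responded = r,
                 reactivity_pct = if (n > 0L) 100 * r / n else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Reactivity regression and genotype ANCOVA
#'
#' Regresses reactivity on prior time asleep. The default observational
#' unit is the trial, scored 0 or 100, matching the large denominator
#' degrees of freedom of published reactivity regressions; binned
#' percentages can be used instead. When two or more genotypes are present
#' their lines are compared by [ancova()].
#'
#' @param table Output of [reactivity_table()] (per-trial mode) or of
#'   [reactivity_curve()] plus a `genotype` column (per-bin mode).
#' @param unit `"trial"` (default) or `"bin"`.
#' @return A list with `fits` (named list of [ols_fit()] per genotype) and
#'   `ancova` (an [ancova()] result, or `NULL` with a single genotype).
#' @export
reactivity_regression <- function(table, unit = c("trial", "bin")) {
  unit <- match.arg(unit)
  if (unit == "trial") {
    x <- table$time_asleep_min
    y <- 100 * as.numeric(table$responded)
  } else {
    keep <- !is.na(table$reactivity_pct)
    table <- table[keep, , drop = FALSE]
    # bin midpoint; the open-ended overflow bin is placed at its lower edge
    x <- ifelse(is.finite(table$bin_hi_min),
                (table$bin_lo_min + table$bin_hi_min) / 2,
                table$bin_lo_min)
    y <- table$reactivity_pct
  }
  gens <- unique(table$genotype)
  groups <- lapply(gens, function(g) {
    sel <- table$genotype == g
    if (length(unique(x[sel])) < 3L) {
      stop("genotype ", g, " has fewer than 3 distinct time-asleep values")
    }
    list(x = x[sel], y = y[sel])
  })
  names(groups) <- gens
  fits <- lapply(groups, function(g) ols_fit(g$x, g$y))
  list(fits = fits,
       ancova = if (length(groups) >= 2L) ancova(groups) else NULL)
}
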