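#' Classify metabolic bins by sleep state
#'
#' Labels each VCO2 bin `"sleep"` if every one of its minutes lies inside a
#' scored sleep bout, `"wake"` if none does, and `"mixed"` otherwise. The
#' bout table and the metabolic trace must share the same ZT anchor.
#'
#' @param bouts Output of [score_sleep()] (its `zt0_offset_min` attribute
#'   is checked against the metabolic trace).
#' @param mtrace A [metabolic_trace()].
#' @return A `data.frame` with one row per bin: `bin_index` (0-based),
#'   `zt_min` (ZT minute of the bin's first minute), `phase` (phase of that
#'   minute), `label`.
#' @export
classify_bins <- function(bouts, mtrace) {
  stopifnot(inherits(mtrace, "metabolic_trace"))
  zt0 <- attr(bouts, "zt0_offset_min")
  if (is.null(zt0) || zt0 != mtrace$zt0_offset_min) {
    stop("bouts and metabolic trace have misaligned ZT anchors")
  }
  bw <- mtrace$bin_min
  n_min <- length(mtrace$vco2) * bw
  asleep <- logical(n_min)
  if (nrow(bouts) > 0L) {
    rel <- bouts$start_min - zt0
    for (i in seq_len(nrow(bouts))) {
      lo <- max(rel[i] + 1L, 1L)
      hi <- min(rel[i] + bouts$duration_min[i], n_min)
      if (lo <= hi) asleep[lo:hi] <- TRUE
    }
  }
  per_bin <- matrix(asleep, nrow = bw)
  n_sleep <- colSums(per_bin)
  label <- ifelse(n_sleep == bw, "sleep", ifelse(n_sleep == 0L, "wake", "mixed"))
  start <- (seq_along(mtrace$vco2) - 1L) * bw
  data.frame(
    bin_index = start %/% bw,
    zt_min = zt0 + start,
    phase = phase_of_minute(zt0 + start),
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Percent change in VCO2 relative to a reference bin
#'
#' The bout-aligned downscaling statistic: `(v1 - vk) / v1 * 100`, so a
#' *positive* value means metabolic suppression relative to the bout's
#' first bin. Undefined (`NA`) when the reference `v1` is not positive.
#'
#' @param v1 Reference (first-bin) VCO2, scalar.
#' @param vk Comparison VCO2 value(s).
#' @return Numeric percent change(s); `NA` if `v1 <= 0`.
#' @examples
#' pct_change(10, 9)    # 10
#' pct_change(10, 12)   # -20
#' @export
pct_change <- function(v1, vk) {
  stopifnot(length(v1) == 1L)
  if (any(vk < 0, na.rm = TRUE)) stop("vk must be non-negative")
  if (is.na(v1) || v1 <= 0) return(rep(NA_real_, length(vk)))
  (v1 - vk) / v1 * 100
}

#' VCO2 profile of a single sleep bout
#'
#' Extracts the successive instrument bins that lie fully inside one sleep
#' bout and computes the percent-change series relative to the first bin.
#' Bins are taken from the instrument's fixed grid; by default only bouts
#' whose start falls on that grid are profiled (`allow_offset` relaxes this
#' by accepting bouts whose first full bin starts within `allow_offset`
#' minutes of the bout's start). Bouts too short to contain one full bin,
#' or with a non-positive first bin, yield `NULL` with a message.
#'
#' @param bout One row of a [score_sleep()] bout table (the table's
#'   ZT-anchor attribute must match the metabolic trace).
#' @param mtrace A [metabolic_trace()].
#' @param zt0_offset_min ZT anchor of the bout, taken from the bout table's
#'   attribute when available.
#' @param allow_offset Maximum tolerated gap (minutes) between bout start
#'   and its first full instrument bin; default 0 (grid-aligned bouts only).
#' @return An object of class `bout_vco2_profile`: list with `fly_id`,
#'   `start_min`, `duration_min`, `phase`, `v_bins`, `pct_change` (one
#'   element shorter than `v_bins`), or `NULL` if the bout is excluded.
#' @export
bout_profile <- function(bout, mtrace, zt0_offset_min = NULL,
                         allow_offset = 0L) {
  stopifnot(inherits(mtrace, "metabolic_trace"))
  zt0 <- if (!is.null(zt0_offset_min)) zt0_offset_min
         else attr(bout, "zt0_offset_min")
  if (is.null(zt0)) zt0 <- mtrace$zt0_offset_min
  if (zt0 != mtrace$zt0_offset_min) {
    stop("bout and metabolic trace have misaligned ZT anchors")
  }
  bw <- mtrace$bin_min
  rel <- bout$start_min - zt0
  gap <- (bw - rel %% bw) %% bw
  if (gap > allow_offset) return(NULL)
  first_bin <- (rel + gap) %/% bw              # 0-based bin index
  n_bins <- (bout$duration_min - gap) %/% bw
  if (n_bins < 1L || first_bin + n_bins > length(mtrace$vco2)) {
    message("bout at minute ", bout$start_min,
            " too short for one full bin; excluded")
    return(NULL)
  }
  v <- mtrace$vco2[(first_bin + 1L):(first_bin + n_bins)]
  if (v[1] <= 0) {
    message("bout at minute ", bout$start_min,
            " has non-positive first-bin VCO2; excluded")
    return(NULL)
  }
  structure(
    list(fly_id = bout$fly_id, start_min = bout$start_min,
         duration_min = bout$duration_min,
         phase = phase_of_minute(bout$start_min),
         v_bins = v,
         pct_change = if (n_bins > 1L) pct_change(v[1], v[-1]) else numeric(0)),
    class = "bout_vco2_profile"
  )
}

#' Profile every sleep bout of a fly
#'
#' @param bouts A [score_sleep()] bout table.
#' @param mtrace A [metabolic_trace()].
#' @inheritParams bout_profile
#' @return List of `bout_vco2_profile` objects (excluded bouts dropped).
#' @export
bout_profiles <- function(bouts, mtrace, allow_offset = 0L) {
  zt0 <- attr(bouts, "zt0_offset_min")
  out <- lapply(seq_len(nrow(bouts)), function(i) {
    suppressMessages(bout_profile(bouts[i, , drop = FALSE], mtrace,
                                  zt0_offset_min = zt0,
                                  allow_offset = allow_offset))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Per-fly mean percent change by time asleep
#'
#' Averages the percent-change series across a fly's sleep bouts within a
#' phase: the k-th element of each bout's series compares the bout's first
#' 5-min bin with its k+1-th, so it is labelled with time asleep
#' `5 * (k + 1)` minutes. Only bouts long enough to contain a given bin
#' contribute to its mean.
#'
#' The series is reported up to `max_time_min` (default 40 minutes, the
#' same bounded range used for reactivity analysis): beyond the length of
#' all but the rarest bouts, bins are occupied by one or two bouts whose
#' changes all share a single reference bin, so they carry almost no
#' independent information and would dominate downstream regressions.
#' Set `max_time_min = Inf` to keep the full series.
#'
#' @param profiles List of `bout_vco2_profile` objects (one fly).
#' @param phase `"day"` or `"night"`.
#' @param max_time_min Largest time-asleep bin reported, minutes.
#' @return A `data.frame`: `fly_id`, `phase`, `time_asleep_min`,
#'   `mean_pct_change`, `n_bouts`.
#' @export
fly_pct_change_by_time <- function(profiles, phase, max_time_min = 40) {
  phase <- match.arg(phase, c("day", "night"))
  profiles <- Filter(function(p) p$phase == phase && length(p$pct_change) > 0L,
                     profiles)
  if (!length(profiles)) {
    return(data.frame(fly_id = character(), phase = character(),
                      time_asleep_min = numeric(), mean_pct_change = numeric(),
                      n_bouts = integer()))
  }
  fly <- profiles[[1]]$fly_id
  kmax <- max(vapply(profiles, function(p) length(p$pct_change), integer(1)))
  kmax <- min(kmax, floor(max_time_min / 5) - 1L)
  if (kmax < 1L) {
    return(data.frame(fly_id = character(), phase = character(),
                      time_asleep_min = numeric(), mean_pct_change = numeric(),
                      n_bouts = integer()))
  }
  out <- do.call(rbind, lapply(seq_len(kmax), function(k) {
    vals <- unlist(lapply(profiles, function(p) {
      if (length(p$pct_change) >= k) p$pct_change[k] else NULL
    }))
    data.frame(fly_id = fly, phase = phase,
               time_asleep_min = 5 * (k + 1),
               mean_pct_change = mean(vals), n_bouts = length(vals),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean VCO2 by behavioural state
#'
#' Per-phase mean VCO2 per bin during waking, sleeping, and overall. Mixed
#' bins (partially asleep) are excluded from the state means but included
#' in the total by default.
#'
#' @param classification Output of [classify_bins()].
#' @param mtrace The matching [metabolic_trace()].
#' @param phase `"day"` or `"night"`.
#' @param include_mixed_in_total Include mixed bins in `vco2_total`
#'   (default TRUE).
#' @return One-row `data.frame`: `fly_id`, `phase`, `vco2_wake`,
#'   `vco2_sleep`, `vco2_total`, and the three bin counts. States with no
#'   bins are `NA`.
#' @export
state_means <- function(classification, mtrace, phase,
                        include_mixed_in_total = TRUE) {
  phase <- match.arg(phase, c("day", "night"))
  stopifnot(nrow(classification) == length(mtrace$vco2))
  sel <- classification$phase == phase
  if (!any(sel)) stop("no bins in requested phase")
  v <- mtrace$vco2[sel]
  lab <- classification$label[sel]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  tot_sel <- if (include_mixed_in_total) rep(TRUE, length(v))
             else lab != "mixed"
  data.frame(
    fly_id = mtrace$fly_id, phase = phase,
    vco2_wake = mean_or_na(v[lab == "wake"]),
    vco2_sleep = mean_or_na(v[lab == "sleep"]),
    vco2_total = mean_or_na(v[tot_sel]),
    n_wake_bins = sum(lab == "wake"),
    n_sleep_bins = sum(lab == "sleep"),
    n_mixed_bins = sum(lab == "mixed"),
    stringsAsFactors = FALSE
  )
}

#' Metabolic-downscaling regression and genotype ANCOVA
#'
#' Regresses per-fly mean percent change in VCO2 on time asleep, per
#' genotype, and compares the genotype regression lines by [ancova()].
#'
#' @param points Row-bound [fly_pct_change_by_time()] tables across flies.
#' @param genotypes Named character vector mapping `fly_id` to genotype.
#' @return A list with `fits` (named [ols_fit()] list per genotype) and
#'   `ancova` (`NULL` with a single genotype).
#' @export
metabolic_regression <- function(points, genotypes) {
  if (nrow(points) == 0L) stop("no points to regress")
  gen <- genotypes[points$fly_id]
  if (anyNA(gen)) stop("missing genotype for some flies")
  groups <- lapply(unique(gen), function(g) {
    sel <- gen == g
    if (length(unique(points$time_asleep_min[sel])) < 3L) {
      stop("genotype ", g, " has fewer than 3 distinct time-asleep values")
    }
    list(x = points$time_asleep_min[sel], y = points$mean_pct_change[sel])
  })
  names(groups) <- unique(gen)
  list(fits = lapply(groups, function(g) ols_fit(g$x, g$y)),
       ancova = if (length(groups) >= 2L) ancova(groups) else NULL)
}
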