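#' Per-fly activity trace
#'
#' The substrate of all downstream scoring: one beam-cross count per minute
#' for a single fly, anchored to Zeitgeber time. Minute `t` (0-based, counted
#' from the start of the recording) covers the half-open interval
#' `[t, t + 1)`; its absolute ZT minute is `zt0_offset_min + t`. A minute is
#' *active* iff its count is greater than zero.
#'
#' @param fly_id Character scalar identifying the fly.
#' @param counts Integer vector of non-negative per-minute beam-cross counts.
#' @param zt0_offset_min Minutes elapsed since lights-on (ZT0) at the first
#'   recorded minute, in `[0, 1440)`.
#' @param genotype Character label carried through to group-level analyses.
#' @return An object of class `activity_trace`.
#' @examples
#' tr <- activity_trace("f1", c(2L, 0L, 0L, 0L, 0L, 0L, 3L))
#' is_active(tr)
#' @export
activity_trace <- function(fly_id, counts, zt0_offset_min = 0L,
                           genotype = "unknown") {
  stopifnot(is.character(fly_id), length(fly_id) == 1L, nzchar(fly_id))
  counts <- as.integer(counts)
  if (length(counts) < 1L) {
    stop("an activity trace needs at least one minute of counts")
  }
  if (anyNA(counts) || any(counts < 0L)) {
    stop("activity counts must be non-negative integers")
  }
  zt0_offset_min <- as.integer(zt0_offset_min)
  if (is.na(zt0_offset_min) || zt0_offset_min < 0L || zt0_offset_min >= 1440L) {
    stop("zt0_offset_min must lie in [0, 1440)")
  }
  structure(
    list(fly_id = fly_id, genotype = as.character(genotype),
         zt0_offset_min = zt0_offset_min, counts = counts),
    class = "activity_trace"
  )
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> fly %s (%s): %d min, ZT offset %d min, %d active\n",
              x$fly_id, x$genotype, length(x$counts), x$zt0_offset_min,
              sum(x$counts > 0L)))
  invisible(x)
}

#' @export
length.activity_trace <- function(x) length(x$counts)

#' Active-minute predicate
#'
#' @param trace An [activity_trace()].
#' @return Logical vector, one element per minute: `TRUE` iff count > 0.
#' @export
is_active <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  trace$counts > 0L
}

#' Per-fly position trace
#'
#' Planar coordinates from video tracking, already subsampled (default 1
#' frame per second). Movement between consecutive frames is scored as a
#' displacement above `movement_threshold_mm`.
#'
#' @param fly_id Character scalar.
#' @param xy_mm Two-column numeric matrix of coordinates in millimetres.
#' @param fps Frames per second after subsampling (> 0).
#' @return An object of class `position_trace`.
#' @export
position_trace <- function(fly_id, xy_mm, fps = 1) {
  stopifnot(is.character(fly_id), length(fly_id) == 1L)
  xy_mm <- as.matrix(xy_mm)
  if (ncol(xy_mm) != 2L || !all(is.finite(xy_mm))) {
    stop("xy_mm must be a two-column matrix of finite coordinates")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  structure(list(fly_id = fly_id, fps = fps, xy_mm = xy_mm),
            class = "position_trace")
}

#' Frame-to-frame movement flags from a position trace
#'
#' @param ptrace A [position_trace()].
#' @param movement_threshold_mm Displacement (mm) above which a frame pair
#'   counts as movement; default 3 mm.
#' @return Logical vector of length `nrow(xy_mm) - 1`.
#' @export
movement_flags <- function(ptrace, movement_threshold_mm = 3) {
  stopifnot(inherits(ptrace, "position_trace"))
  d <- diff(ptrace$xy_mm)
  sqrt(rowSums(d^2)) > movement_threshold_mm
}

#' Per-fly metabolic (VCO2) trace
#'
#' CO2 produced per fixed-width time bin (default 5 min), in arbitrary but
#' consistent units. Bin `k` (0-based) covers minutes
#' `[k * bin_min, (k + 1) * bin_min)` from the start of the recording.
#'
#' @param fly_id Character scalar.
#' @param vco2 Numeric vector of non-negative per-bin VCO2 values.
#' @param bin_min Bin width in minutes; must divide 1440.
#' @param zt0_offset_min As for [activity_trace()].
#' @return An object of class `metabolic_trace`.
#' @export
metabolic_trace <- function(fly_id, vco2, bin_min = 5L, zt0_offset_min = 0L) {
  stopifnot(is.character(fly_id), length(fly_id) == 1L)
  vco2 <- as.numeric(vco2)
  if (anyNA(vco2) || any(vco2 < 0)) stop("vco2 values must be non-negative")
  bin_min <- as.integer(bin_min)
  if (bin_min < 1L || 1440L %% bin_min != 0L) {
    stop("bin_min must be a positive divisor of 1440")
  }
  zt0_offset_min <- as.integer(zt0_offset_min)
  if (zt0_offset_min < 0L || zt0_offset_min >= 1440L) {
    stop("zt0_offset_min must lie in [0, 1440)")
  }
  structure(
    list(fly_id = fly_id, bin_min = bin_min, vco2 = vco2,
         zt0_offset_min = zt0_offset_min),
    class = "metabolic_trace"
  )
}

#' @export
print.metabolic_trace <- function(x, ...) {
  cat(sprintf("<metabolic_trace> fly %s: %d x %d-min bins, ZT offset %d min\n",
              x$fly_id, length(x$vco2), x$bin_min, x$zt0_offset_min))
  invisible(x)
}

#' Construct a stimulus-event table
#'
#' One row per delivered mechanical stimulus. `protocol` is `"escalating"`
#' for the staircase arousal-threshold assay and `"fixed"` for the
#' maximal-intensity reactivity assay. `latency_s` is the delay from
#' delivery to the first movement, `NA` when the fly never responded.
#'
#' @param fly_id,zt_min,protocol,intensity_g,responded,latency_s Vectors of
#'   equal length (scalars recycled) giving the event fields.
#' @return A `data.frame` with one row per event, sorted by
#'   (`fly_id`, `zt_min`, `intensity_g`).
#' @export
stimulus_events <- function(fly_id, zt_min, protocol, intensity_g,
                            responded, latency_s = NA_real_) {
  df <- data.frame(
    fly_id = as.character(fly_id),
    zt_min = as.integer(zt_min),
    protocol = as.character(protocol),
    intensity_g = as.numeric(intensity_g),
    responded = as.logical(responded),
    latency_s = as.numeric(latency_s),
    stringsAsFactors = FALSE
  )
  validate_stimulus_events(df)
  df[order(df$fly_id, df$zt_min, df$intensity_g), , drop = FALSE]
}

validate_stimulus_events <- function(df) {
  bad <- setdiff(df$protocol, c("escalating", "fixed"))
  if (length(bad)) stop("unknown protocol token(s): ", paste(bad, collapse = ", "))
  if (any(df$intensity_g < 0)) stop("intensity_g must be non-negative")
  if (any(df$responded & is.na(df$latency_s))) {
    stop("responded events must carry a latency")
  }
  if (any(!is.na(df$latency_s) & df$latency_s < 0)) {
    stop("latency_s must be non-negative")
  }
  invisible(df)
}
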