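#' @section Monitor-file dialect:
#' Activity monitor files are tab-separated text with one line per 1-minute
#' reading. Each line carries ten metadata fields -- reading index, date
#' (`"d Mon yy"`, English month abbreviations), time (`"HH:MM:SS"`), a status
#' field, and six auxiliary fields -- followed by 32 integer channel counts.
#' Timestamps must advance by exactly one minute per line; a gap is an error
#' unless zero-filling is requested.
#' @name dam-dialect
#' @keywords internal
NULL

.months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

parse_clock_hm <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))[[1]]
  if (length(m) != 3L) stop("clock time must be HH:MM, got: ", s)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23L || mi > 59L) stop("invalid clock time: ", s)
  h * 60L + mi
}

# absolute minute since 2000-01-01 00:00 for a monitor timestamp
dam_abs_minute <- function(date_str, time_str, line) {
  dparts <- strsplit(trimws(date_str), "[[:space:]]+")[[1]]
  mon <- match(dparts[2], .months)
  tm <- regmatches(time_str, regexec("^([0-9]{2}):([0-9]{2}):([0-9]{2})$",
                                     time_str))[[1]]
  if (length(dparts) != 3L || is.na(mon) || length(tm) != 4L) {
    stop(sprintf("line %d: malformed timestamp '%s %s'", line, date_str, time_str))
  }
  day <- suppressWarnings(as.integer(dparts[1]))
  yr <- suppressWarnings(as.integer(dparts[3])) + 2000L
  if (is.na(day) || is.na(yr)) {
    stop(sprintf("line %d: malformed date '%s'", line, date_str))
  }
  serial <- as.integer(as.Date(sprintf("%04d-%02d-%02d", yr, mon, day))) -
    as.integer(as.Date("2000-01-01"))
  h <- as.integer(tm[2]); mi <- as.integer(tm[3])
  serial * 1440L + h * 60L + mi
}

#' Read a 32-channel activity monitor file
#'
#' Parses the tab-separated monitor dialect (see the dialect note in
#' [write_dam_monitor()]) into one [activity_trace()] per non-empty channel.
#' The ZT anchor of each trace is computed from the file's first timestamp
#' and the supplied lights-on clock time.
#'
#' @param path Path to a monitor file.
#' @param lights_on Clock time of lights-on (ZT0) as `"HH:MM"`.
#' @param gap_fill If `TRUE`, gaps in the 1-minute timestamp sequence are
#'   filled with zero counts; if `FALSE` (default) a gap is an error.
#' @param drop_empty Drop channels whose counts are all zero (default). Set
#'   to `FALSE` to keep all 32 channels.
#' @param genotype Genotype label attached to every returned trace.
#' @return A list of [activity_trace()] objects named by channel id
#'   (`"ch01"` ... `"ch32"`).
#' @export
read_dam_monitor <- function(path, lights_on = "08:00", gap_fill = FALSE,
                             drop_empty = TRUE, genotype = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 42L)) {
    bad <- which(nf != 42L)[1]
    stop(sprintf("line %d: expected 42 tab-separated fields, found %d",
                 bad, nf[bad]))
  }
  mat <- do.call(rbind, fields)
  counts <- suppressWarnings(matrix(as.integer(mat[, 11:42, drop = FALSE]),
                                    nrow = nrow(mat)))
  if (anyNA(counts)) {
    bad <- which(rowSums(is.na(counts)) > 0L)[1]
    stop(sprintf("line %d: non-integer channel count", bad))
  }
  if (any(counts < 0L)) stop("negative channel count")
  abs_min <- vapply(seq_len(nrow(mat)),
                    function(i) dam_abs_minute(mat[i, 2], mat[i, 3], i),
                    integer(1))
  d <- diff(abs_min)
  if (any(d <= 0L)) {
    stop(sprintf("line %d: non-monotonic timestamp", which(d <= 0L)[1] + 1L))
  }
  if (any(d > 1L)) {
    if (!gap_fill) {
      stop(sprintf("line %d: %d-minute gap in timestamps (use gap_fill = TRUE to zero-fill)",
                   which(d > 1L)[1] + 1L, d[which(d > 1L)[1]]))
    }
    full <- seq(abs_min[1], abs_min[length(abs_min)])
    filled <- matrix(0L, nrow = length(full), ncol = 32L)
    filled[match(abs_min, full), ] <- counts
    counts <- filled
  }
  first_min_of_day <- abs_min[1] %% 1440L
  zt0 <- (first_min_of_day - parse_clock_hm(lights_on)) %% 1440L
  traces <- lapply(seq_len(32L), function(ch) {
    activity_trace(sprintf("ch%02d", ch), counts[, ch],
                   zt0_offset_min = zt0, genotype = genotype)
  })
  names(traces) <- sprintf("ch%02d", seq_len(32L))
  if (drop_empty) {
    traces <- traces[vapply(traces, function(tr) any(tr$counts > 0L), logical(1))]
  }
  traces
}

#' Write activity traces as a 32-channel monitor file
#'
#' Emits the exact dialect accepted by [read_dam_monitor()]: tab-separated
#' lines of ten metadata fields then 32 integer counts, one line per minute.
#' Traces are placed on channels 1, 2, ... in order; unused channels are
#' written as zeros.
#'
#' @param traces List of [activity_trace()] objects (at most 32), all of
#'   equal length and with a common `zt0_offset_min`.
#' @param path Output path.
#' @param lights_on Clock time of lights-on used to reconstruct timestamps.
#' @param start_date First calendar date of the recording (`Date` or
#'   `"YYYY-MM-DD"`); purely cosmetic, the analysis only uses ZT.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(traces, path, lights_on = "08:00",
                              start_date = "2024-01-01") {
  if (length(traces) == 0L) stop("no traces to write")
  if (length(traces) > 32L) stop("a monitor file holds at most 32 channels")
  stopifnot(all(vapply(traces, inherits, logical(1), "activity_trace")))
  n <- length(traces[[1]]$counts)
  if (!all(vapply(traces, function(tr) length(tr$counts), integer(1)) == n)) {
    stop("all traces must have equal length")
  }
  zt0 <- traces[[1]]$zt0_offset_min
  if (!all(vapply(traces, function(tr) tr$zt0_offset_min, integer(1)) == zt0)) {
    stop("all traces must share a common zt0_offset_min")
  }
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (i in seq_along(traces)) counts[, i] <- traces[[i]]$counts
  serial0 <- as.integer(as.Date(start_date)) - as.integer(as.Date("2000-01-01"))
  start_abs <- serial0 * 1440L + (parse_clock_hm(lights_on) + zt0) %% 1440L
  abs_min <- start_abs + seq_len(n) - 1L
  dser <- abs_min %/% 1440L
  dates <- as.Date("2000-01-01") + dser
  date_str <- sprintf("%d %s %02d",
                      as.integer(format(dates, "%d")),
                      .months[as.integer(format(dates, "%m"))],
                      as.integer(format(dates, "%Y")) %% 100L)
  mod <- abs_min %% 1440L
  time_str <- sprintf("%02d:%02d:00", mod %/% 60L, mod %% 60L)
  meta <- cbind(seq_len(n), date_str, time_str, 1L,
                matrix(0L, nrow = n, ncol = 6L))
  out <- apply(cbind(meta, counts), 1L, paste, collapse = "\t")
  writeLines(out, path)
  invisible(path)
}
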