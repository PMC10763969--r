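#' Read and write stimulus logs
#'
#' Stimulus logs are headered CSV with columns
#' `fly_id,zt_min,protocol,intensity_g,responded,latency_s`. `responded` is
#' coded 0/1 and `latency_s` may be empty only for non-responses.
#'
#' @param path Path to a CSV file.
#' @return For the reader, a stimulus-event `data.frame` (see
#'   [stimulus_events()]) sorted by (`fly_id`, `zt_min`, `intensity_g`);
#'   for the writer, `path` invisibly.
#' @export
read_stimulus_log <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    fly_id = "character", zt_min = "integer", protocol = "character",
    intensity_g = "numeric", responded = "integer", latency_s = "numeric"
  ))
  expected <- c("fly_id", "zt_min", "protocol", "intensity_g",
                "responded", "latency_s")
  if (!identical(names(df), expected)) {
    stop("stimulus log must have header: ", paste(expected, collapse = ","))
  }
  if (nrow(df) == 0L) {
    df$responded <- logical(0)
    return(df)
  }
  if (!all(df$responded %in% c(0L, 1L))) {
    stop("responded must be coded 0/1")
  }
  df$responded <- df$responded == 1L
  validate_stimulus_events(df)
  df <- df[order(df$fly_id, df$zt_min, df$intensity_g), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_stimulus_log
#' @param events A stimulus-event `data.frame`.
#' @export
write_stimulus_log <- function(events, path) {
  validate_stimulus_events(events)
  out <- events
  out$responded <- as.integer(out$responded)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write VCO2 tables
#'
#' VCO2 tables are headered CSV with columns `fly_id,bin_index,vco2`; bin
#' indices per fly must be consecutive from 0. Bin width and ZT anchor are
#' recording-level settings supplied by the caller.
#'
#' @param path Path to a CSV file.
#' @param bin_min Bin width in minutes attached to each returned trace.
#' @param zt0_offset_min ZT anchor attached to each returned trace.
#' @return For the reader, a named list of [metabolic_trace()] objects (one
#'   per `fly_id`); for the writer, `path` invisibly.
#' @export
read_vco2_table <- function(path, bin_min = 5L, zt0_offset_min = 0L) {
  df <- utils::read.csv(path, colClasses = c(
    fly_id = "character", bin_index = "integer", vco2 = "numeric"
  ))
  if (!identical(names(df), c("fly_id", "bin_index", "vco2"))) {
    stop("VCO2 table must have header: fly_id,bin_index,vco2")
  }
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  if (anyNA(df$vco2) || any(df$vco2 < 0)) stop("negative or missing vco2 value")
  traces <- lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$bin_index), , drop = FALSE]
    if (!identical(d$bin_index, seq_len(nrow(d)) - 1L)) {
      stop("bin indices for fly ", d$fly_id[1],
           " must be consecutive from 0 (missing or duplicated bin)")
    }
    metabolic_trace(d$fly_id[1], d$vco2, bin_min = bin_min,
                    zt0_offset_min = zt0_offset_min)
  })
  traces[order(names(traces))]
}

#' @rdname read_vco2_table
#' @param mtraces A list of [metabolic_trace()] objects.
#' @export
write_vco2_table <- function(mtraces, path) {
  stopifnot(all(vapply(mtraces, inherits, logical(1), "metabolic_trace")))
  df <- do.call(rbind, lapply(mtraces, function(m) {
    data.frame(fly_id = m$fly_id, bin_index = seq_along(m$vco2) - 1L,
               vco2 = m$vco2, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(fly_id = character(), bin_index = integer(),
                                    vco2 = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
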