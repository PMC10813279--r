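#' Epoch-level actigraphy series
#'
#' The canonical per-participant container: a uniformly spaced, timezone-naive
#' grid of epochs (default 60 s) carrying up to four channels -- motor
#' activity in PIM counts (`activity_pim`), wrist skin temperature in deg C
#' (`wrist_temp`), illuminance in lux (`lux`) and blue-light irradiance in
#' uW/cm^2 (`blue`) -- together with a per-epoch validity flag and optional
#' diary events (e.g. bedtime / waketime button presses).
#'
#' Masked (invalid) epochs are carried on the grid so spacing stays uniform,
#' but are excluded from every downstream mean, variance, fit and index.
#'
#' @param participant_id Opaque participant identifier.
#' @param start_time Timestamp of the first epoch (`POSIXct` or a string
#'   parseable as `"%Y-%m-%dT%H:%M:%S"`); interpreted as local clock time,
#'   no timezone arithmetic is ever applied.
#' @param channels Named list or data.frame of equal-length numeric vectors;
#'   recognised names: `activity_pim`, `wrist_temp`, `lux`, `blue`.
#' @param epoch_length Epoch length in seconds (default 60).
#' @param valid Logical vector, `TRUE` for usable epochs. Defaults to
#'   non-missing rows. Epochs with any `NA` channel value are forced invalid.
#' @param events Optional data.frame with columns `time` (`POSIXct`) and
#'   `label` (character), e.g. diary markers `"bedtime"` / `"waketime"`.
#'
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, start_time, channels,
                         epoch_length = 60, valid = NULL, events = NULL) {
  alx_check(is.character(participant_id) && length(participant_id) == 1L,
            "participant_id must be a single string")
  start_time <- as_naive_time(start_time)
  alx_check(length(start_time) == 1L && !is.na(start_time),
            "start_time must be a single parseable timestamp")
  alx_check(is.numeric(epoch_length) && length(epoch_length) == 1L &&
              epoch_length > 0,
            "epoch_length must be a positive number of seconds")

  known <- c("activity_pim", "wrist_temp", "lux", "blue")
  channels <- as.list(channels)
  alx_check(length(channels) >= 1L && !is.null(names(channels)) &&
              all(nzchar(names(channels))),
            "channels must be a named list with at least one channel")
  bad <- setdiff(names(channels), known)
  alx_check(length(bad) == 0L,
            paste0("unknown channel(s): ", paste(bad, collapse = ", ")),
            "actilux_lookup_error")
  lens <- vapply(channels, length, integer(1))
  alx_check(length(unique(lens)) == 1L,
            "all channel arrays must have equal length",
            "actilux_integrity_error")
  n <- lens[[1]]
  alx_check(n >= 1L, "series must contain at least one epoch",
            "actilux_format_error")
  channels <- lapply(channels, as.numeric)

  if (is.null(valid)) valid <- rep(TRUE, n)
  alx_check(is.logical(valid) && length(valid) == n,
            "valid must be a logical vector matching the epoch count")
  any_na <- Reduce(`|`, lapply(channels, is.na), rep(FALSE, n))
  valid <- valid & !any_na

  for (ch in intersect(c("lux", "blue"), names(channels))) {
    neg <- valid & channels[[ch]] < 0
    alx_check(!any(neg),
              paste0("channel '", ch, "' has negative values at unmasked epochs"),
              "actilux_integrity_error")
  }

  if (!is.null(events)) {
    events <- as.data.frame(events)
    alx_check(all(c("time", "label") %in% names(events)),
              "events must have columns 'time' and 'label'",
              "actilux_format_error")
    events$time <- as_naive_time(events$time)
    events$label <- as.character(events$label)
    events <- events[order(events$time), c("time", "label"), drop = FALSE]
    rownames(events) <- NULL
  }

  structure(
    list(participant_id = participant_id,
         start_time = start_time,
         epoch_length = as.numeric(epoch_length),
         channels = channels,
         valid = valid,
         events = events),
    class = "epoch_series"
  )
}

# Parse timestamps as timezone-naive local clock time (stored as UTC POSIXct
# purely as an arithmetic carrier; no offsets are ever applied).
as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

format_naive_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @export
print.epoch_series <- function(x, ...) {
  cat("<epoch_series> participant", x$participant_id, "\n")
  cat("  start:", format_naive_time(x$start_time),
      " epochs:", n_epochs(x),
      sprintf("(%.0f s each, %.2f d)", x$epoch_length,
              n_epochs(x) * x$epoch_length / 86400), "\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  masked epochs:", sum(!x$valid), "\n")
  if (!is.null(x$events)) cat("  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Number of epochs in a series
#' @param series An `epoch_series`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(series) length(series$valid)

#' Epoch timestamps of a series
#' @param series An `epoch_series`.
#' @return `POSIXct` vector, one timestamp per epoch (start of epoch).
#' @export
epoch_times <- function(series) {
  series$start_time + (seq_len(n_epochs(series)) - 1) * series$epoch_length
}

#' Clock time of each epoch in fractional hours since local midnight
#' @param series An `epoch_series`.
#' @return Numeric vector in `[0, 24)`.
#' @export
clock_hours <- function(series) {
  tt <- as.numeric(epoch_times(series)) %% 86400
  tt / 3600
}

#' Elapsed time of each epoch in hours since the first epoch
#' @param series An `epoch_series`.
#' @return Numeric vector starting at 0.
#' @export
elapsed_hours <- function(series) {
  (seq_len(n_epochs(series)) - 1) * series$epoch_length / 3600
}

get_channel <- function(series, channel) {
  alx_check(channel %in% names(series$channels),
            paste0("channel '", channel, "' not present in series"),
            "actilux_lookup_error")
  series$channels[[channel]]
}
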