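#' Column-mapping dialect for delimited epoch files
#'
#' Wearable exports differ in column naming, delimiter and decimal mark;
#' a dialect maps them onto the canonical [epoch_series()] model instead of
#' guessing any one device's layout.
#'
#' @param sep Field delimiter (default `","`).
#' @param dec Decimal mark (default `"."`).
#' @param timestamp Name of the timestamp column.
#' @param activity_pim,wrist_temp,lux,blue Channel column names; set a channel
#'   to `NULL` to skip it (at least one channel column is required).
#' @param valid Optional name of a logical validity column (`TRUE`/`FALSE`);
#'   absent from most raw exports, written by [write_epoch_series()].
#' @param epoch_length Expected epoch length in seconds; `NULL` (default)
#'   infers it from the first timestamp difference.
#' @return A list of class `epoch_dialect`.
#' @export
epoch_dialect <- function(sep = ",", dec = ".", timestamp = "timestamp",
                          activity_pim = "activity_pim",
                          wrist_temp = "wrist_temp",
                          lux = "lux", blue = "blue",
                          valid = NULL, epoch_length = NULL) {
  structure(list(sep = sep, dec = dec, timestamp = timestamp,
                 activity_pim = activity_pim, wrist_temp = wrist_temp,
                 lux = lux, blue = blue, valid = valid,
                 epoch_length = epoch_length),
            class = "epoch_dialect")
}

#' Read a delimited-text epoch file into an `epoch_series`
#'
#' Rows with unparseable channel values become masked epochs; gaps in the
#' timestamp grid are filled with masked epochs so spacing stays uniform.
#' Duplicated or non-monotonic timestamps and off-grid rows are integrity
#' errors (they indicate a corrupt export, not missing data).
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect An [epoch_dialect()] mapping column names.
#' @param participant_id Participant identifier; defaults to the file name
#'   without extension.
#' @param events Optional data.frame of diary events (`time`, `label`), e.g.
#'   from [read_events()].
#' @return An [epoch_series()].
#' @export
read_epoch_series <- function(path, dialect = epoch_dialect(),
                              participant_id = NULL, events = NULL) {
  alx_check(file.exists(path), paste0("file not found: ", path),
            "actilux_format_error")
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = dialect$sep, dec = dialect$dec,
               colClasses = "character", check.names = FALSE,
               strip.white = TRUE, comment.char = ""),
    error = function(e) alx_abort(paste0("cannot parse '", path, "': ",
                                         conditionMessage(e)),
                                  "actilux_format_error"))
  if (nrow(raw) == 0L)
    alx_abort("epoch file is empty (no data rows)", "actilux_format_error")

  chan_names <- c("activity_pim", "wrist_temp", "lux", "blue")
  wanted <- c(timestamp = dialect$timestamp,
              unlist(dialect[chan_names]))
  missing_cols <- setdiff(unname(wanted), names(raw))
  if (length(missing_cols) > 0L)
    alx_abort(paste0("missing required column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "actilux_format_error")

  ts <- as_naive_time(raw[[dialect$timestamp]])
  if (anyNA(ts))
    alx_abort("unparseable timestamp(s) in epoch file",
              "actilux_integrity_error")
  d <- diff(as.numeric(ts))
  if (any(d <= 0))
    alx_abort("timestamps must be strictly increasing (duplicate or reversed rows)",
              "actilux_integrity_error")

  epoch_length <- dialect$epoch_length
  if (is.null(epoch_length))
    epoch_length <- if (length(d) > 0) min(d) else 60
  off <- round((as.numeric(ts) - as.numeric(ts[1])) / epoch_length)
  if (any(abs((as.numeric(ts) - as.numeric(ts[1])) - off * epoch_length) > 1e-6))
    alx_abort("timestamps do not lie on a uniform epoch grid",
              "actilux_integrity_error")

  n <- off[length(off)] + 1
  idx <- off + 1
  parse_num <- function(x) {
    if (!identical(dialect$dec, ".")) x <- gsub(dialect$dec, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  channels <- list()
  for (ch in chan_names) {
    col <- dialect[[ch]]
    if (is.null(col)) next
    v <- rep(NA_real_, n)
    v[idx] <- parse_num(raw[[col]])
    channels[[ch]] <- v
  }
  alx_check(length(channels) >= 1L, "dialect maps no channel columns",
            "actilux_format_error")

  valid <- rep(FALSE, n)
  valid[idx] <- TRUE
  if (!is.null(dialect$valid) && dialect$valid %in% names(raw))
    valid[idx] <- valid[idx] & as.logical(raw[[dialect$valid]])

  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))

  epoch_series(participant_id = participant_id, start_time = ts[1],
               channels = channels, epoch_length = epoch_length,
               valid = valid, events = events)
}

#' Write an `epoch_series` to canonical CSV
#'
#' One row per epoch, ISO-8601 timestamps without offset, a `valid` column,
#' and channel values printed with enough digits for an exact round trip
#' through [read_epoch_series()].
#'
#' @param series An [epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_series <- function(series, path) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  df <- data.frame(timestamp = format_naive_time(epoch_times(series)),
                   stringsAsFactors = FALSE)
  for (ch in names(series$channels)) df[[ch]] <- fmt(series$channels[[ch]])
  df$valid <- ifelse(series$valid, "TRUE", "FALSE")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column diary events file
#'
#' @param path CSV with columns `time` (ISO-8601 local timestamp) and `label`.
#' @return data.frame with `POSIXct` `time` and character `label`.
#' @export
read_events <- function(path) {
  alx_check(file.exists(path), paste0("file not found: ", path),
            "actilux_format_error")
  ev <- read.table(path, header = TRUE, sep = ",", colClasses = "character",
                   strip.white = TRUE)
  alx_check(all(c("time", "label") %in% names(ev)),
            "events file must have columns 'time' and 'label'",
            "actilux_format_error")
  tt <- as_naive_time(ev$time)
  alx_check(!anyNA(tt), "unparseable timestamps in events file",
            "actilux_integrity_error")
  data.frame(time = tt, label = ev$label, stringsAsFactors = FALSE)
}
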