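#' Cole-style sleep/wake scoring of 1-minute activity counts
#'
#' Weighted moving window over the activity series,
#' \deqn{D_t = 0.001 (106 a_{t-4} + 54 a_{t-3} + 58 a_{t-2} + 76 a_{t-1} +
#'   230 a_t + 74 a_{t+1} + 67 a_{t+2})}
#' with \eqn{a = \mathrm{activity}/\mathrm{scale}} and zero padding at the
#' boundaries; an epoch is scored sleep iff \eqn{D_t < 1}. The published
#' weights assume a particular count magnitude, so `scale` converts
#' device-specific counts (PIM counts here) onto that magnitude.
#'
#' @param activity Per-minute activity counts (numeric; `NA` treated as 0 for
#'   the moving sum, i.e. masked epochs do not wake their neighbours).
#' @param scale Positive conversion factor applied to counts (default 100).
#' @return Logical vector, `TRUE` = sleep.
#' @export
cole_score <- function(activity, scale = 100) {
  alx_check(is.numeric(scale) && length(scale) == 1L && scale > 0,
            "scale must be a single positive number")
  a <- as.numeric(activity) / scale
  a[is.na(a)] <- 0
  n <- length(a)
  shift <- function(x, k) {
    # value at t + k, zero-padded
    if (k == 0) return(x)
    if (k > 0) c(x[-seq_len(k)], rep(0, k)) else c(rep(0, -k), x[seq_len(n + k)])
  }
  w <- c(106, 54, 58, 76, 230, 74, 67)
  off <- -4:2
  D <- rep(0, n)
  for (j in seq_along(w)) D <- D + w[j] * shift(a, off[j])
  D <- 0.001 * D
  D < 1
}

#' A diary-anchored rest interval
#'
#' @param bedtime,waketime Timestamps (`POSIXct` or parseable strings);
#'   `waketime` must follow `bedtime` by less than 24 h.
#' @param source `"diary_event"` or `"config_default"`.
#' @return List of class `rest_interval`.
#' @export
rest_interval <- function(bedtime, waketime,
                          source = c("diary_event", "config_default")) {
  source <- match.arg(source)
  bedtime <- as_naive_time(bedtime); waketime <- as_naive_time(waketime)
  alx_check(!is.na(bedtime) && !is.na(waketime), "unparseable interval times",
            "actilux_format_error")
  len <- as.numeric(waketime) - as.numeric(bedtime)
  alx_check(len > 0, "waketime must be after bedtime",
            "actilux_integrity_error")
  alx_check(len < 86400, "rest interval must be shorter than 24 h",
            "actilux_integrity_error")
  structure(list(bedtime = bedtime, waketime = waketime, source = source),
            class = "rest_interval")
}

#' Pair diary events into nightly rest intervals
#'
#' Walks the event list in time order and pairs each `bedtime` marker with
#' the next `waketime` marker; unpaired markers are dropped with a warning.
#'
#' @param events data.frame with `time`, `label`
#'   (labels `"bedtime"` / `"waketime"`).
#' @return List of [rest_interval()] objects.
#' @export
rest_intervals_from_events <- function(events) {
  alx_check(is.data.frame(events) && all(c("time", "label") %in% names(events)),
            "events must have columns 'time' and 'label'",
            "actilux_format_error")
  ev <- events[order(events$time), ]
  out <- list()
  pending_bed <- NULL
  for (i in seq_len(nrow(ev))) {
    lab <- ev$label[i]
    if (lab == "bedtime") {
      pending_bed <- ev$time[i]
    } else if (lab == "waketime" && !is.null(pending_bed)) {
      out[[length(out) + 1L]] <- rest_interval(pending_bed, ev$time[i],
                                               "diary_event")
      pending_bed <- NULL
    }
  }
  if (length(out) == 0L)
    warning("no bedtime/waketime pairs found in events")
  out
}

#' Summarise one night of scored sleep
#'
#' Sleep onset is the start of the first run of at least `onset_rule`
#' consecutive sleep-scored minutes at or after bedtime. Total sleep time
#' (TST) and wake after sleep onset (WASO) partition the span from onset to
#' waketime exactly; sleep efficiency is 100 TST / time-in-bed; sleep phase
#' is the clock midpoint of bedtime and waketime.
#'
#' @param flags Logical sleep flags (`TRUE` = sleep), one per minute.
#' @param times `POSIXct` timestamps aligned with `flags`.
#' @param interval A [rest_interval()].
#' @param onset_rule Minimum consecutive sleep minutes defining onset
#'   (default 5).
#' @return One-row data.frame of class `sleep_night`: `status` (`"ok"` or
#'   `"unscorable"`), `bedtime`, `waketime`, `time_in_bed`,
#'   `sleep_onset`, `sleep_latency`, `total_sleep_time`, `waso`,
#'   `sleep_efficiency`, `sleep_phase` (fractional hours). Durations are in
#'   minutes. An unscorable night (no qualifying sleep run) carries `NA`
#'   summaries, never silent zeros.
#' @export
summarize_night <- function(flags, times, interval, onset_rule = 5) {
  alx_check(inherits(interval, "rest_interval"), "interval must be a rest_interval")
  alx_check(length(flags) == length(times), "flags and times must align")
  alx_check(is.numeric(onset_rule) && onset_rule >= 1,
            "onset_rule must be >= 1")

  sel <- times >= interval$bedtime & times < interval$waketime
  f <- flags[sel]
  tib <- as.numeric(interval$waketime - interval$bedtime, units = "mins")
  phase <- (((as.numeric(interval$bedtime) %% 86400) / 3600) +
              tib / 120) %% 24

  base <- data.frame(
    bedtime = format_naive_time(interval$bedtime),
    waketime = format_naive_time(interval$waketime),
    time_in_bed = tib,
    sleep_phase = phase,
    stringsAsFactors = FALSE
  )
  if (length(f) == 0L) {
    out <- cbind(data.frame(status = "unscorable"), base,
                 data.frame(sleep_onset = NA_character_,
                            sleep_latency = NA_real_, total_sleep_time = NA_real_,
                            waso = NA_real_, sleep_efficiency = NA_real_))
    class(out) <- c("sleep_night", "data.frame")
    return(out)
  }

  r <- rle(f)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  cand <- which(r$values & r$lengths >= onset_rule)
  if (length(cand) == 0L) {
    out <- cbind(data.frame(status = "unscorable"), base,
                 data.frame(sleep_onset = NA_character_,
                            sleep_latency = NA_real_, total_sleep_time = NA_real_,
                            waso = NA_real_, sleep_efficiency = NA_real_))
    class(out) <- c("sleep_night", "data.frame")
    return(out)
  }
  onset_idx <- run_start[cand[1]]
  onset_time <- times[sel][onset_idx]
  latency <- as.numeric(onset_time - interval$bedtime, units = "mins")
  after <- f[onset_idx:length(f)]
  tst <- sum(after)
  waso <- sum(!after)
  se <- 100 * tst / tib

  out <- cbind(data.frame(status = "ok"), base,
               data.frame(sleep_onset = format_naive_time(onset_time),
                          sleep_latency = latency, total_sleep_time = tst,
                          waso = waso, sleep_efficiency = se))
  class(out) <- c("sleep_night", "data.frame")
  out
}

#' Score and summarise every night of a series
#'
#' Applies [cole_score()] to the activity channel (1-min epochs required)
#' and [summarize_night()] within each rest interval. Intervals default to
#' the series' diary events; when no events are present, a configured
#' default clock window is replicated over all recorded nights.
#'
#' @param series An [epoch_series()] with an `activity_pim` channel at 60 s
#'   epochs.
#' @param intervals Optional list of [rest_interval()]; defaults to
#'   [rest_intervals_from_events()] on `series$events`, falling back to
#'   `default_window`.
#' @param scale Passed to [cole_score()].
#' @param onset_rule Passed to [summarize_night()].
#' @param default_window Fallback clock window `c(bedtime, waketime)` in
#'   `"HH:MM"` (waketime on the next day).
#' @return data.frame, one row per night (see [summarize_night()]) plus a
#'   `participant_id` column.
#' @export
score_sleep <- function(series, intervals = NULL, scale = 100,
                        onset_rule = 5, default_window = c("23:00", "07:00")) {
  if (abs(series$epoch_length - 60) > 1e-9)
    alx_abort("sleep scoring requires 1-min epochs; resample the series first",
              "actilux_resolution_error")
  if (is.null(intervals)) {
    if (!is.null(series$events) &&
        any(series$events$label %in% c("bedtime", "waketime"))) {
      intervals <- rest_intervals_from_events(series$events)
    } else {
      intervals <- default_rest_intervals(series, default_window)
    }
  }
  alx_check(length(intervals) >= 1L, "no rest intervals to score",
            "actilux_insufficient_data_error")

  flags <- cole_score(ifelse(series$valid, series$channels$activity_pim, NA),
                      scale = scale)
  times <- epoch_times(series)
  nights <- lapply(intervals, function(iv)
    summarize_night(flags, times, iv, onset_rule = onset_rule))
  out <- do.call(rbind, nights)
  out <- cbind(data.frame(participant_id = series$participant_id,
                          night = seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# Replicate a default clock rest window over all nights covered by the series.
default_rest_intervals <- function(series, window = c("23:00", "07:00")) {
  parse_clock <- function(s) {
    p <- as.integer(strsplit(s, ":")[[1]])
    p[1] + p[2] / 60
  }
  bed_h <- parse_clock(window[1]); wake_h <- parse_clock(window[2])
  t0 <- as.numeric(series$start_time)
  t1 <- t0 + n_epochs(series) * series$epoch_length
  day0 <- floor(t0 / 86400)
  day1 <- floor(t1 / 86400)
  out <- list()
  for (d in day0:day1) {
    bed <- d * 86400 + bed_h * 3600
    wake_off <- if (wake_h <= bed_h) 1 else 0
    wake <- (d + wake_off) * 86400 + wake_h * 3600
    if (bed >= t0 && wake <= t1) {
      out[[length(out) + 1L]] <- rest_interval(
        as.POSIXct(bed, origin = "1970-01-01", tz = "UTC"),
        as.POSIXct(wake, origin = "1970-01-01", tz = "UTC"),
        "config_default")
    }
  }
  out
}
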