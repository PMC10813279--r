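#' Floored log10 transform for irradiance data
#'
#' Device zeros make a plain log10 undefined; values are floored at a small
#' positive irradiance first. The default floor (0.01 uW/cm^2) sits below the
#' lowest hygiene anchor (0.1 uW/cm^2) so no recommendation-relevant level is
#' ever clipped.
#'
#' @param x Irradiance values (uW/cm^2), non-negative.
#' @param floor Positive floor applied before the log (uW/cm^2).
#' @return `log10(pmax(x, floor))`.
#' @export
log10_floor <- function(x, floor = 0.01) {
  alx_check(is.numeric(floor) && length(floor) == 1L && floor > 0,
            "floor must be a single positive number")
  log10(pmax(x, floor))
}

#' Clock-aligned mean daily profile of one channel
#'
#' Averages all unmasked epochs of all recorded days into bins of the local
#' clock day (48 x 30 min by default; bin 0 starts at 00:00). The default is
#' pool-then-mean: every unmasked epoch across days is pooled into its clock
#' bin and averaged once, which is robust to partial days. `per_day = TRUE`
#' switches to per-day bin means averaged across days.
#'
#' @param series An [epoch_series()].
#' @param channel Channel label.
#' @param transform `"raw"` or `"log10"` (floored log10, see [log10_floor()]).
#' @param bin_minutes Bin width in minutes; must divide 1440 (default 30).
#' @param floor Floor used when `transform = "log10"`.
#' @param per_day If `TRUE`, average per-day bin means instead of pooling.
#' @return A data.frame of class `daily_profile` with columns `bin`,
#'   `start_hour`, `mid_hour`, `mean`, `n_contrib`, `missing`; bins with no
#'   contributing epochs are flagged `missing` (mean `NA`), never imputed.
#'   Channel, transform, bin width and participant id travel as attributes.
#' @export
bin_daily_profile <- function(series, channel, transform = c("raw", "log10"),
                              bin_minutes = 30, floor = 0.01,
                              per_day = FALSE) {
  transform <- match.arg(transform)
  alx_check(1440 %% bin_minutes == 0,
            "bin_minutes must divide 1440")
  x <- get_channel(series, channel)
  alx_check(any(series$valid), "series has no unmasked epochs",
            "actilux_insufficient_data_error")
  if (transform == "log10") x <- log10_floor(x, floor)

  n_bins <- as.integer(1440 / bin_minutes)
  ch <- clock_hours(series)
  bin <- floor(ch * 60 / bin_minutes) %% n_bins
  keep <- series$valid
  xb <- x[keep]
  bb <- bin[keep]

  n_contrib <- tabulate(bb + 1L, nbins = n_bins)
  if (per_day) {
    day <- floor(as.numeric(epoch_times(series)) / 86400)[keep]
    dm <- stats::aggregate(list(x = xb), list(b = bb, d = day), mean)
    means <- as.numeric(tapply(dm$x, factor(dm$b, levels = 0:(n_bins - 1)),
                               mean))
  } else {
    sums <- rep(0, n_bins)
    agg <- tapply(xb, factor(bb, levels = 0:(n_bins - 1)), sum)
    sums[!is.na(agg)] <- agg[!is.na(agg)]
    means <- ifelse(n_contrib > 0, sums / n_contrib, NA_real_)
  }

  out <- data.frame(
    bin = 0:(n_bins - 1),
    start_hour = (0:(n_bins - 1)) * bin_minutes / 60,
    mid_hour = ((0:(n_bins - 1)) + 0.5) * bin_minutes / 60,
    mean = means,
    n_contrib = n_contrib,
    missing = n_contrib == 0
  )
  structure(out,
            class = c("daily_profile", "data.frame"),
            channel = channel, transform = transform,
            bin_minutes = bin_minutes,
            participant_id = series$participant_id)
}

#' Write a daily profile to CSV
#' @param profile A [bin_daily_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$participant_id <- attr(profile, "participant_id")
  df$channel <- attr(profile, "channel")
  df$transform <- attr(profile, "transform")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stack per-participant profiles into a participants x bins matrix
#'
#' @param profiles Named list of `daily_profile` objects on an identical bin
#'   grid (names become row names).
#' @return Numeric matrix, one row per participant, one column per bin;
#'   missing bins are `NA`.
#' @export
profile_matrix <- function(profiles) {
  alx_check(length(profiles) >= 1L, "need at least one profile")
  nb <- vapply(profiles, nrow, integer(1))
  alx_check(length(unique(nb)) == 1L,
            "profiles must share one bin grid", "actilux_integrity_error")
  m <- do.call(rbind, lapply(profiles, function(p) p$mean))
  if (!is.null(names(profiles))) rownames(m) <- names(profiles)
  colnames(m) <- paste0("bin", seq_len(ncol(m)) - 1)
  m
}
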