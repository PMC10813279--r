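#' Non-parametric rest--activity indices
#'
#' Classical non-parametric characterisation of a circadian record:
#' inter-daily stability (IS), intra-daily variability (IV), the most-active
#' 10 h (M10) and least-active 5 h (L5) windows with their clock onsets,
#' relative amplitude RA = (M10 - L5)/(M10 + L5), and the circadian function
#' index CFI = (IS + (2 - IV)/2 + RA)/3 with the IV term clipped to `[0, 1]`.
#'
#' IS and IV are computed on hourly means (the field convention), with
#' \deqn{IS = N \sum_h (\bar x_h - \bar x)^2 / (24 \sum_i (x_i - \bar x)^2)}
#' over the N hourly values and 24 clock-hour classes, and IV the mean
#' squared successive difference of the hourly sequence divided by its
#' variance (`basis = "epoch"` uses raw epochs instead). M10/L5 are found by
#' exhaustive wrap-around window search over the mean daily profile at epoch
#' resolution, ties broken by the earliest clock onset.
#'
#' @param series An [epoch_series()] with at least 24 h of data.
#' @param channel Channel label.
#' @param basis `"hourly"` (default) or `"epoch"` for the IS/IV aggregation.
#' @return List of class `nonparam_indices`: `is_`, `iv`, `m10`, `m10_onset`,
#'   `l5`, `l5_onset`, `ra`, `cfi`, `basis`.
#' @export
nonparametric_indices <- function(series, channel,
                                  basis = c("hourly", "epoch")) {
  basis <- match.arg(basis)
  x <- get_channel(series, channel)
  alx_check(n_epochs(series) * series$epoch_length >= 86400,
            "need at least 24 h of data", "actilux_insufficient_data_error")

  xv <- ifelse(series$valid, x, NA_real_)
  if (basis == "hourly") {
    hour_idx <- floor((seq_len(n_epochs(series)) - 1) *
                        series$epoch_length / 3600)
    seq_vals <- as.numeric(tapply(xv, hour_idx, mean, na.rm = TRUE))
    seq_vals[is.nan(seq_vals)] <- NA_real_
    # clock-hour class of each sequential hour
    start_hour <- floor((as.numeric(series$start_time) %% 86400) / 3600)
    classes <- (start_hour + seq_along(seq_vals) - 1) %% 24
  } else {
    seq_vals <- xv
    per_day <- round(86400 / series$epoch_length)
    classes <- round((as.numeric(epoch_times(series)) %% 86400) /
                       series$epoch_length) %% per_day
  }
  ok <- !is.na(seq_vals)
  vals <- seq_vals[ok]
  N <- length(vals)
  alx_check(N >= 24, "too few hourly values for IS/IV",
            "actilux_insufficient_data_error")
  xbar <- mean(vals)
  ss <- sum((vals - xbar)^2)
  if (ss <= .Machine$double.eps * N * max(1, xbar^2))
    alx_abort("channel has zero variance; IS/IV are undefined",
              "actilux_degenerate_error")

  p <- if (basis == "hourly") 24 else round(86400 / series$epoch_length)
  class_means <- tapply(vals, factor(classes[ok], levels = 0:(p - 1)),
                        mean)
  class_means <- class_means[!is.na(class_means)]
  is_ <- N * sum((class_means - xbar)^2) / (p * ss)

  # successive differences over adjacent (gap-free) pairs
  adj <- which(ok[-1] & ok[-length(ok)])
  d2 <- (seq_vals[adj + 1] - seq_vals[adj])^2
  alx_check(length(d2) >= 1, "no adjacent pairs for IV",
            "actilux_insufficient_data_error")
  iv <- mean(d2) / (ss / N)

  mp <- mean_clock_profile(series, channel)
  w10 <- best_window(mp$mean, round(10 * 3600 / series$epoch_length), max)
  w5 <- best_window(mp$mean, round(5 * 3600 / series$epoch_length), min)
  epoch_h <- series$epoch_length / 3600
  m10 <- w10$value; m10_onset <- (w10$start - 1) * epoch_h
  l5 <- w5$value; l5_onset <- (w5$start - 1) * epoch_h
  ra <- if ((m10 + l5) > 0) (m10 - l5) / (m10 + l5) else 0
  cfi <- (is_ + min(max((2 - iv) / 2, 0), 1) + ra) / 3

  structure(list(is_ = is_, iv = iv, m10 = m10, m10_onset = m10_onset,
                 l5 = l5, l5_onset = l5_onset, ra = ra, cfi = cfi,
                 basis = basis, channel = channel),
            class = "nonparam_indices")
}

#' @export
print.nonparam_indices <- function(x, ...) {
  cat(sprintf("<nonparam_indices> channel %s (basis %s)\n", x$channel, x$basis))
  cat(sprintf("  IS %.3f  IV %.3f  RA %.3f  CFI %.3f\n",
              x$is_, x$iv, x$ra, x$cfi))
  cat(sprintf("  M10 %.4g at %s  L5 %.4g at %s\n",
              x$m10, hours_to_hhmm(x$m10_onset),
              x$l5, hours_to_hhmm(x$l5_onset)))
  invisible(x)
}

# Mean value per clock epoch across days (wrap-around daily profile at the
# epoch resolution), unmasked epochs only.
mean_clock_profile <- function(series, channel) {
  x <- get_channel(series, channel)
  per_day <- round(86400 / series$epoch_length)
  slot <- (round((as.numeric(epoch_times(series)) %% 86400) /
                   series$epoch_length)) %% per_day
  keep <- series$valid
  sums <- rep(0, per_day)
  agg_s <- tapply(x[keep], factor(slot[keep], levels = 0:(per_day - 1)), sum)
  agg_n <- tabulate(slot[keep] + 1L, nbins = per_day)
  sums[!is.na(agg_s)] <- agg_s[!is.na(agg_s)]
  list(mean = ifelse(agg_n > 0, sums / agg_n, NA_real_), n = agg_n)
}

# Exhaustive circular window search: window of `w` epochs maximising
# (`which_fun = max`) or minimising (`min`) the window mean; first index in
# clock order wins ties.  NA slots propagate: windows touching an all-masked
# clock slot are skipped.
best_window <- function(profile, w, which_fun) {
  n <- length(profile)
  alx_check(w >= 1 && w <= n, "window longer than profile")
  ext <- c(profile, profile[seq_len(w - 1)])
  means <- vapply(seq_len(n), function(s) mean(ext[s:(s + w - 1)]), numeric(1))
  if (all(is.na(means)))
    alx_abort("no evaluable window (all contain missing clock slots)",
              "actilux_insufficient_data_error")
  target <- which_fun(means, na.rm = TRUE)
  start <- which(means == target)[1]
  list(value = target, start = start)
}
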