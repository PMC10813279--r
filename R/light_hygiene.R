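# D65 melanopic conversion: 1 lx melanopic EDI corresponds to
# 1.3262 mW/m^2 of melanopic irradiance = 0.13262 uW/cm^2.
MEDI_UW_CM2_PER_LX <- 0.13262

#' Convert melanopic EDI (lx) to melanopic irradiance (uW/cm^2)
#'
#' Uses the D65 melanopic efficacy: 1 lx mEDI = 1.3262 mW/m^2 =
#' 0.13262 uW/cm^2. Hence 250 lx ~ 33 uW/cm^2, 10 lx ~ 1.33 uW/cm^2 and
#' 1 lx ~ 0.13 uW/cm^2.
#'
#' @param medi Melanopic EDI in lux (non-negative).
#' @return Melanopic irradiance in uW/cm^2.
#' @seealso [irradiance_to_medi()]
#' @export
medi_to_irradiance <- function(medi) {
  alx_check(all(medi >= 0, na.rm = TRUE), "mEDI must be non-negative",
            "actilux_parameter_error")
  medi * MEDI_UW_CM2_PER_LX
}

#' Convert melanopic irradiance (uW/cm^2) to melanopic EDI (lx)
#' @param irradiance Melanopic irradiance in uW/cm^2 (non-negative).
#' @return Melanopic EDI in lux.
#' @export
irradiance_to_medi <- function(irradiance) {
  alx_check(all(irradiance >= 0, na.rm = TRUE),
            "irradiance must be non-negative", "actilux_parameter_error")
  irradiance / MEDI_UW_CM2_PER_LX
}

#' Recommendation-anchored blue-light reference curve
#'
#' A continuous 24 h target curve for melanopic blue-light irradiance built
#' from three published hygiene anchors: at least 250 lx mEDI
#' (33 uW/cm^2) during daytime, at most 10 lx mEDI (1.33 uW/cm^2) in the
#' pre-bed evening, and under 1 lx mEDI (printed anchor 0.1 uW/cm^2) during
#' sleep. The default shape is a reconstruction:
#'
#' * daytime (`day_start`--`day_end`): half-sine arc
#'   \eqn{P\sin(\pi (t - 6)/14)} with \eqn{P} chosen so the arc crosses the
#'   daytime target at `day_anchor` (09:00) and its mirror hour (17:00),
#'   floored at the pre-bed ceiling so the curve stays continuous into the
#'   evening;
#' * evening (`day_end`--`evening_end`): cosine ramp from the pre-bed
#'   ceiling down to the sleep ceiling;
#' * sleep plateau (`evening_end`--`sleep_end`, wrapping midnight): constant
#'   sleep ceiling;
#' * morning (`sleep_end`--`day_start`): cosine ramp back up to the day arc.
#'
#' `preset = "plateau33"` replaces the day arc with a flat plateau at the
#' daytime target.
#'
#' @param day_target Daytime anchor (uW/cm^2, default 33).
#' @param prebed_ceiling Evening ceiling (uW/cm^2, default 1.33).
#' @param sleep_ceiling Sleep ceiling (uW/cm^2, default 0.1).
#' @param day_start,day_end Daytime window bounds (hours, default 6 and 20).
#' @param day_anchor Clock hour at which the day arc equals `day_target`
#'   (default 9; the arc is symmetric so 17:00 matches too).
#' @param evening_end End of the evening ramp (default 23).
#' @param sleep_end End of the sleep plateau next morning (default 5).
#' @param preset `"halfsine"` (default) or `"plateau33"`.
#' @return Object of class `reference_curve` with `$value(t)` (vectorised in
#'   clock hours, 24 h periodic) and the anchor set.
#' @export
reference_curve <- function(day_target = 33, prebed_ceiling = 1.33,
                            sleep_ceiling = 0.1,
                            day_start = 6, day_end = 20, day_anchor = 9,
                            evening_end = 23, sleep_end = 5,
                            preset = c("halfsine", "plateau33")) {
  preset <- match.arg(preset)
  alx_check(day_target >= prebed_ceiling && prebed_ceiling >= sleep_ceiling &&
              sleep_ceiling > 0,
            "anchors must satisfy day_target >= prebed_ceiling >= sleep_ceiling > 0")
  alx_check(day_start < day_end && day_end < evening_end && evening_end <= 24 &&
              sleep_end < day_start && sleep_end >= 0,
            "breakpoints must be ordered: sleep_end < day_start < day_end < evening_end")

  span <- day_end - day_start
  P <- day_target / sin(pi * (day_anchor - day_start) / span)

  day_value <- function(t) {
    if (preset == "plateau33") rep(day_target, length(t))
    else pmax(P * sin(pi * (t - day_start) / span), prebed_ceiling)
  }
  value <- function(t) {
    t <- t %% 24
    out <- numeric(length(t))
    day <- t >= day_start & t < day_end
    eve <- t >= day_end & t < evening_end
    morn <- t >= sleep_end & t < day_start
    plat <- !(day | eve | morn)
    out[day] <- day_value(t[day])
    out[eve] <- sleep_ceiling + (prebed_ceiling - sleep_ceiling) *
      (1 + cos(pi * (t[eve] - day_end) / (evening_end - day_end))) / 2
    day_at_start <- day_value(day_start)
    out[morn] <- sleep_ceiling + (day_at_start - sleep_ceiling) *
      (1 - cos(pi * (t[morn] - sleep_end) / (day_start - sleep_end))) / 2
    out[plat] <- sleep_ceiling
    out
  }

  structure(list(value = value,
                 anchors = c(day_target = day_target,
                             prebed_ceiling = prebed_ceiling,
                             sleep_ceiling = sleep_ceiling),
                 breakpoints = c(day_start = day_start, day_end = day_end,
                                 day_anchor = day_anchor,
                                 evening_end = evening_end,
                                 sleep_end = sleep_end),
                 peak = if (preset == "halfsine") P else day_target,
                 preset = preset),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("<reference_curve> preset", x$preset, "\n")
  cat(sprintf("  anchors (uW/cm^2): day %.4g, pre-bed %.4g, sleep %.4g; peak %.4g\n",
              x$anchors[["day_target"]], x$anchors[["prebed_ceiling"]],
              x$anchors[["sleep_ceiling"]], x$peak))
  invisible(x)
}

# Shared window integrator: sum over 30-min bins of the positive part of
# (sign) * (exposure - reference), reference evaluated at bin midpoints.
window_area <- function(profile, ref, window_hours, sign) {
  alx_check(inherits(profile, "daily_profile"), "profile must be a daily_profile")
  alx_check(inherits(ref, "reference_curve"), "ref must be a reference_curve")
  if (!identical(attr(profile, "transform"), "raw"))
    alx_abort("light indices need a raw (uW/cm^2) profile, not log-transformed",
              "actilux_unit_error")
  lo <- window_hours[1]; hi <- window_hours[2]
  mid <- profile$mid_hour
  inwin <- if (lo < hi) mid >= lo & mid < hi else mid >= lo | mid < hi
  bin_h <- attr(profile, "bin_minutes") / 60
  sub <- profile[inwin, ]
  usable <- !sub$missing
  contrib <- pmax(0, sign * (sub$mean[usable] - ref$value(sub$mid_hour[usable])))
  structure(sum(contrib * bin_h),
            n_missing = sum(!usable), n_bins = nrow(sub))
}

#' Nocturnal excess index of blue light (NEI_bl)
#'
#' Area (uW/cm^2 x h) of blue-light exposure *above* the reference curve in
#' the night window 20:00--05:00 (wrapping midnight), accumulated over the
#' profile's 30-min bins with the reference evaluated at bin midpoints.
#' Missing bins contribute zero and are counted in the `n_missing` attribute.
#'
#' @param profile A raw-unit blue-channel [bin_daily_profile()].
#' @param ref A [reference_curve()].
#' @param window Night window in hours (default `c(20, 5)`, half-open).
#' @return Numeric area in uW/cm^2 x h with attributes `n_missing`, `n_bins`.
#' @export
compute_nei <- function(profile, ref = reference_curve(), window = c(20, 5)) {
  window_area(profile, ref, window, sign = +1)
}

#' Daytime deficit index of blue light (DDI_bl)
#'
#' Area (uW/cm^2 x h) of blue-light exposure *below* the reference curve in
#' the day window 06:00--20:00; the mirror of [compute_nei()].
#'
#' @inheritParams compute_nei
#' @param window Day window in hours (default `c(6, 20)`, half-open).
#' @return Numeric area in uW/cm^2 x h with attributes `n_missing`, `n_bins`.
#' @export
compute_ddi <- function(profile, ref = reference_curve(), window = c(6, 20)) {
  window_area(profile, ref, window, sign = -1)
}

#' Both light-hygiene indices for one participant
#'
#' @param series An [epoch_series()] with a `blue` channel.
#' @param ref A [reference_curve()].
#' @param mode `"mean_profile"` (indices on the mean daily profile, default)
#'   or `"per_day_mean"` (per-day profiles, indices averaged across days).
#' @return List of class `light_indices`: `ddi_bl`, `nei_bl`, `mode`.
#' @export
light_indices <- function(series, ref = reference_curve(),
                          mode = c("mean_profile", "per_day_mean")) {
  mode <- match.arg(mode)
  if (mode == "mean_profile") {
    prof <- bin_daily_profile(series, "blue", transform = "raw")
    ddi <- compute_ddi(prof, ref)
    nei <- compute_nei(prof, ref)
  } else {
    days <- split_days(series)
    dd <- vapply(days, function(s)
      as.numeric(compute_ddi(bin_daily_profile(s, "blue"), ref)), numeric(1))
    nn <- vapply(days, function(s)
      as.numeric(compute_nei(bin_daily_profile(s, "blue"), ref)), numeric(1))
    ddi <- mean(dd); nei <- mean(nn)
  }
  structure(list(ddi_bl = as.numeric(ddi), nei_bl = as.numeric(nei),
                 mode = mode),
            class = "light_indices")
}

#' Split a series into calendar days
#'
#' One sub-series per local calendar day (midnight to midnight); days with
#' no unmasked epochs are dropped.
#'
#' @param series An [epoch_series()].
#' @return List of [epoch_series()] objects.
#' @export
split_days <- function(series) {
  day <- floor(as.numeric(epoch_times(series)) / 86400)
  out <- list()
  for (d in unique(day)) {
    sel <- day == d
    if (!any(series$valid[sel])) next
    first <- which(sel)[1]
    out[[length(out) + 1L]] <- epoch_series(
      participant_id = series$participant_id,
      start_time = epoch_times(series)[first],
      channels = lapply(series$channels, function(v) v[sel]),
      epoch_length = series$epoch_length,
      valid = series$valid[sel])
  }
  out
}
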