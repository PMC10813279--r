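#' Configuration for the synthetic Arctic actigraphy cohort
#'
#' Defaults emulate the structure of a week-long, 1-minute wrist-actigraphy
#' study around the spring equinox at ~67 deg N: diurnal PIM activity gated
#' by a jittered nightly sleep interval, a nocturnal wrist-temperature
#' cosinor (MESOR ~31.9 degC, amplitude ~1.4, acrophase ~02:45), a daylight
#' blue-light half-sine envelope scaled by the photoperiod plus lognormal
#' indoor evening light, and hormone values generated from linear models on
#' each participant's realized correlates. Effect hooks plant a BMI-dependent
#' evening blue-light excess (raised-cosine clock weight peaking at 23:30 by
#' default, optionally restricted to MTNR1B G-allele carriers) and a
#' G-carrier-specific wrist-temperature MESOR slope in BMI, giving every
#' analysis stage a recoverable ground truth.
#'
#' @param n_participants Cohort size (default 62).
#' @param seed Integer RNG seed (default 1).
#' @param latitude,day_of_year Site and date driving the photoperiod
#'   (defaults 66.9 deg N, day 80 ~ spring equinox).
#' @param days Recording length in days (default 7).
#' @param epoch_length Epoch length in seconds (default 60).
#' @param activity,wt,sleep,light,effects,leptin,cortisol,demographics
#'   Named lists overriding individual model parameters; see the defaults in
#'   the function body for the full set.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 62, seed = 1,
                       latitude = 66.9, day_of_year = 80,
                       days = 7, epoch_length = 60,
                       activity = list(), wt = list(), sleep = list(),
                       light = list(), effects = list(), leptin = list(),
                       cortisol = list(), demographics = list()) {
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    alx_check(length(bad) == 0,
              paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    n_participants = n_participants, seed = seed,
    latitude = latitude, day_of_year = day_of_year,
    days = days, epoch_length = epoch_length,
    activity = merge_defaults(list(
      wake_mean = 4000, wake_sd = 900, wake_between_sd = 500,
      waso_mean = 800, waso_sd = 200, sleep_sd = 30), activity),
    wt = merge_defaults(list(
      mesor = 31.9, mesor_between_sd = 0.4, amplitude = 1.4,
      amplitude_between_sd = 0.3, acrophase = 2.75, noise_sd = 0.3), wt),
    sleep = merge_defaults(list(
      bedtime_mean = 22.58, bedtime_between_sd = 0.93,
      waketime_mean = 6.85, waketime_between_sd = 1.05,
      night_jitter_sd = 0.33, waso_bouts_mean = 5,
      waso_bout_minutes = 10), sleep),
    light = merge_defaults(list(
      day_peak = 25, day_peak_sdlog = 0.4, day_noise_sdlog = 0.6,
      evening_meanlog = log(0.8), evening_sdlog = 1.1,
      evening_start = 19, sleep_meanlog = log(0.02), sleep_sdlog = 1,
      morning_shift_sd = 0.5), light),
    effects = merge_defaults(list(
      beta_nei_bmi = 0.12, restrict_to_g_carriers = FALSE,
      beta_wt_bmi_g = -0.08, effect_peak_hour = 23.5,
      effect_half_width = 3.5), effects),
    leptin = merge_defaults(list(
      intercept = -12, slope_bmi = 1.2, slope_waso = 0.08,
      noise_sd = 4), leptin),
    cortisol = merge_defaults(list(
      intercept = 250, slope_ddi = 0.25, slope_shift = -40,
      noise_sd = 60), cortisol),
    demographics = merge_defaults(list(
      bmi_mean = 24.2, bmi_sd = 4.6, bmi_min = 16,
      age_mean = 36.2, age_sd = 14.2, age_range = c(12, 59),
      female_freq = 0.823, native_freq = 24 / 62,
      g_carrier_freq = 0.44, gg_given_carrier = 0.2), demographics)
  )
  sds <- c(cfg$activity$wake_sd, cfg$activity$sleep_sd, cfg$wt$noise_sd,
           cfg$sleep$night_jitter_sd, cfg$leptin$noise_sd,
           cfg$cortisol$noise_sd)
  alx_check(all(sds >= 0), "all noise standard deviations must be >= 0")
  freqs <- c(cfg$demographics$female_freq, cfg$demographics$native_freq,
             cfg$demographics$g_carrier_freq,
             cfg$demographics$gg_given_carrier)
  alx_check(all(freqs >= 0 & freqs <= 1),
            "frequencies must lie in [0, 1]")
  alx_check(n_participants >= 0, "n_participants must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate one participant's week of actigraphy
#'
#' Builds the four channels on the configured epoch grid (starting at local
#' midnight) given the participant's metadata and person-level parameters
#' drawn by [simulate_cohort()]. Exposed mainly for testing; most users call
#' [simulate_cohort()].
#'
#' @param meta One-row data.frame with at least `participant_id`, `bmi`,
#'   `g_carrier`.
#' @param config A [sim_config()].
#' @param person Optional list of person-level latent parameters (drawn from
#'   the configured distributions when omitted).
#' @return List with `series` (an [epoch_series()] including nightly
#'   bedtime/waketime events) and `person` (the latent parameters actually
#'   used, including planted WASO minutes and the evening excess level).
#' @export
simulate_participant <- function(meta, config, person = NULL) {
  cfg <- config
  n_per_day <- round(86400 / cfg$epoch_length)
  n <- n_per_day * cfg$days
  epoch_h <- cfg$epoch_length / 3600
  t_clock <- ((seq_len(n) - 1) * epoch_h) %% 24

  if (is.null(person)) person <- draw_person(meta, cfg)

  # --- sleep mask (TRUE = asleep) and WASO bouts -------------------------
  asleep <- rep(FALSE, n)
  waso_mask <- rep(FALSE, n)
  ev_time <- character(0); ev_label <- character(0)
  waso_total <- 0
  # the record starts at midnight: the first morning is still in bed
  first_wake <- round(person$waketime[1] / epoch_h)
  if (first_wake >= 1) asleep[seq_len(min(n, first_wake))] <- TRUE
  for (d in seq_len(cfg$days)) {
    bed <- person$bedtime[d]; wake <- person$waketime[d]
    # bed in hours from midnight of day d (bed may be < 24), wake next day
    i0 <- round(((d - 1) * 24 + bed) / epoch_h) + 1
    i1_raw <- round(((d - 1) * 24 + wake + 24) / epoch_h)
    i0 <- max(1, i0); i1 <- min(n, i1_raw)
    if (i0 > i1) next
    asleep[i0:i1] <- TRUE
    # WASO bouts inside the night
    nb <- person$waso_bouts[d]
    if (nb > 0 && (i1 - i0) > 60) {
      for (b in seq_len(nb)) {
        len <- max(1, round(person$waso_bout_minutes *
                              60 / cfg$epoch_length))
        lo <- i0 + 30; hi <- i1 - 30 - len
        if (hi <= lo) next
        s <- floor(runif(1, lo, hi + 1))
        waso_mask[s:(s + len - 1)] <- TRUE
        waso_total <- waso_total + len * cfg$epoch_length / 60
      }
    }
    if (i1_raw <= n) {
      # only fully recorded nights get diary markers
      ev_time <- c(ev_time, fmt_sim_time(i0, cfg), fmt_sim_time(i1 + 1, cfg))
      ev_label <- c(ev_label, "bedtime", "waketime")
    }
  }
  sleeping <- asleep & !waso_mask

  # --- activity (PIM) ----------------------------------------------------
  act <- numeric(n)
  daytime_wake <- !asleep
  act[daytime_wake] <- pmax(0, rnorm(sum(daytime_wake), person$wake_level,
                                     cfg$activity$wake_sd))
  act[waso_mask] <- pmax(0, rnorm(sum(waso_mask), cfg$activity$waso_mean,
                                  cfg$activity$waso_sd))
  act[sleeping] <- abs(rnorm(sum(sleeping), 0, cfg$activity$sleep_sd))

  # --- wrist temperature -------------------------------------------------
  wt <- person$wt_mesor +
    person$wt_amplitude * cos(2 * pi * (t_clock - cfg$wt$acrophase) / 24) +
    rnorm(n, 0, cfg$wt$noise_sd)

  # --- blue light --------------------------------------------------------
  pp <- photoperiod(cfg$latitude, cfg$day_of_year)
  sr <- if (pp$polar == "day") 0 else if (pp$polar == "night") 12 else pp$sunrise
  ss <- if (pp$polar == "day") 24 else if (pp$polar == "night") 12 else pp$sunset
  tt <- t_clock - person$morning_shift
  env <- if (pp$polar == "night") rep(0, n) else
    ifelse(tt > sr & tt < ss,
           sin(pi * (tt - sr) / max(ss - sr, 1e-9)), 0)
  blue <- numeric(n)
  awake <- !asleep
  day_part <- awake & env > 0
  blue[day_part] <- person$day_peak * env[day_part] *
    exp(rnorm(sum(day_part), 0, cfg$light$day_noise_sdlog))
  evening <- awake & (t_clock >= cfg$light$evening_start | t_clock < 2)
  blue[evening] <- blue[evening] +
    rlnorm(sum(evening), cfg$light$evening_meanlog, cfg$light$evening_sdlog)
  # planted evening excess: raised-cosine clock weight
  dt <- pmin(abs(t_clock - cfg$effects$effect_peak_hour),
             24 - abs(t_clock - cfg$effects$effect_peak_hour))
  wgt <- ifelse(dt <= cfg$effects$effect_half_width,
                0.5 * (1 + cos(pi * dt / cfg$effects$effect_half_width)), 0)
  blue[awake] <- blue[awake] + person$evening_excess * wgt[awake]
  blue[asleep] <- rlnorm(sum(asleep), cfg$light$sleep_meanlog,
                         cfg$light$sleep_sdlog)
  blue <- pmax(0, blue)

  lux <- blue / MEDI_UW_CM2_PER_LX

  series <- epoch_series(
    participant_id = meta$participant_id,
    start_time = "2022-03-21T00:00:00",
    channels = list(activity_pim = act, wrist_temp = wt, lux = lux,
                    blue = blue),
    epoch_length = cfg$epoch_length,
    events = data.frame(time = ev_time, label = ev_label,
                        stringsAsFactors = FALSE))
  person$waso_planted <- waso_total
  list(series = series, person = person)
}

fmt_sim_time <- function(epoch_idx, cfg) {
  t0 <- as.numeric(as_naive_time("2022-03-21T00:00:00"))
  format_naive_time(as.POSIXct(t0 + (epoch_idx - 1) * cfg$epoch_length,
                               origin = "1970-01-01", tz = "UTC"))
}

# Person-level latent draws; the planted evening excess is
# beta_nei_bmi * (BMI - 25), applied (optionally only in G-carriers) and the
# G-carrier wT MESOR shift is beta_wt_bmi_g * (BMI - 25).
draw_person <- function(meta, cfg) {
  eligible <- !cfg$effects$restrict_to_g_carriers || isTRUE(meta$g_carrier)
  excess <- if (eligible) cfg$effects$beta_nei_bmi * (meta$bmi - 25) else 0
  wt_shift <- if (isTRUE(meta$g_carrier))
    cfg$effects$beta_wt_bmi_g * (meta$bmi - 25) else 0
  list(
    wake_level = pmax(500, rnorm(1, cfg$activity$wake_mean,
                                 cfg$activity$wake_between_sd)),
    wt_mesor = rnorm(1, cfg$wt$mesor, cfg$wt$mesor_between_sd) + wt_shift,
    wt_amplitude = pmax(0.2, rnorm(1, cfg$wt$amplitude,
                                   cfg$wt$amplitude_between_sd)),
    day_peak = exp(rnorm(1, log(cfg$light$day_peak),
                         cfg$light$day_peak_sdlog)),
    morning_shift = rnorm(1, 0, cfg$light$morning_shift_sd),
    bedtime = rnorm(cfg$days,
                    rnorm(1, cfg$sleep$bedtime_mean,
                          cfg$sleep$bedtime_between_sd),
                    cfg$sleep$night_jitter_sd),
    waketime = rnorm(cfg$days,
                     rnorm(1, cfg$sleep$waketime_mean,
                           cfg$sleep$waketime_between_sd),
                     cfg$sleep$night_jitter_sd),
    waso_bouts = rpois(cfg$days, cfg$sleep$waso_bouts_mean),
    waso_bout_minutes = cfg$sleep$waso_bout_minutes,
    evening_excess = excess,
    wt_shift = wt_shift
  )
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Draws participant metadata (BMI, age, sex, population, MTNR1B genotype)
#' from the configured distributions, simulates each participant's
#' [epoch_series()], derives hormone values from linear models on realized
#' correlates (leptin on BMI and planted WASO; cortisol on the realized
#' DDI_bl and the participant's morning light shift), and returns the
#' planted truth needed by effect-recovery tests. Identical config and seed
#' give a bit-identical cohort.
#'
#' @param config A [sim_config()].
#' @param compute_realized If `TRUE` (default) compute each participant's
#'   realized DDI_bl (used by the cortisol model and reported in the truth
#'   table); turning it off skips the binning pass.
#' @return List of class `sim_cohort`: `series` (named list of
#'   [epoch_series()]), `meta` (data.frame, one row per participant),
#'   `truth` (data.frame of planted per-participant quantities),
#'   `effects` (the effect sizes and correlation-peak clock time used),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), compute_realized = TRUE) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  dm <- cfg$demographics

  meta <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
  if (n > 0) {
    meta$bmi <- pmax(dm$bmi_min, rnorm(n, dm$bmi_mean, dm$bmi_sd))
    meta$age <- pmin(dm$age_range[2],
                     pmax(dm$age_range[1], rnorm(n, dm$age_mean, dm$age_sd)))
    meta$sex <- ifelse(runif(n) < dm$female_freq, "female", "male")
    meta$population <- ifelse(runif(n) < dm$native_freq, "native",
                              "non_native")
    carrier <- runif(n) < dm$g_carrier_freq
    gg <- carrier & (runif(n) < dm$gg_given_carrier)
    meta$genotype <- ifelse(gg, "GG", ifelse(carrier, "CG", "CC"))
    meta$g_carrier <- carrier
  } else {
    meta$bmi <- numeric(0); meta$age <- numeric(0)
    meta$sex <- character(0); meta$population <- character(0)
    meta$genotype <- character(0); meta$g_carrier <- logical(0)
  }

  series <- list()
  truth_rows <- list()
  ref <- reference_curve()
  for (i in seq_len(n)) {
    sim <- simulate_participant(meta[i, ], cfg)
    series[[meta$participant_id[i]]] <- sim$series
    ddi <- NA_real_
    if (compute_realized) {
      prof <- bin_daily_profile(sim$series, "blue", transform = "raw")
      ddi <- as.numeric(compute_ddi(prof, ref))
    }
    truth_rows[[i]] <- data.frame(
      participant_id = meta$participant_id[i],
      evening_excess = sim$person$evening_excess,
      wt_mesor_true = sim$person$wt_mesor,
      wt_shift = sim$person$wt_shift,
      waso_planted = sim$person$waso_planted,
      morning_shift = sim$person$morning_shift,
      ddi_realized = ddi,
      stringsAsFactors = FALSE)
  }
  truth <- if (n > 0) do.call(rbind, truth_rows) else
    data.frame(participant_id = character(0))

  if (n > 0) {
    meta$leptin <- cfg$leptin$intercept +
      cfg$leptin$slope_bmi * meta$bmi +
      cfg$leptin$slope_waso * truth$waso_planted +
      rnorm(n, 0, cfg$leptin$noise_sd)
    ddi_term <- if (compute_realized) truth$ddi_realized else 0
    meta$cortisol <- cfg$cortisol$intercept +
      cfg$cortisol$slope_ddi * ddi_term +
      cfg$cortisol$slope_shift * truth$morning_shift +
      rnorm(n, 0, cfg$cortisol$noise_sd)
  } else {
    meta$leptin <- numeric(0); meta$cortisol <- numeric(0)
  }

  structure(list(series = series, meta = meta, truth = truth,
                 effects = c(cfg$effects,
                             list(correlation_peak_hour =
                                    cfg$effects$effect_peak_hour)),
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$meta), "participants,",
      x$config$days, "days at", x$config$epoch_length, "s epochs\n")
  invisible(x)
}

#' Write a simulated cohort to disk in the canonical text formats
#'
#' One epoch CSV per participant (readable by [read_epoch_series()]), a
#' cohort metadata CSV and a planted-truth JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$series))
    write_epoch_series(cohort$series[[pid]],
                       file.path(dir, paste0(pid, ".csv")))
  write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
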