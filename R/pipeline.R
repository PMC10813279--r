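#' Per-participant actigraphy summary row
#'
#' Computes the full index set for one participant: cosinor MESOR /
#' amplitude / acrophase for activity, wrist temperature and blue light,
#' non-parametric indices for activity and blue light, mean nightly sleep
#' parameters, and the blue-light hygiene indices DDI_bl and NEI_bl.
#'
#' @param series An [epoch_series()].
#' @param ref A [reference_curve()].
#' @param sleep_scale,onset_rule Passed to [score_sleep()].
#' @return One-row data.frame.
#' @export
participant_summary <- function(series, ref = reference_curve(),
                                sleep_scale = 100, onset_rule = 5) {
  row <- data.frame(participant_id = series$participant_id,
                    stringsAsFactors = FALSE)
  for (ch in c("activity_pim", "wrist_temp", "blue")) {
    short <- c(activity_pim = "act", wrist_temp = "wt", blue = "bl")[[ch]]
    cf <- fit_cosinor(series, ch)
    row[[paste0(short, "_mesor")]] <- cf$mesor
    row[[paste0(short, "_amplitude")]] <- cf$amplitude
    row[[paste0(short, "_acrophase")]] <- cf$acrophase
  }
  for (ch in c("activity_pim", "blue")) {
    short <- c(activity_pim = "act", blue = "bl")[[ch]]
    np <- nonparametric_indices(series, ch)
    row[[paste0(short, "_is")]] <- np$is_
    row[[paste0(short, "_iv")]] <- np$iv
    row[[paste0(short, "_m10")]] <- np$m10
    row[[paste0(short, "_m10_onset")]] <- np$m10_onset
    row[[paste0(short, "_l5")]] <- np$l5
    row[[paste0(short, "_l5_onset")]] <- np$l5_onset
    row[[paste0(short, "_ra")]] <- np$ra
    row[[paste0(short, "_cfi")]] <- np$cfi
  }
  row$bl_l5_log10 <- log10_floor(row$bl_l5)

  nights <- score_sleep(series, scale = sleep_scale, onset_rule = onset_rule)
  okn <- nights$status == "ok"
  msleep <- function(col) if (any(okn)) mean(nights[[col]][okn]) else NA_real_
  row$n_nights_scored <- sum(okn)
  row$time_in_bed <- msleep("time_in_bed")
  row$total_sleep_time <- msleep("total_sleep_time")
  row$sleep_latency <- msleep("sleep_latency")
  row$sleep_efficiency <- msleep("sleep_efficiency")
  row$waso <- msleep("waso")
  row$sleep_phase <- if (any(okn))
    circular_mean_hours(nights$sleep_phase[okn]) else NA_real_

  li <- light_indices(series, ref)
  row$ddi_bl <- li$ddi_bl
  row$nei_bl <- li$nei_bl
  row
}

# Mean of clock hours on the 24 h circle.
circular_mean_hours <- function(h) {
  a <- 2 * pi * h / 24
  (atan2(mean(sin(a)), mean(cos(a))) * 24 / (2 * pi)) %% 24
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis: obtain a cohort (from a simulate
#' block or from epoch files on disk), compute the per-participant index
#' table, r-charts of log10 blue-light profiles against BMI, leptin and
#' cortisol, the BMI-group confidence-interval window, and genotype-
#' stratified r-charts; write all results plus a run manifest under the
#' output directory. Outputs are deterministic given the config and seed.
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   `simulate` (list of [sim_config()] arguments) *or* `input`
#'   (list with `epoch_dir` and `meta_file`); optional `reference` (list of
#'   [reference_curve()] arguments), `q` (FDR level, default 0.1),
#'   `stratify_by` (meta column, default `"g_carrier"`), `seed`, `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisible list with the computed objects (`participants`,
#'   `rcharts`, `ci_window`, `stratified`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  alx_check(is.list(config), "config must be a list or a YAML file path")
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (!has_sim && !has_input)
    alx_abort("config needs either a 'simulate' block or an 'input' block",
              "actilux_parameter_error")
  if (has_sim && has_input)
    alx_abort("config must not give both 'simulate' and 'input'",
              "actilux_parameter_error")
  out_dir <- out_dir %||% config$out_dir
  alx_check(!is.null(out_dir), "an output directory is required")

  q <- config$q %||% 0.1
  stratify_by <- config$stratify_by %||% "g_carrier"
  ref <- do.call(reference_curve, config$reference %||% list())

  if (has_sim) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    series <- cohort$series
    meta <- cohort$meta
  } else {
    alx_check(dir.exists(config$input$epoch_dir),
              paste0("input directory not found: ", config$input$epoch_dir),
              "actilux_format_error")
    alx_check(file.exists(config$input$meta_file),
              paste0("meta file not found: ", config$input$meta_file),
              "actilux_format_error")
    meta <- read.table(config$input$meta_file, header = TRUE, sep = ",",
                       stringsAsFactors = FALSE)
    dialect <- do.call(epoch_dialect, config$input$dialect %||%
                         list(valid = "valid"))
    files <- list.files(config$input$epoch_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    files <- files[basename(files) != basename(config$input$meta_file)]
    series <- lapply(files, read_epoch_series, dialect = dialect)
    names(series) <- vapply(series, function(s) s$participant_id, "")
    cohort <- NULL
  }
  if (!is.null(meta$genotype) && is.null(meta$g_carrier))
    meta$g_carrier <- meta$genotype %in% c("CG", "GG")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # per-participant indices
  participants <- do.call(rbind, lapply(series, participant_summary,
                                        ref = ref))
  participants <- merge(meta, participants, by = "participant_id",
                        sort = TRUE)
  write_num_csv(participants, file.path(out_dir, "participants.csv"))

  # log10 blue profiles for the association layer
  profiles <- lapply(series, bin_daily_profile, channel = "blue",
                     transform = "log10")
  pm <- profile_matrix(profiles)
  pm <- pm[match(participants$participant_id, rownames(pm)), , drop = FALSE]

  rcharts <- list()
  for (outc in intersect(c("bmi", "leptin", "cortisol"),
                         names(participants))) {
    rc <- compute_rchart(pm, participants[[outc]], q = q)
    rcharts[[outc]] <- rc
    write_num_csv(rc$bins, file.path(out_dir, paste0("rchart_", outc, ".csv")))
    if (!is.null(rc$cosinor_of_r))
      jsonlite::write_json(
        unclass(rc$cosinor_of_r)[c("mesor", "amplitude", "acrophase",
                                   "f_stat", "p_zero_amplitude", "n_used")],
        file.path(out_dir, paste0("rchart_", outc, "_cosinor.json")),
        auto_unbox = TRUE, digits = NA)
  }

  # BMI-group CI window on the log10 profiles
  ciw <- NULL
  if ("bmi" %in% names(participants)) {
    lean <- participants$bmi < 25
    if (sum(lean) >= 2 && sum(!lean) >= 2) {
      ciw <- ci_window(pm[lean, , drop = FALSE], pm[!lean, , drop = FALSE],
                       labels = c("bmi_lt_25", "bmi_ge_25"))
      write_num_csv(ciw$bins, file.path(out_dir, "ci_window_bins.csv"))
      jsonlite::write_json(
        ciw[c("empty", "start_bin", "end_bin", "start_hour", "end_hour",
              "n_bins", "lower_group")],
        file.path(out_dir, "ci_window.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  # stratified r-chart for BMI
  strat <- NULL
  if (stratify_by %in% names(participants) && "bmi" %in% names(participants)) {
    strat <- stratified_rchart(pm, participants$bmi,
                               participants[[stratify_by]], q = q)
    for (lev in names(strat)) {
      if (isFALSE(strat[[lev]]$evaluable)) next
      write_num_csv(strat[[lev]]$bins,
                    file.path(out_dir,
                              paste0("rchart_bmi_", stratify_by, "_",
                                     lev, ".csv")))
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("actilux")),
    seed = config$seed %||% (if (has_sim) cohort$config$seed else NULL),
    n_participants = nrow(participants),
    q = q, stratify_by = stratify_by,
    mode = if (has_sim) "simulate" else "input",
    config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(participants = participants, rcharts = rcharts,
                 ci_window = ciw, stratified = strat, manifest = manifest,
                 cohort = cohort))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic CSV writer: numbers at full precision, no row names.
write_num_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], digits = 15, format = "g"))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot an r-chart
#'
#' r per clock bin with raw and FDR significance thresholds and the fitted
#' cosine of r(t); requires ggplot2.
#'
#' @param rchart A [compute_rchart()] result.
#' @return A ggplot object.
#' @export
plot_rchart <- function(rchart) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    alx_abort("ggplot2 is required for plotting", "actilux_lookup_error")
  b <- rchart$bins[rchart$bins$evaluable, ]
  n_typ <- stats::median(b$n)
  r_crit <- crit_r(n_typ, rchart$alpha)
  g <- ggplot2::ggplot(b, ggplot2::aes(x = .data$mid_hour, y = .data$r)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant_fdr),
                        size = 1.8) +
    ggplot2::geom_hline(yintercept = c(-r_crit, r_crit),
                        linetype = "dashed", colour = "lightblue3") +
    ggplot2::labs(x = "clock time (h)", y = "r") +
    ggplot2::theme_minimal()
  if (!is.null(rchart$cosinor_of_r)) {
    cf <- rchart$cosinor_of_r
    tt <- seq(0, 24, by = 0.1)
    fitdf <- data.frame(mid_hour = tt,
                        r = cf$mesor + cf$amplitude *
                          cos(2 * pi * (tt - cf$acrophase) / 24))
    g <- g + ggplot2::geom_line(data = fitdf, colour = "firebrick")
  }
  g
}

# |r| threshold at two-sided level alpha for n pairs.
crit_r <- function(n, alpha = 0.05) {
  if (is.na(n) || n < 4) return(NA_real_)
  tc <- qt(1 - alpha / 2, n - 2)
  tc / sqrt(n - 2 + tc^2)
}
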