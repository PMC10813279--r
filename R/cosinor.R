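#' Single-component cosinor fit
#'
#' Least-squares fit of \eqn{y(t) = M + \beta\cos(2\pi t/\tau) +
#' \gamma\sin(2\pi t/\tau)} with fixed period \eqn{\tau} (default 24 h).
#' Reports MESOR \eqn{M}, amplitude \eqn{A = \sqrt{\beta^2+\gamma^2}},
#' acrophase as the local clock time (hours in `[0, 24)`) at which the fitted
#' curve peaks, and the zero-amplitude F-test with `(2, n - 3)` degrees of
#' freedom against the intercept-only model.
#'
#' A constant input (zero residual and zero amplitude) returns amplitude 0
#' and `p_zero_amplitude = 1` by convention.
#'
#' @param x An [epoch_series()] (times taken from its clock grid) or a numeric
#'   vector of times in hours.
#' @param ... Passed to methods.
#' @return An object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase`, `period`, `beta`, `gamma`, `f_stat`, `p_zero_amplitude`,
#'   `residual_sd`, `n_used`.
#' @export
fit_cosinor <- function(x, ...) UseMethod("fit_cosinor")

#' @rdname fit_cosinor
#' @param channel Channel label (series method).
#' @param period Fixed period in hours (default 24).
#' @export
fit_cosinor.epoch_series <- function(x, channel, period = 24, ...) {
  y <- get_channel(x, channel)
  keep <- x$valid
  fit <- fit_cosinor(elapsed_hours(x)[keep], y[keep], period = period)
  # report acrophase on the local clock: elapsed time 0 is start_time
  start_clock <- (as.numeric(x$start_time) %% 86400) / 3600
  fit$acrophase <- (fit$acrophase + start_clock) %% period
  fit$channel <- channel
  fit
}

#' @rdname fit_cosinor
#' @param y Numeric response values (default method).
#' @export
fit_cosinor.default <- function(x, y, period = 24, ...) {
  alx_check(is.numeric(x) && is.numeric(y) && length(x) == length(y),
            "x and y must be numeric vectors of equal length")
  keep <- stats::complete.cases(x, y)
  t <- x[keep]; y <- y[keep]
  n <- length(y)
  if (n < 4 || diff(range(t)) <= period / 2)
    alx_abort("cosinor needs >= 4 points spanning more than half a period",
              "actilux_insufficient_data_error")

  w <- 2 * pi * t / period
  X <- cbind(1, cos(w), sin(w))
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  mesor <- b[[1]]; beta <- b[[2]]; gamma <- b[[3]]
  amplitude <- sqrt(beta^2 + gamma^2)
  acrophase <- (period * atan2(gamma, beta) / (2 * pi)) %% period

  rss <- sum(fit$residuals^2)
  ss0 <- sum((y - mean(y))^2)
  scale0 <- max(ss0, .Machine$double.eps * n * max(1, mean(y)^2))
  if (ss0 <= .Machine$double.eps * n * max(1, mean(y))^2) {
    # constant series: no rhythm to detect
    amplitude <- 0; acrophase <- 0
    f_stat <- 0; p <- 1; resid_sd <- 0
  } else {
    f_stat <- ((ss0 - rss) / 2) / (rss / (n - 3))
    if (!is.finite(f_stat) || rss <= .Machine$double.eps * scale0) {
      f_stat <- Inf; p <- 0
    } else {
      p <- pf(f_stat, 2, n - 3, lower.tail = FALSE)
    }
    resid_sd <- sqrt(rss / (n - 3))
  }

  structure(list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
                 period = period, beta = beta, gamma = gamma,
                 f_stat = f_stat, p_zero_amplitude = p,
                 residual_sd = resid_sd, n_used = n),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> period %.4g h, n = %d\n", x$period, x$n_used))
  cat(sprintf("  MESOR %.4g  amplitude %.4g  acrophase %s\n",
              x$mesor, x$amplitude, hours_to_hhmm(x$acrophase)))
  cat(sprintf("  zero-amplitude F = %.4g, p = %.3g\n",
              x$f_stat, x$p_zero_amplitude))
  invisible(x)
}

#' Format fractional hours as hh:mm clock text
#' @param h Hours in `[0, 24)` (recycled, `NA` safe).
#' @return Character vector like `"14:47"`.
#' @export
hours_to_hhmm <- function(h) {
  out <- rep(NA_character_, length(h))
  ok <- !is.na(h)
  mins <- round((h[ok] %% 24) * 60)
  mins <- mins %% 1440
  out[ok] <- sprintf("%d:%02d", mins %/% 60, mins %% 60)
  out
}
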