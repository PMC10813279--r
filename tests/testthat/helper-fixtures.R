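# In-code fixtures shared across test files.

# A series with a given channel vector starting at local midnight.
make_series <- function(x, channel = "blue", epoch_length = 60,
                        start = "2022-03-21T00:00:00", valid = NULL,
                        id = "T01") {
  chans <- setNames(list(x), channel)
  epoch_series(id, start, chans, epoch_length = epoch_length, valid = valid)
}

# Noiseless cosine sampled on a minute grid over `days` days:
# y(t) = mesor + amplitude * cos(2*pi*(t - acrophase)/24).
cosine_series <- function(mesor = 10, amplitude = 3, acrophase = 15,
                          days = 7, channel = "wrist_temp",
                          epoch_length = 60, noise_sd = 0) {
  n <- days * round(86400 / epoch_length)
  t <- (seq_len(n) - 1) * epoch_length / 3600
  y <- mesor + amplitude * cos(2 * pi * (t - acrophase) / 24)
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  make_series(y, channel = channel, epoch_length = epoch_length)
}

# Square-wave activity: `high` during [on, off) clock hours, else 0.
square_series <- function(high = 1000, on = 8, off = 18, days = 7,
                          channel = "activity_pim", epoch_length = 60) {
  n <- days * round(86400 / epoch_length)
  tc <- (((seq_len(n) - 1) * epoch_length / 3600)) %% 24
  make_series(ifelse(tc >= on & tc < off, high, 0), channel = channel,
              epoch_length = epoch_length)
}

# Write a small epoch CSV fixture; returns the path.
write_epoch_fixture <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# Brute-force BH oracle: largest k with p_(k) <= k*q/m, reject all p <= p_(k).
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# Fine-grid (1-s) numerical integration oracle for the light indices: step
# exposure profile given as 48 bin values, reference evaluated every second.
area_oracle <- function(bin_values, ref, window, sign) {
  tt <- seq(0, 24 - 1 / 3600, by = 1 / 3600)
  inwin <- if (window[1] < window[2]) {
    tt >= window[1] & tt < window[2]
  } else {
    tt >= window[1] | tt < window[2]
  }
  expo <- bin_values[floor(tt * 2) + 1]
  dev <- pmax(0, sign * (expo - ref$value(tt)))
  sum(dev[inwin], na.rm = TRUE) / 3600
}
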