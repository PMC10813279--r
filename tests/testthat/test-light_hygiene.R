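test_that("mEDI conversion reproduces the published anchors", {
  expect_equal(round(medi_to_irradiance(250)), 33)
  expect_equal(round(medi_to_irradiance(10), 2), 1.33)
  expect_equal(round(medi_to_irradiance(1), 1), 0.1)
  expect_equal(medi_to_irradiance(0), 0)
  expect_error(medi_to_irradiance(-1), class = "actilux_parameter_error")
})

test_that("conversion and its inverse compose to identity", {
  x <- c(0, 0.1, 1, 10, 250, 1e4)
  expect_equal(irradiance_to_medi(medi_to_irradiance(x)), x,
               tolerance = 1e-12)
  expect_equal(medi_to_irradiance(irradiance_to_medi(x)), x,
               tolerance = 1e-12)
})

test_that("the default reference curve hits its anchors", {
  ref <- reference_curve()
  expect_equal(ref$value(20), 1.33)          # pre-bed ceiling at 20:00
  expect_equal(ref$value(2), 0.1)            # sleep plateau
  expect_equal(ref$value(9), 33, tolerance = 1e-12)   # day target at 09:00
  expect_equal(ref$value(17), 33, tolerance = 1e-12)  # and at 17:00
  expect_equal(ref$value(13), 33 / sin(3 * pi / 14), tolerance = 1e-12)
  expect_equal(ref$peak, 52.93, tolerance = 1e-4)
})

test_that("the reference curve is continuous and floored at the sleep ceiling", {
  ref <- reference_curve()
  t <- seq(0, 24, by = 1 / 240)
  v <- ref$value(t)
  expect_true(all(v >= 0.1 - 1e-12))
  jumps <- abs(diff(v))
  expect_lt(max(jumps), 0.3)  # max slope ~ P*pi/14 per h => < 0.05/step
  # 24 h periodicity
  expect_equal(ref$value(0), ref$value(24))
})

test_that("inconsistent anchors are rejected", {
  expect_error(reference_curve(day_target = 1, prebed_ceiling = 2),
               class = "actilux_parameter_error")
  expect_error(reference_curve(sleep_ceiling = 0),
               class = "actilux_parameter_error")
})

test_that("exposure equal to the reference gives exactly zero NEI and DDI", {
  ref <- reference_curve()
  mids <- ((0:47) + 0.5) / 2
  s <- make_series(rep(ref$value(mids), each = 30), channel = "blue")
  p <- bin_daily_profile(s, "blue")
  expect_identical(as.numeric(compute_nei(p, ref)), 0)
  expect_identical(as.numeric(compute_ddi(p, ref)), 0)
})

test_that("a uniform +1 offset over the night window gives NEI of 9", {
  ref <- reference_curve()
  mids <- ((0:47) + 0.5) / 2
  base <- ref$value(mids)
  night <- mids >= 20 | mids < 5
  vals <- base + ifelse(night, 1, 0)
  s <- make_series(rep(vals, each = 30), channel = "blue")
  p <- bin_daily_profile(s, "blue")
  expect_equal(as.numeric(compute_nei(p, ref)), 9, tolerance = 1e-12)
  expect_equal(as.numeric(compute_ddi(p, ref)), 0)
})

test_that("bin sums match the 1-s oracle exactly where the reference is flat", {
  # with prebed = sleep ceiling the whole night window is flat, so the
  # midpoint rule is exact for step exposure profiles
  ref <- reference_curve(prebed_ceiling = 0.1, sleep_ceiling = 0.1)
  set.seed(21)
  for (rep_i in 1:5) {
    vals <- rlnorm(48, -1, 1.5)
    s <- make_series(rep(vals, each = 30), channel = "blue")
    p <- bin_daily_profile(s, "blue")
    nei <- as.numeric(compute_nei(p, ref))
    oracle <- area_oracle(vals, ref, c(20, 5), +1)
    expect_lt(abs(nei - oracle) / max(oracle, 1e-12), 1e-9)
  }
  # flat day plateau: DDI against the plateau33 preset
  refp <- reference_curve(preset = "plateau33")
  for (rep_i in 1:5) {
    vals <- rlnorm(48, 2, 1)
    s <- make_series(rep(vals, each = 30), channel = "blue")
    p <- bin_daily_profile(s, "blue")
    ddi <- as.numeric(compute_ddi(p, refp))
    oracle <- area_oracle(vals, refp, c(6, 20), -1)
    expect_lt(abs(ddi - oracle) / max(oracle, 1e-12), 1e-9)
  }
})

test_that("bin sums track the 1-s oracle within the discretization bound", {
  ref <- reference_curve()
  # zero exposure all day: DDI equals the integral of the curve over the
  # day window (~471 uW/cm^2 h); midpoint-rule error is bounded by
  # width^2/24 * max|R''| * window
  s <- make_series(rep(0, 7 * 1440), channel = "blue")
  p <- bin_daily_profile(s, "blue")
  ddi <- as.numeric(compute_ddi(p, ref))
  oracle <- area_oracle(rep(0, 48), ref, c(6, 20), -1)
  expect_equal(oracle, 2 * 14 * ref$peak / pi, tolerance = 2e-3)
  max_dd <- ref$peak * (pi / 14)^2
  bound <- (0.5^2 / 24) * max_dd * 14 + 1e-6
  expect_lt(abs(ddi - oracle), bound)

  set.seed(22)
  for (rep_i in 1:3) {
    vals <- rlnorm(48, 0, 1.5)
    s <- make_series(rep(vals, each = 30), channel = "blue")
    p <- bin_daily_profile(s, "blue")
    nei <- as.numeric(compute_nei(p, ref))
    oracle <- area_oracle(vals, ref, c(20, 5), +1)
    # ramp segment only spans 20:00-23:00; generous smoothness bound
    expect_lt(abs(nei - oracle), 0.05)
  }
})

test_that("exposure above the reference everywhere gives zero DDI", {
  ref <- reference_curve()
  s <- make_series(rep(100, 2 * 1440), channel = "blue")
  p <- bin_daily_profile(s, "blue")
  expect_equal(as.numeric(compute_ddi(p, ref)), 0)
})

test_that("pointwise monotonicity: more light lowers DDI and raises NEI", {
  ref <- reference_curve()
  set.seed(23)
  vals <- rlnorm(48, 0, 1)
  up <- vals + runif(48, 0, 2)
  mk <- function(v) bin_daily_profile(make_series(rep(v, each = 30),
                                                  channel = "blue"), "blue")
  expect_lte(as.numeric(compute_ddi(mk(up), ref)),
             as.numeric(compute_ddi(mk(vals), ref)))
  expect_gte(as.numeric(compute_nei(mk(up), ref)),
             as.numeric(compute_nei(mk(vals), ref)))
})

test_that("raising the sleep plateau raises NEI by at most delta x hours", {
  set.seed(24)
  vals <- rlnorm(48, 0, 1)
  mk <- function(v) bin_daily_profile(make_series(rep(v, each = 30),
                                                  channel = "blue"), "blue")
  r1 <- reference_curve(sleep_ceiling = 0.1)
  r2 <- reference_curve(sleep_ceiling = 0.3)
  n1 <- as.numeric(compute_nei(mk(vals), r1))
  n2 <- as.numeric(compute_nei(mk(vals), r2))
  expect_lte(n1 - n2, (0.3 - 0.1) * 9 + 1e-12)
  expect_gte(n1 - n2, 0)  # a higher reference can only lower the excess
})

test_that("log-transformed profiles are rejected with a unit error", {
  s <- make_series(rlnorm(1440), channel = "blue")
  p <- bin_daily_profile(s, "blue", transform = "log10")
  expect_error(compute_nei(p), class = "actilux_unit_error")
  expect_error(compute_ddi(p), class = "actilux_unit_error")
})

test_that("missing bins contribute zero and are reported", {
  ref <- reference_curve()
  x <- rep(5, 2 * 1440)
  tc <- (((seq_along(x) - 1) / 60)) %% 24
  valid <- !(tc >= 21 & tc < 22)  # mask two night bins
  s <- make_series(x, channel = "blue", valid = valid)
  p <- bin_daily_profile(s, "blue")
  nei <- compute_nei(p, ref)
  expect_equal(attr(nei, "n_missing"), 2)
  expect_equal(attr(nei, "n_bins"), 18)
})

test_that("per-day and mean-profile index modes agree on identical days", {
  ref <- reference_curve()
  vals <- c(rep(0.05, 12), rep(20, 28), rep(3, 8))
  s <- make_series(rep(rep(vals, each = 30), 3), channel = "blue")
  a <- light_indices(s, ref, mode = "mean_profile")
  b <- light_indices(s, ref, mode = "per_day_mean")
  expect_equal(a$ddi_bl, b$ddi_bl, tolerance = 1e-10)
  expect_equal(a$nei_bl, b$nei_bl, tolerance = 1e-10)
})
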