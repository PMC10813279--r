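test_that("BH step-up handles the textbook cases", {
  expect_true(all(bh_fdr(rep(0.001, 48), q = 0.1)))
  expect_true(bh_fdr(0.04, q = 0.1))   # m = 1 reduces to p <= q
  expect_false(bh_fdr(0.2, q = 0.1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "actilux_parameter_error")
  expect_error(bh_fdr(c(-0.1, 0.5)), class = "actilux_parameter_error")
})

test_that("BH flags match the brute-force oracle on sampled p-grids", {
  set.seed(31)
  grid <- seq(0.01, 1, by = 0.01)
  for (len in 1:10) {
    for (rep_i in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      q <- sample(c(0.05, 0.1, 0.25), 1)
      expect_identical(bh_fdr(p, q), bh_oracle(p, q))
    }
  }
  # cross-check against stats::p.adjust on a larger vector
  p <- sample(grid, 48, replace = TRUE)
  expect_identical(bh_fdr(p, 0.1), stats::p.adjust(p, "BH") <= 0.1)
})

test_that("an exactly linear bin reaches r = 1 with p ~ 0", {
  set.seed(32)
  n <- 30
  outcome <- rnorm(n, 25, 4)
  profs <- matrix(rnorm(n * 48), n, 48)
  profs[, 47] <- 2 * outcome + 3
  rc <- compute_rchart(profs, outcome)
  expect_equal(rc$bins$r[47], 1, tolerance = 1e-12)
  expect_lt(rc$bins$p[47], 1e-12)
  expect_true(rc$bins$significant_fdr[47])
})

test_that("r-chart is invariant to participant order and profile offsets", {
  set.seed(33)
  n <- 40
  outcome <- rnorm(n, 25, 4)
  profs <- matrix(rnorm(n * 48), n, 48)
  rc1 <- compute_rchart(profs, outcome)
  perm <- sample(n)
  rc2 <- compute_rchart(profs[perm, ], outcome[perm])
  expect_equal(rc1$bins$r, rc2$bins$r, tolerance = 1e-12)
  rc3 <- compute_rchart(profs + 5, outcome)
  expect_equal(rc1$bins$r, rc3$bins$r, tolerance = 1e-12)
})

test_that("constant outcomes are a degenerate-correlation error", {
  profs <- matrix(rnorm(10 * 48), 10, 48)
  expect_error(compute_rchart(profs, rep(3, 10)),
               class = "actilux_degenerate_error")
})

test_that("bins with too few pairs are flagged not evaluable", {
  set.seed(34)
  profs <- matrix(rnorm(6 * 48), 6, 48)
  profs[1:4, 5] <- NA  # only 2 pairs left in bin 5
  rc <- compute_rchart(profs, rnorm(6))
  expect_false(rc$bins$evaluable[5])
  expect_true(all(rc$bins$evaluable[-5]))
})

test_that("null outcomes give ~5% raw and ~0 FDR significant bins", {
  set.seed(35)
  n_rep <- 200
  n <- 40
  raw_frac <- fdr_frac <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    profs <- matrix(rnorm(n * 48), n, 48)
    rc <- compute_rchart(profs, rnorm(n))
    raw_frac[i] <- mean(rc$bins$significant_raw)
    fdr_frac[i] <- mean(rc$bins$significant_fdr)
  }
  expect_lt(abs(mean(raw_frac) - 0.05), 0.015)
  expect_lt(mean(fdr_frac), 0.02)
})

test_that("a planted sinusoidal effect peaking at 23:30 is recovered", {
  set.seed(36)
  n <- 200; n_rep <- 50
  mids <- ((0:47) + 0.5) / 2
  w <- 0.6 * cos(2 * pi * (mids - 23.5) / 24)
  err <- numeric(n_rep); rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    profs <- matrix(rnorm(n * 48), n, 48)
    outcome <- profs %*% w + rnorm(n, 0, 2)
    rc <- compute_rchart(profs, as.numeric(outcome))
    d <- rc$cosinor_of_r$acrophase - 23.5
    err[i] <- ((d + 12) %% 24) - 12
    rej[i] <- rc$cosinor_of_r$p_zero_amplitude < 0.05
  }
  expect_lt(abs(mean(err)), 0.5)      # mean acrophase within 30 min
  expect_gte(mean(rej), 0.9)
})

test_that("identical groups give an empty CI window", {
  set.seed(37)
  profs <- matrix(rnorm(20 * 48), 20, 48)
  cw <- ci_window(profs, profs)
  expect_true(cw$empty)
  expect_equal(cw$n_bins, 0)
})

test_that("a planted evening shift is localised exactly", {
  set.seed(38)
  n <- 400
  A <- matrix(rnorm(n * 48), n, 48)
  B <- matrix(rnorm(n * 48), n, 48)
  shift_bins <- 44:48  # 21:30-00:00
  B[, shift_bins] <- B[, shift_bins] + 5  # 5 pooled SDs
  cw <- ci_window(A, B)
  expect_false(cw$empty)
  expect_equal(cw$start_bin, 43)  # bin index 43 = 21:30
  expect_equal(cw$start_hour, 21.5)
  expect_equal(cw$end_hour, 0)
  expect_equal(cw$n_bins, 5)
  expect_equal(cw$lower_group, "A")
  # threshold curve is the upper CI bound of the lower group
  expect_equal(cw$threshold_curve$threshold,
               cw$bins$hi_a[cw$bins$bin %in% 43:47])
})

test_that("two disjoint runs resolve to the longest, ties to earliest", {
  set.seed(39)
  n <- 500
  A <- matrix(rnorm(n * 48), n, 48)
  B <- matrix(rnorm(n * 48), n, 48)
  B[, 10:12] <- B[, 10:12] + 6   # 3 bins
  B[, 30:34] <- B[, 30:34] + 6   # 5 bins -> longest
  cw <- ci_window(A, B)
  expect_equal(cw$n_bins, 5)
  expect_equal(cw$start_bin, 29)

  # tie: two equal runs; earliest start in clock order from 12:00 wins
  C <- matrix(rnorm(n * 48), n, 48)
  D <- matrix(rnorm(n * 48), n, 48)
  D[, 30:32] <- D[, 30:32] + 6   # 14:30 run
  D[, 40:42] <- D[, 40:42] + 6   # 19:30 run
  cw2 <- ci_window(C, D)
  expect_equal(cw2$n_bins, 3)
  expect_equal(cw2$start_bin, 29)
})

test_that("CI windows may wrap midnight", {
  set.seed(40)
  n <- 400
  A <- matrix(rnorm(n * 48), n, 48)
  B <- matrix(rnorm(n * 48), n, 48)
  wrap_bins <- c(47, 48, 1, 2)  # 23:00 .. 01:00
  B[, wrap_bins] <- B[, wrap_bins] + 6
  cw <- ci_window(A, B)
  expect_equal(cw$n_bins, 4)
  expect_equal(cw$start_bin, 46)
  expect_equal(cw$end_bin, 1)
})

test_that("group labels only swap attribution, not the window", {
  set.seed(41)
  A <- matrix(rnorm(100 * 48), 100, 48)
  B <- matrix(rnorm(100 * 48), 100, 48) +
    matrix(rep(c(rep(0, 40), rep(4, 8)), each = 100), 100, 48)
  cw1 <- ci_window(A, B, labels = c("lean", "high"))
  cw2 <- ci_window(B, A, labels = c("high", "lean"))
  expect_equal(cw1$start_bin, cw2$start_bin)
  expect_equal(cw1$n_bins, cw2$n_bins)
  expect_equal(cw1$lower_group, "lean")
  expect_equal(cw2$lower_group, "lean")
})

test_that("Fisher z comparison of independent correlations", {
  eq <- compare_correlations(0.4, 30, 0.4, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # published contrast: r = -0.659 (n=22) vs 0.049 (n=28)
  res <- compare_correlations(-0.659, 22, 0.049, 28)
  z_hand <- (atanh(-0.659) - atanh(0.049)) / sqrt(1 / 19 + 1 / 25)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$z, -2.76, tolerance = 0.005)
  # antisymmetry
  res2 <- compare_correlations(0.049, 28, -0.659, 22)
  expect_equal(res2$z, -res$z, tolerance = 1e-12)
  expect_error(compare_correlations(1, 10, 0.5, 10),
               class = "actilux_degenerate_error")
})

test_that("stratified r-charts mirror their strata", {
  set.seed(42)
  n <- 30
  profs <- matrix(rnorm(n * 48), n, 48)
  outcome <- rnorm(n)
  strata <- rep(c("x", "y"), each = 15)
  st <- stratified_rchart(profs, outcome, strata)
  expect_named(st, c("x", "y"))
  direct <- compute_rchart(profs[1:15, ], outcome[1:15])
  expect_equal(st$x$bins$r, direct$bins$r, tolerance = 1e-12)

  # identical data in both strata -> identical charts
  profs2 <- rbind(profs[1:15, ], profs[1:15, ])
  out2 <- c(outcome[1:15], outcome[1:15])
  st2 <- stratified_rchart(profs2, out2, strata)
  expect_equal(st2$x$bins$r, st2$y$bins$r, tolerance = 1e-12)

  # undersized stratum flagged, other still returned
  st3 <- stratified_rchart(profs, outcome, c("solo", rep("rest", n - 1)))
  expect_false(st3$solo$evaluable)
  expect_s3_class(st3$rest, "rchart")
})

test_that("adjusted association collapses to the simple slope when orthogonal", {
  set.seed(43)
  n <- 500
  d <- data.frame(age = rnorm(n), sex = rep(c("f", "m"), n / 2),
                  population = rep(c("a", "a", "b", "b"), n / 4))
  d$x <- rep(c(1, -1), n / 2) * rep(1, n) + rnorm(n)
  d$x <- d$x - ave(d$x, d$sex)           # orthogonal to sex
  d$x <- d$x - ave(d$x, d$population)    # and population
  d$x <- d$x - d$age * sum(d$x * d$age) / sum(d$age^2)
  d$y <- 0.5 * d$x + rnorm(n, 0, 1e-8)
  d$y <- d$y - ave(d$y, d$sex); d$y <- d$y - ave(d$y, d$population)
  d$y <- d$y - d$age * sum(d$y * d$age) / sum(d$age^2)
  fit <- adjusted_association(d, "y", "x")
  simple <- cor(d$x, d$y)
  expect_equal(fit$coefficient, simple, tolerance = 1e-4)
  expect_lt(fit$p, 1e-10)
})

test_that("confounding by age is removed by adjustment", {
  set.seed(44)
  n <- 1000
  age <- rnorm(n, 40, 12)
  x <- 0.1 * age + rnorm(n)
  y <- 0.2 * age + rnorm(n)
  d <- data.frame(x = x, y = y, age = age,
                  sex = sample(c("f", "m"), n, TRUE),
                  population = sample(c("a", "b"), n, TRUE))
  unadj <- cor(x, y)
  expect_gt(unadj, 0.2)
  fit <- adjusted_association(d, "y", "x")
  expect_lt(abs(fit$coefficient), 0.08)

  # collinear design errors out
  d$dup <- d$x
  expect_error(adjusted_association(d, "y", "x",
                                    covariates = c("age", "dup")),
               class = "actilux_degenerate_error")
})
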