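#' Benjamini-Hochberg step-up rejection flags
#'
#' Standard step-up procedure at FDR level `q`: with order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, find the largest \eqn{k} with
#' \eqn{p_{(k)} \le k q / m} and reject all hypotheses with
#' \eqn{p \le p_{(k)}}.
#'
#' @param p Numeric p-values in `[0, 1]` (no `NA`).
#' @param q FDR level (default 0.1).
#' @return Logical rejection flags, same length and order as `p`.
#' @export
bh_fdr <- function(p, q = 0.1) {
  alx_check(is.numeric(p) && length(p) >= 1 && !anyNA(p) &&
              all(p >= 0 & p <= 1),
            "p-values must lie in [0, 1]", "actilux_parameter_error")
  alx_check(is.numeric(q) && length(q) == 1L && q > 0 && q < 1,
            "q must be in (0, 1)")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

#' Time-resolved correlation chart (r-chart)
#'
#' For each clock bin of a per-participant daily-profile matrix, the Pearson
#' correlation between participants' bin values and a scalar outcome, with a
#' two-sided p-value from the t transform on `n - 2` df, Benjamini-Hochberg
#' FDR flags across the bin family, and a cosinor fit to r(t) over bin
#' midpoints with its zero-amplitude test (the chart's rhythm summary).
#'
#' @param profiles Participants x bins numeric matrix (see
#'   [profile_matrix()]), conventionally of log10-floored blue-light values.
#' @param outcome Numeric outcome per participant (e.g. BMI, leptin).
#' @param q FDR level for the within-chart correction (default 0.1).
#' @param bin_minutes Bin width represented by the columns (default 30).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Raw per-bin significance level (default 0.05).
#' @return Object of class `rchart`: `$bins` data.frame (`bin`, `mid_hour`,
#'   `r`, `p`, `n`, `evaluable`, `significant_raw`, `significant_fdr`),
#'   `$cosinor_of_r` ([fit_cosinor()] on the evaluable bins), `$q`,
#'   `$outcome_label`. Bins with fewer than 4 complete pairs or a constant
#'   bin value are flagged not evaluable.
#' @export
compute_rchart <- function(profiles, outcome, q = 0.1, bin_minutes = 30,
                           method = c("pearson", "spearman"), alpha = 0.05) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  alx_check(nrow(profiles) == length(outcome),
            "outcome must have one value per profile row")
  ok_out <- !is.na(outcome)
  if (sum(ok_out) >= 2 && stats::var(outcome[ok_out]) == 0)
    alx_abort("outcome is constant; correlations are undefined",
              "actilux_degenerate_error")

  nb <- ncol(profiles)
  mid <- (seq_len(nb) - 0.5) * bin_minutes / 60
  r <- p <- rep(NA_real_, nb)
  n <- integer(nb)
  for (b in seq_len(nb)) {
    xb <- profiles[, b]
    cc <- !is.na(xb) & ok_out
    n[b] <- sum(cc)
    if (n[b] < 4) next
    if (stats::sd(xb[cc]) == 0) next
    if (method == "spearman") {
      rb <- cor(rank(xb[cc]), rank(outcome[cc]))
    } else {
      rb <- cor(xb[cc], outcome[cc])
    }
    r[b] <- rb
    if (abs(rb) >= 1) {
      p[b] <- 0
    } else {
      tt <- rb * sqrt((n[b] - 2) / (1 - rb^2))
      p[b] <- 2 * pt(-abs(tt), n[b] - 2)
    }
  }
  evaluable <- !is.na(r)
  sig_raw <- evaluable & !is.na(p) & p < alpha
  sig_fdr <- rep(FALSE, nb)
  if (any(evaluable)) sig_fdr[evaluable] <- bh_fdr(p[evaluable], q = q)

  cos_fit <- if (sum(evaluable) >= 4) {
    fit_cosinor(mid[evaluable], r[evaluable], period = 24)
  } else NULL

  structure(list(
    bins = data.frame(bin = seq_len(nb) - 1L, mid_hour = mid, r = r, p = p,
                      n = n, evaluable = evaluable,
                      significant_raw = sig_raw, significant_fdr = sig_fdr),
    cosinor_of_r = cos_fit, q = q, alpha = alpha, method = method,
    outcome_label = deparse(substitute(outcome))),
    class = "rchart")
}

#' @export
print.rchart <- function(x, ...) {
  cat(sprintf("<rchart> %d bins, %d evaluable; raw-significant %d, FDR(q=%.2g) %d\n",
              nrow(x$bins), sum(x$bins$evaluable),
              sum(x$bins$significant_raw), x$q, sum(x$bins$significant_fdr)))
  if (!is.null(x$cosinor_of_r))
    cat(sprintf("  cosinor of r(t): amplitude %.3f, acrophase %s, p = %.3g\n",
                x$cosinor_of_r$amplitude,
                hours_to_hhmm(x$cosinor_of_r$acrophase),
                x$cosinor_of_r$p_zero_amplitude))
  invisible(x)
}

#' Detect the window of non-overlapping group confidence intervals
#'
#' Per clock bin, each group's mean and t-based 95% confidence interval are
#' computed; a bin qualifies when the two intervals are disjoint. The window
#' is the maximal contiguous run of qualifying bins treating the bin circle
#' as wrap-around (evening windows cross midnight); ties are broken by the
#' earliest start in clock order beginning at 12:00. The threshold curve is
#' the upper confidence bound of the lower-mean group inside the window.
#'
#' @param profiles_a,profiles_b Participants x bins matrices for the two
#'   groups (e.g. BMI < 25 vs BMI > 25).
#' @param level Confidence level (default 0.95).
#' @param bin_minutes Bin width (default 30).
#' @param labels Group labels (length 2).
#' @return Object of class `ci_window`: `$empty`, `$start_bin`, `$end_bin`
#'   (inclusive, may wrap), `$start_hour`, `$end_hour`, `$n_bins`,
#'   `$lower_group`, `$threshold_curve` (data.frame `bin`, `mid_hour`,
#'   `threshold`), `$bins` per-bin detail.
#' @export
ci_window <- function(profiles_a, profiles_b, level = 0.95,
                      bin_minutes = 30, labels = c("A", "B")) {
  A <- as.matrix(profiles_a); B <- as.matrix(profiles_b)
  alx_check(ncol(A) == ncol(B), "groups must share one bin grid",
            "actilux_integrity_error")
  nb <- ncol(A)
  ci <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) return(c(NA, NA, NA, n))
    m <- mean(x); se <- sd(x) / sqrt(n)
    hw <- qt((1 + level) / 2, df = n - 1) * se
    c(m, m - hw, m + hw, n)
  }
  ca <- t(apply(A, 2, ci)); cb <- t(apply(B, 2, ci))
  if (all(ca[, 4] < 2) || all(cb[, 4] < 2))
    alx_abort("a group has fewer than 2 contributors in every bin",
              "actilux_insufficient_data_error")
  disjoint <- !is.na(ca[, 1]) & !is.na(cb[, 1]) &
    (ca[, 2] > cb[, 3] | cb[, 2] > ca[, 3])

  mid <- (seq_len(nb) - 0.5) * bin_minutes / 60
  bins <- data.frame(bin = seq_len(nb) - 1L, mid_hour = mid,
                     mean_a = ca[, 1], lo_a = ca[, 2], hi_a = ca[, 3],
                     n_a = ca[, 4],
                     mean_b = cb[, 1], lo_b = cb[, 2], hi_b = cb[, 3],
                     n_b = cb[, 4],
                     disjoint = disjoint)

  run <- longest_circular_run(disjoint, order_from = which.min(abs(mid - 12)))
  if (is.null(run)) {
    out <- list(empty = TRUE, start_bin = NA_integer_, end_bin = NA_integer_,
                start_hour = NA_real_, end_hour = NA_real_, n_bins = 0L,
                lower_group = NA_character_,
                threshold_curve = data.frame(bin = integer(), mid_hour = numeric(),
                                             threshold = numeric()),
                bins = bins, labels = labels, level = level)
    class(out) <- "ci_window"
    return(out)
  }
  idx <- run  # bin indices (1-based) of the window, in clock order
  a_lower <- mean(ca[idx, 1], na.rm = TRUE) < mean(cb[idx, 1], na.rm = TRUE)
  thr <- if (a_lower) ca[idx, 3] else cb[idx, 3]
  out <- list(
    empty = FALSE,
    start_bin = idx[1] - 1L, end_bin = idx[length(idx)] - 1L,
    start_hour = (idx[1] - 1L) * bin_minutes / 60,
    end_hour = ((idx[length(idx)]) * bin_minutes / 60) %% 24,
    n_bins = length(idx),
    lower_group = labels[if (a_lower) 1 else 2],
    threshold_curve = data.frame(bin = idx - 1L, mid_hour = mid[idx],
                                 threshold = thr),
    bins = bins, labels = labels, level = level)
  class(out) <- "ci_window"
  out
}

#' @export
print.ci_window <- function(x, ...) {
  if (x$empty) {
    cat("<ci_window> empty (all intervals overlap)\n")
  } else {
    cat(sprintf("<ci_window> %s-%s (%d bins); lower group: %s\n",
                hours_to_hhmm(x$start_hour), hours_to_hhmm(x$end_hour %% 24),
                x$n_bins, x$lower_group))
  }
  invisible(x)
}

# Longest run of TRUE on a circle of bins; returns 1-based indices in clock
# order or NULL if none. Ties: earliest start scanning clockwise from
# `order_from` (index). An all-TRUE circle returns the full cycle starting
# at `order_from`.
longest_circular_run <- function(flag, order_from = 1L) {
  n <- length(flag)
  if (!any(flag)) return(NULL)
  if (all(flag)) return(((order_from - 1L + 0:(n - 1L)) %% n) + 1L)
  ext <- c(flag, flag)
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & starts <= n)
  lens <- pmin(r$lengths[cand], n)
  best_len <- max(lens)
  best <- cand[lens == best_len]
  # tie-break: earliest start in clock order from order_from
  s <- starts[best]
  key <- (s - order_from) %% n
  s0 <- s[which.min(key)]
  ((s0 - 1L + 0:(best_len - 1L)) %% n) + 1L
}

#' Compare two independent correlations (Fisher z)
#'
#' \deqn{z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#'   \sqrt{1/(n_1-3) + 1/(n_2-3)}}
#' with a two-sided normal p-value; for independent samples only.
#'
#' @param r1,r2 Sample correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  alx_check(abs(r1) < 1 && abs(r2) < 1,
            "correlations of magnitude 1 cannot be compared",
            "actilux_degenerate_error")
  alx_check(n1 >= 4 && n2 >= 4, "need n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Stratified r-charts
#'
#' [compute_rchart()] applied within each stratum (e.g. MTNR1B G-allele
#' carriers vs CC homozygotes) on an identical bin grid. Strata with fewer
#' than 4 members are flagged not evaluable; the others are still returned.
#'
#' @param profiles Participants x bins matrix.
#' @param outcome Numeric outcome per participant.
#' @param strata Factor/vector assigning each participant to a stratum.
#' @param ... Passed to [compute_rchart()].
#' @return Named list of class `stratified_rchart`; each element is either an
#'   `rchart` or a list with `evaluable = FALSE` and the stratum size.
#' @export
stratified_rchart <- function(profiles, outcome, strata, ...) {
  profiles <- as.matrix(profiles)
  alx_check(nrow(profiles) == length(outcome) &&
              length(strata) == length(outcome),
            "profiles, outcome and strata must align")
  out <- list()
  for (lev in unique(as.character(strata))) {
    sel <- !is.na(strata) & as.character(strata) == lev
    if (sum(sel) < 4) {
      out[[lev]] <- list(evaluable = FALSE, n = sum(sel))
    } else {
      out[[lev]] <- compute_rchart(profiles[sel, , drop = FALSE],
                                   outcome[sel], ...)
    }
  }
  class(out) <- "stratified_rchart"
  out
}

#' Covariate-adjusted association
#'
#' Ordinary least squares of a standardized outcome on a standardized
#' predictor plus covariates (by default age, sex, population); returns the
#' predictor's standardized coefficient and p-value. A thin wrapper over
#' [stats::lm()] reproducing the adjusted-association table structure.
#'
#' @param data data.frame containing all variables.
#' @param outcome,predictor Column names (numeric).
#' @param covariates Character vector of covariate column names.
#' @return List with `coefficient` (standardized), `p`, `n`, and the fitted
#'   `model`.
#' @export
adjusted_association <- function(data, outcome, predictor,
                                 covariates = c("age", "sex", "population")) {
  alx_check(all(c(outcome, predictor, covariates) %in% names(data)),
            "outcome, predictor and covariates must be columns of data",
            "actilux_lookup_error")
  d <- data[, c(outcome, predictor, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  alx_check(nrow(d) >= length(covariates) + 2,
            "too few complete cases", "actilux_insufficient_data_error")
  d[[outcome]] <- as.numeric(scale(d[[outcome]]))
  d[[predictor]] <- as.numeric(scale(d[[predictor]]))
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit))))
    alx_abort("design matrix is rank deficient (collinear covariates)",
              "actilux_degenerate_error")
  sm <- summary(fit)$coefficients
  list(coefficient = sm[predictor, "Estimate"],
       p = sm[predictor, "Pr(>|t|)"],
       n = nrow(d), model = fit)
}
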