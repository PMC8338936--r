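# Linear quantile regression by direct pinball-loss minimisation.
#
# The tau-th conditional quantile of y given x is estimated by the line
# (a, b) minimising the check (pinball) loss
#   sum_i rho_tau(y_i - a - b x_i),  rho_tau(u) = u (tau - 1[u < 0]).
# For fixed slope b the optimal intercept is the tau-th (type-1) quantile of
# the residuals y - b x, and the profiled objective is convex piecewise
# linear in b, so a bracketed golden-section search recovers the global
# minimiser. Slope inference is by xy-pair bootstrap.

pinball_loss <- function(u, tau) sum(u * (tau - (u < 0)))

# type-1 tau-quantile: the pinball-optimal constant
quantile1 <- function(x, tau) {
  stats::quantile(x, probs = tau, type = 1, names = FALSE)
}

# fit (intercept, slope) for one tau
rq_fit1 <- function(x, y, tau) {
  prof <- function(b) {
    r <- y - b * x
    a <- quantile1(r, tau)
    pinball_loss(r - a, tau)
  }
  # bracket the convex profile around the OLS slope
  b0 <- stats::cov(x, y) / stats::var(x)
  span <- max(abs(b0), 4 * stats::sd(y) / stats::sd(x), 1e-8)
  lo <- b0 - span; hi <- b0 + span
  while (prof(lo) <= prof(lo + 1e-3 * span) && span < 1e8) {
    span <- span * 4; lo <- b0 - span
  }
  while (prof(hi) <= prof(hi - 1e-3 * span) && span < 1e8) {
    span <- span * 4; hi <- b0 + span
  }
  opt <- stats::optimize(prof, c(lo, hi), tol = 1e-10 * max(span, 1))
  b <- opt$minimum
  a <- quantile1(y - b * x, tau)
  c(intercept = a, slope = b)
}

#' Linear quantile regression (pinball loss) with bootstrap inference
#'
#' Fits, for each quantile level `tau`, the line minimising the pinball loss
#' of `y` on `x`. The default scale is log10-log10 (both variables must be
#' positive; zeros are dropped, as on the logarithmic axes of the front
#' scatter plots), with a raw-scale option. Slope confidence intervals and
#' p-values come from an xy-pair bootstrap (percentile interval; two-sided
#' p-value `2 * min(P(slope* <= 0), P(slope* >= 0))`, bounded below by
#' `1/n_boot`).
#'
#' @param x diagnostic values (e.g. colocated FSLE).
#' @param y AFC values.
#' @param taus quantile levels (defaults 0.75, 0.90, 0.95, 0.99).
#' @param scale `"log10"` (default) or `"raw"`.
#' @param n_boot bootstrap resamples for slope inference (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param min_n minimum sample size per fit (default 50).
#' @return data frame with one row per tau: `tau`, `slope`, `intercept`,
#'   `slope_lo`, `slope_hi` (95% percentile CI), `p`, `n`.
#' @export
quantile_regression <- function(x, y, taus = c(0.75, 0.90, 0.95, 0.99),
                                scale = c("log10", "raw"), n_boot = 1000,
                                seed = 1, min_n = 50) {
  scale <- match.arg(scale)
  if (any(taus <= 0 | taus >= 1)) {
    stop_cfg("quantile_regression: taus must lie in (0, 1)")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (scale == "log10") {
    pos <- x > 0 & y > 0
    x <- log10(x[pos]); y <- log10(y[pos])
  }
  n <- length(x)
  if (n < min_n) {
    stop_cfg("quantile_regression: n = ", n, " < ", min_n, " for taus ",
             paste(taus, collapse = ", "))
  }
  boot_idx <- with_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  })
  rows <- lapply(taus, function(tau) {
    fit <- rq_fit1(x, y, tau)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- boot_idx[b, ]
      rq_fit1(x[i], y[i], tau)[["slope"]]
    }, numeric(1))
    ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    p <- max(2 * min(mean(bs <= 0), mean(bs >= 0)), 1 / n_boot)
    data.frame(tau = tau, slope = fit[["slope"]],
               intercept = fit[["intercept"]],
               slope_lo = ci[1], slope_hi = ci[2], p = p, n = n)
  })
  do.call(rbind, rows)
}
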