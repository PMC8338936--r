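# Front/no-front statistics: threshold splits, Mann-Whitney, bootstrap
# difference of means, chlorophyll-gated regression.

#' Front-detection thresholds
#'
#' Reference values: FSLE 0.08/day, SST gradient 0.009 degC/km, chlorophyll
#' 0.22 mg/m^3 (FSLE analysis) and 0.17 mg/m^3 (SST-gradient analysis).
#'
#' @param fsle,sst_grad,chl_fsle,chl_sst_grad positive thresholds.
#' @export
front_thresholds <- function(fsle = 0.08, sst_grad = 0.009,
                             chl_fsle = 0.22, chl_sst_grad = 0.17) {
  if (any(c(fsle, sst_grad, chl_fsle, chl_sst_grad) <= 0)) {
    stop_cfg("front_thresholds: all thresholds must be > 0")
  }
  structure(list(fsle = fsle, sst_grad = sst_grad, chl_fsle = chl_fsle,
                 chl_sst_grad = chl_sst_grad), class = "front_thresholds")
}

#' Split AFC values by front proximity
#'
#' AFC values whose colocated diagnostic exceeds the threshold are "in
#' proximity of a front" (over group); the remainder form the under group.
#' Records with a missing diagnostic are excluded and counted.
#'
#' @param points data frame with column `afc` and the diagnostic column.
#' @param diagnostic `"fsle"` or `"sst_grad"`.
#' @param thresholds a [front_thresholds()] object (or a single number).
#' @return list with `over`, `under` (AFC vectors), `n_over`, `n_under`,
#'   `n_missing`, `threshold`.
#' @export
threshold_split <- function(points, diagnostic = c("fsle", "sst_grad"),
                            thresholds = front_thresholds()) {
  diagnostic <- match.arg(diagnostic)
  thr <- if (is.numeric(thresholds)) thresholds else thresholds[[diagnostic]]
  d <- points[[diagnostic]]
  if (is.null(d)) stop_cfg("threshold_split: no column '", diagnostic, "'")
  miss <- is.na(d) | is.na(points$afc)
  d <- d[!miss]; afc <- points$afc[!miss]
  over <- afc[d > thr]; under <- afc[d <= thr]
  list(over = over, under = under, n_over = length(over),
       n_under = length(under), n_missing = sum(miss), threshold = thr)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test of the null that the two samples come from the same
#' distribution: exact enumeration when both groups have at most 8 values
#' and there are no ties, normal approximation with tie correction
#' otherwise (via `stats::wilcox.test`).
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop_cfg("mann_whitney: empty group")
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bootstrap test on the difference of group means
#'
#' Builds the null distribution by pooling the two groups and resampling,
#' with replacement and `n_boot` times, two groups of the original sizes;
#' the two-sided p-value is the fraction of null |mean difference| at least
#' as large as the observed |mean difference|. Deterministic under a fixed
#' seed. If all pooled values are identical the test is degenerate and
#' returns p = 1 with a warning.
#'
#' @param over,under AFC groups (non-empty).
#' @param n_boot number of resamples (>= 1000).
#' @param seed RNG seed.
#' @return list with `mean_over`, `mean_under`, `n_over`, `n_under`, `p`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_mean_diff <- function(over, under, n_boot = 1000, seed = 1) {
  if (!length(over) || !length(under)) {
    stop_cfg("bootstrap_mean_diff: empty group")
  }
  if (n_boot < 1000) stop_cfg("bootstrap_mean_diff: n_boot must be >= 1000")
  res <- list(mean_over = mean(over), mean_under = mean(under),
              n_over = length(over), n_under = length(under),
              n_boot = n_boot, seed = seed)
  pool <- c(over, under)
  if (max(pool) == min(pool)) {
    warning("bootstrap_mean_diff: degenerate data (all values identical); p = 1")
    res$p <- 1
    return(res)
  }
  obs <- abs(res$mean_over - res$mean_under)
  n1 <- length(over); n2 <- length(under)
  null_diff <- with_seed(seed, {
    m1 <- matrix(sample(pool, n1 * n_boot, replace = TRUE), nrow = n_boot)
    m2 <- matrix(sample(pool, n2 * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(m1) - rowMeans(m2)
  })
  res$p <- mean(abs(null_diff) >= obs)
  res
}

#' Chlorophyll-gated linear regression of AFC on a front diagnostic
#'
#' Keeps the points whose colocated chlorophyll exceeds the threshold and
#' fits an ordinary (Pearson) linear regression of AFC on the diagnostic,
#' by default on log10-log10 scale (zeros dropped, as on logarithmic axes).
#'
#' @param points data frame with `afc`, `chl` and the diagnostic column.
#' @param diagnostic `"fsle"` or `"sst_grad"`.
#' @param chl_threshold gate value (mg/m^3); `-Inf` disables the gate.
#' @param scale `"log10"` (default) or `"raw"`.
#' @param min_n minimum number of gated points (default 10).
#' @return list with `R`, `R2`, `p`, `n`, `slope`, `intercept`.
#' @export
chl_gated_regression <- function(points, diagnostic = c("fsle", "sst_grad"),
                                 chl_threshold = 0.22,
                                 scale = c("log10", "raw"), min_n = 10) {
  diagnostic <- match.arg(diagnostic)
  scale <- match.arg(scale)
  d <- points[[diagnostic]]; y <- points$afc; chl <- points$chl
  keep <- !is.na(d) & !is.na(y)
  if (is.finite(chl_threshold)) {
    keep <- keep & !is.na(chl) & chl > chl_threshold
  }
  d <- d[keep]; y <- y[keep]
  if (scale == "log10") {
    pos <- d > 0 & y > 0
    d <- log10(d[pos]); y <- log10(y[pos])
  }
  n <- length(d)
  if (n < min_n) {
    stop_cfg("chl_gated_regression: only ", n,
             " points pass the gate (need >= ", min_n, ")")
  }
  ct <- stats::cor.test(d, y)
  fit <- stats::lm(y ~ d)
  list(R = unname(ct$estimate), R2 = unname(ct$estimate)^2, p = ct$p.value,
       n = n, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Sensitivity of the gated correlation to the chlorophyll threshold
#'
#' Recomputes [chl_gated_regression()] over a sweep of gate values.
#'
#' @inheritParams chl_gated_regression
#' @param thresholds vector of gate values.
#' @return data frame with `threshold`, `R`, `R2`, `p`, `n` (NA rows where
#'   fewer than `min_n` points pass).
#' @export
chl_gate_sweep <- function(points, diagnostic = c("fsle", "sst_grad"),
                           thresholds, scale = c("log10", "raw"),
                           min_n = 10) {
  diagnostic <- match.arg(diagnostic); scale <- match.arg(scale)
  rows <- lapply(thresholds, function(th) {
    r <- tryCatch(
      chl_gated_regression(points, diagnostic, th, scale, min_n),
      error = function(e) list(R = NA_real_, R2 = NA_real_, p = NA_real_,
                               n = NA_integer_)
    )
    data.frame(threshold = th, R = r$R, R2 = r$R2, p = r$p, n = r$n)
  })
  do.call(rbind, rows)
}
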