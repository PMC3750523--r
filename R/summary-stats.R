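#' Noise of a copy-number series
#'
#' The squared coefficient of variation `eta = var / mean^2` of a molecular
#' count series, the standard dimensionless noise measure for protein and
#' mRNA copy numbers.
#'
#' @param series Nonempty numeric series with positive mean.
#' @return Nonnegative scalar.
#' @examples
#' eta(c(0, 2))  # 1.0
#' @export
eta <- function(series) {
  if (length(series) == 0L) stop("series is empty")
  m <- mean(series)
  if (m <= 0) stop("eta undefined: series mean is not positive")
  # population variance: eta of a constant series is exactly 0
  v <- mean((series - m)^2)
  v / m^2
}

#' Mean and noise with batch-means Monte Carlo standard errors
#'
#' Samples from one long trajectory are autocorrelated, so naive standard
#' errors underestimate the Monte Carlo uncertainty.  The series is split
#' into `batches` contiguous batches; the statistic is computed per batch
#' and its standard error taken as `sd(batch values) / sqrt(batches)`.
#'
#' @param series Numeric count series.
#' @param batches Number of contiguous batches (default 20).
#' @param burn_in Number of leading samples to drop before computing
#'   statistics (default 0: the transient is included, matching the
#'   sampling protocol of the reference experiments).
#' @return List with `mean`, `eta`, `se_mean`, `se_eta`, `n`.
#' @export
series_stats <- function(series, batches = 20L, burn_in = 0L) {
  if (burn_in > 0) series <- series[-seq_len(burn_in)]
  n <- length(series)
  if (n < 2L * batches) stop("series too short for ", batches, " batches")
  idx <- cut(seq_len(n), batches, labels = FALSE)
  bm <- tapply(series, idx, mean)
  be <- tapply(series, idx, function(s) {
    m <- mean(s)
    if (m > 0) mean((s - m)^2) / m^2 else NA_real_
  })
  list(mean = mean(series),
       eta = if (mean(series) > 0) eta(series) else NA_real_,
       se_mean = sd(bm) / sqrt(batches),
       se_eta = sd(be[is.finite(be)]) /
         sqrt(max(1L, sum(is.finite(be)))),
       n = n)
}

#' Gain of a statistic relative to a null model
#'
#' `gain = tested / null`; values above 1 mean the tested model exhibits
#' larger values of the statistic than the null model.  Monte Carlo
#' standard errors, if supplied, are propagated to the ratio by the delta
#' method.
#'
#' @param tested,null Statistic values (null must be `> 0`).
#' @param se_tested,se_null Optional Monte Carlo standard errors.
#' @param statistic Label (`"mean"` or `"eta"`).
#' @return A `gain_result`: list with `statistic`, `tested`, `null`,
#'   `gain`, `se`.
#' @examples
#' gain(0.5, 1.0)$gain  # 0.5
#' @export
gain <- function(tested, null, se_tested = 0, se_null = 0,
                 statistic = "mean") {
  if (!is.numeric(null) || length(null) != 1L || !is.finite(null) ||
      null <= 0)
    stop("null statistic must be a single positive number")
  if (!is.numeric(tested) || length(tested) != 1L || !is.finite(tested))
    stop("tested statistic must be a single finite number")
  g <- tested / null
  se <- abs(g) * sqrt((se_tested / tested)^2 + (se_null / null)^2)
  if (tested == 0) se <- se_tested / null
  structure(list(statistic = statistic, tested = tested, null = null,
                 gain = g, se = se), class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("%s gain: %.4g (tested %.4g / null %.4g), MC se %.2g\n",
              x$statistic, x$gain, x$tested, x$null, x$se))
  invisible(x)
}

#' Cross-correlation between two count series
#'
#' Mean-centered, variance-normalized (Pearson-type) cross-correlation on a
#' lag grid, with the zero-lag value and the half-life of the correlation
#' decay: the smallest lag at which the symmetrized correlation
#' `(cc(+l) + cc(-l)) / 2` first drops to half the zero-lag value, located
#' by linear interpolation between grid points (`NA` if the correlation
#' never decays that far within `max_lag`).
#'
#' @param x,y Equal-length series on a common sampling grid.
#' @param max_lag Largest lag, in time units; must be below half the span.
#' @param dt Sampling interval of the grid (time units per sample).
#' @return A `crosscorr_result`: list with `lag` (signed, time units),
#'   `cc`, `zero_lag`, `half_life`.
#' @examples
#' x <- rnorm(500)
#' cross_correlation(x, x, max_lag = 10, dt = 1)$zero_lag  # 1
#' @export
cross_correlation <- function(x, y, max_lag, dt = 1) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (sd(x) == 0 || sd(y) == 0)
    stop("cross-correlation undefined for a zero-variance series")
  lag_max <- floor(max_lag / dt + 1e-9)
  if (lag_max < 1) stop("max_lag below one sampling interval")
  if (2 * lag_max >= length(x))
    stop("max_lag must be less than half the series span")
  cc <- ccf(x, y, lag.max = lag_max, plot = FALSE, demean = TRUE)
  vals <- as.vector(cc$acf)
  lags <- as.vector(cc$lag) * dt
  zero <- vals[lags == 0]
  pos <- vals[lags >= 0]
  neg <- rev(vals[lags <= 0])
  sym <- (pos + neg) / 2
  half <- zero / 2
  half_life <- NA_real_
  below <- which(sym <= half)
  below <- below[below > 1L]
  if (length(below)) {
    i <- below[1]
    # linear interpolation between grid points (i-1, i)
    l0 <- (i - 2) * dt; l1 <- (i - 1) * dt
    c0 <- sym[i - 1]; c1 <- sym[i]
    half_life <- if (c0 == c1) l1 else l0 + (c0 - half) / (c0 - c1) *
      (l1 - l0)
  }
  structure(list(lag = lags, cc = vals, zero_lag = zero,
                 half_life = half_life),
            class = "crosscorr_result")
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("cross-correlation: zero-lag %.4f, half-life %s (max lag %g)\n",
              x$zero_lag,
              if (is.na(x$half_life)) "not reached"
              else sprintf("%.3f", x$half_life),
              max(x$lag)))
  invisible(x)
}

#' Mean switching time of a toggle switch
#'
#' Classifies each sample of the two repressor-multimer series into state A
#' (`p1 > p2`), state B (`p1 < p2`), or a tie.  Ties are assigned to the
#' incumbent state (no switch on a tie), so low-copy-number equality does
#' not inflate the switch count; leading ties before the first strict
#' inequality are dropped.  A switch is a transition between A and B; the
#' dwell time is `dt` times the number of samples between consecutive
#' switches, and the mean is over completed dwells only.
#'
#' @param p1,p2 Equal-length count series of the two repressor multimers.
#' @param dt Sampling interval in time units.
#' @return A `switching_result`: list with `mean_switching_time`,
#'   `n_switches`, `dwell_times`, and per-state dwell lists `dwell_A`
#'   (dwells ending a stay in A) and `dwell_B`.
#' @export
mean_switching_time <- function(p1, p2, dt) {
  if (length(p1) != length(p2)) stop("series lengths differ")
  state <- ifelse(p1 > p2, 1L, ifelse(p1 < p2, -1L, 0L))
  keep <- which(state != 0L)
  if (length(keep) == 0L)
    stop("insufficient data: the two series are tied throughout")
  # ties inherit the incumbent state
  first <- keep[1]
  s <- state
  for (i in seq_along(s)) {
    if (i < first) s[i] <- NA_integer_
    else if (s[i] == 0L) s[i] <- s[i - 1]
  }
  s <- s[!is.na(s)]
  switch_at <- which(diff(s) != 0L) + 1L  # first sample of the new state
  if (length(switch_at) < 2L)
    stop("insufficient data: fewer than 2 switches observed")
  dwell <- diff(switch_at) * dt
  ending_state <- s[switch_at[-length(switch_at)]]  # state just entered
  structure(list(
    mean_switching_time = mean(dwell),
    n_switches = length(switch_at),
    dwell_times = dwell,
    dwell_A = dwell[ending_state == 1L],
    dwell_B = dwell[ending_state == -1L]),
    class = "switching_result")
}

#' @export
print.switching_result <- function(x, ...) {
  cat(sprintf("mean switching time %.4g over %d switches\n",
              x$mean_switching_time, x$n_switches))
  invisible(x)
}

#' Fraction of sampling times indistinguishable from the final state
#'
#' A stationarity check over replicate trajectories: at each grid time the
#' cross-replicate distribution of counts is compared with the distribution
#' at the final time by a two-sample Kolmogorov-Smirnov test; the returned
#' value is the fraction of grid times at which the test does not reject at
#' level `alpha`.  For a system that is effectively at equilibrium over the
#' whole run this fraction is about `1 - alpha`.
#'
#' @param replicates Either a numeric matrix (replicates x times) or a list
#'   of `trajectory` objects on a common grid (then `species` is required).
#' @param species Species to extract when `replicates` is a trajectory
#'   list.
#' @param alpha Test level (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
stationarity_fraction <- function(replicates, species = NULL,
                                  alpha = 0.05) {
  if (is.list(replicates) && !is.matrix(replicates)) {
    if (is.null(species))
      stop("species must be given for a list of trajectories")
    replicates <- do.call(rbind, lapply(replicates, species_series,
                                        species = species))
  }
  if (!is.matrix(replicates)) stop("replicates must form a matrix")
  if (nrow(replicates) < 2L) stop("need at least 2 replicates")
  final <- replicates[, ncol(replicates)]
  ok <- vapply(seq_len(ncol(replicates)), function(t) {
    col <- replicates[, t]
    if (identical(col, final)) return(TRUE)
    p <- suppressWarnings(ks.test(col, final)$p.value)
    p > alpha
  }, logical(1))
  mean(ok)
}
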