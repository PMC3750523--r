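# Noise, gain, cross-correlation, switching-time, and stationarity
# statistics.

test_that("eta is the squared coefficient of variation", {
  expect_equal(eta(c(5, 5, 5)), 0)
  expect_equal(eta(c(0, 2)), 1)       # var 1 (population), mean 1
  expect_error(eta(numeric()), "empty")
  expect_error(eta(c(0, 0, 0)), "mean")
  # Poisson stationary samples: eta ~ 1/mean
  set.seed(11)
  x <- rpois(2e4, 10)
  s <- series_stats(x)
  expect_lt(abs(s$eta - 0.1) / s$se_eta, 3)
})

test_that("gain is the tested/null ratio with propagated error", {
  expect_equal(gain(0.5, 1.0)$gain, 0.5)
  expect_equal(gain(3.2, 3.2)$gain, 1.0)
  g <- gain(2, 4, se_tested = 0.2, se_null = 0.4)
  expect_equal(g$se, 0.5 * sqrt(0.01 + 0.01))
  expect_error(gain(1, 0), "positive")
  expect_error(gain(1, -2), "positive")
})

test_that("cross-correlation is Pearson-normalized on the lag grid", {
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  self <- cross_correlation(x, x, max_lag = 50, dt = 1)
  expect_equal(self$zero_lag, 1, tolerance = 1e-10)
  expect_true(all(abs(self$cc) <= 1 + 1e-8))
  # AR(1) with coefficient 0.9 decays to 1/2 at lag log(0.5)/log(0.9)
  expect_equal(self$half_life, log(0.5) / log(0.9), tolerance = 0.8)

  # pure shift: argmax of cc at the shift lag
  n <- 3000
  y <- c(x[6:length(x)], rnorm(5))   # y_t = x_{t+5}
  cc <- cross_correlation(x[1:1000], y[1:1000], max_lag = 20, dt = 0.5)
  expect_equal(cc$lag[which.max(cc$cc)], 5 * 0.5)

  # independent white noise: zero-lag correlation ~ 0
  set.seed(22)
  a <- rnorm(5000); b <- rnorm(5000)
  cc0 <- cross_correlation(a, b, max_lag = 10, dt = 1)
  expect_lt(abs(cc0$zero_lag), 3 / sqrt(5000))

  expect_error(cross_correlation(rep(1, 100), rnorm(100), max_lag = 5),
               "zero-variance")
  expect_error(cross_correlation(rnorm(10), rnorm(10), max_lag = 6),
               "half the series span")
})

test_that("half-life interpolates linearly between grid points", {
  # construct series whose correlation decays exactly linearly in lag:
  # impossible directly, so verify interpolation on a known exponential
  # decay: OU-like AR(1) with lag-1 correlation rho has cc(l) = rho^l,
  # crossing 1/2 between integer lags; compare against the closed form
  rho <- 0.7
  set.seed(31)
  x <- as.numeric(arima.sim(list(ar = rho), 5e4))
  cc <- cross_correlation(x, x, max_lag = 20, dt = 1)
  expect_equal(cc$half_life, log(0.5) / log(rho), tolerance = 0.1)
  expect_false(is.na(cc$half_life))
})

test_that("switching times count strict-state transitions", {
  # alternating states, dt = 1: every dwell is one sample long
  p1 <- rep(c(2, 0), 10)
  p2 <- rep(c(0, 2), 10)
  sw <- mean_switching_time(p1, p2, dt = 1)
  expect_equal(sw$mean_switching_time, 1)
  expect_equal(length(sw$dwell_times), sw$n_switches - 1L)

  # no switch at all
  expect_error(mean_switching_time(rep(2, 50), rep(0, 50), dt = 1),
               "fewer than 2 switches")

  # ties interleaved inside a run of A do not create switches
  p1 <- c(3, 2, 3, 1, 3)
  p2 <- c(1, 2, 1, 3, 1)
  sw2 <- mean_switching_time(p1, p2, dt = 1)
  expect_equal(sw2$n_switches, 2L)
  expect_equal(sw2$mean_switching_time, 1)

  # scaling by the sampling interval
  sw3 <- mean_switching_time(rep(c(2, 0), 10), rep(c(0, 2), 10),
                             dt = 1 / 30)
  expect_equal(sw3$mean_switching_time, 1 / 30)
})

test_that("stationarity fraction matches the KS level", {
  # identical constant replicates: nothing distinguishable
  m <- matrix(5, nrow = 50, ncol = 40)
  expect_equal(stationarity_fraction(m), 1)

  # iid stationary replicates: non-rejection at least 1 - alpha
  set.seed(41)
  m2 <- matrix(rpois(200 * 60, 5), nrow = 200)
  expect_gte(stationarity_fraction(m2), 0.90)

  # forced violation over the first 5% of the grid
  m3 <- m2
  m3[, 1:3] <- 0
  expect_lte(stationarity_fraction(m3), 0.95)

  expect_error(stationarity_fraction(m2[1, , drop = FALSE]),
               "2 replicates")
})

test_that("stationarity holds over replicate trajectories of a gene", {
  p <- expression_params(k_M = 2, d_M = 1, k_P = 2, alpha_M = 1)
  mod <- build_homomer_system(p, multimer_params(2))
  reps <- lapply(1:150, function(s)
    simulate_reactions(mod, t_end = 50, seed = 5000 + s))
  frac <- stationarity_fraction(reps, species = "P1x2")
  # transient from the empty state occupies only the first few time units
  expect_gte(frac, 0.85)
})
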