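# Exactness, delays, instant-reaction resolution, and bookkeeping of the
# event-driven simulator.

birth_death <- function(rate_in = 10, rate_out = 1) {
  list(reaction(character(), c(M = 1), rate = rate_in, name = "birth"),
       reaction(c(M = 1), character(), rate = rate_out, name = "death"))
}

test_that("birth-death process is Poisson at stationarity", {
  tr <- simulate_reactions(birth_death(), c(M = 0), t_end = 5000,
                           sample_interval = 1, seed = 101)
  m <- species_series(tr, "M")
  ss <- series_stats(m)
  expect_lt(abs(ss$mean - 10) / ss$se_mean, 3)
  # Fano factor of Poi(10) is 1; batch SE of the Fano via eta * mean
  fano <- var(m) / mean(m)
  expect_lt(abs(fano - 1), 0.1)
})

test_that("empty model and missing reactions leave the state constant", {
  mod <- list(reaction(c(A = 1), c(B = 1), rate = 0, name = "never"))
  tr <- simulate_reactions(mod, c(A = 3, B = 1), t_end = 10, seed = 1)
  expect_true(all(species_series(tr, "A") == 3))
  expect_true(all(species_series(tr, "B") == 1))
})

test_that("a delayed product appears only after its delay has elapsed", {
  mod <- list(reaction(c(A = 1), c(B = 1), rate = 1000,
                       delay = delay_fixed(2), name = "convert"))
  tr <- simulate_reactions(mod, c(A = 1, B = 0), t_end = 5,
                           sample_interval = 0.25, seed = 7)
  b <- species_series(tr, "B")
  expect_true(all(b[tr$time < 2] == 0))
  expect_equal(b[length(b)], 1L)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- expression_params(k_M = 5, d_M = 1, k_P = 2, alpha_M = 2)
  mod <- build_homomer_system(p, multimer_params(3))
  t1 <- simulate_reactions(mod, t_end = 200, seed = 33)
  t2 <- simulate_reactions(mod, t_end = 200, seed = 33)
  t3 <- simulate_reactions(mod, t_end = 200, seed = 34)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))
})

test_that("fixed-delay release reproduces the shifted firing process", {
  # pure A -> B with delay tau: B(t) must equal the number of firings at
  # or before t - tau, for every sampling time
  tau <- 1.5
  mod <- list(reaction(c(A = 1), c(B = 1), rate = 0.8,
                       delay = delay_fixed(tau), name = "fire"))
  tr <- simulate_reactions(mod, c(A = 50, B = 0), t_end = 40,
                           sample_interval = 0.5, seed = 12,
                           record_events = TRUE)
  fired <- tr$events$time
  expected_b <- vapply(tr$time, function(t)
    sum(fired <= t - tau + 1e-12), integer(1))
  expect_equal(unname(species_series(tr, "B")), expected_b)
})

test_that("no molecules are lost or duplicated between firing and release", {
  # stop mid-delay so the waitlist is nonempty: initial + net stoichiometry
  # of all firings must equal final counts + pending releases
  p <- expression_params(k_M = 2, d_M = 0.5, k_P = 1, alpha_M = 3,
                         tau_P = 2)
  mod <- build_monomer_gene(p)
  tr <- simulate_reactions(mod, t_end = 30, seed = 5)
  final <- tr$counts[nrow(tr$counts), ]
  init <- c(S1 = 1, M1 = 0, P1 = 0, X1 = 0)[names(final)]
  net <- setNames(numeric(length(final)), names(final))
  for (j in seq_along(mod)) {
    rx <- mod[[j]]
    for (s in names(rx$reactants))
      net[s] <- net[s] - rx$reactants[[s]] * tr$firings[[j]]
    for (s in names(rx$products))
      net[s] <- net[s] + rx$products[[s]] * tr$firings[[j]]
  }
  expect_equal(unname(init + net), unname(final + tr$pending))
  expect_gt(sum(tr$pending), 0)  # the run really did end mid-delay
})

test_that("instant reactions resolve greedily in priority order", {
  dimerize <- reaction(c(P = 2), c(D = 1), rate = Inf,
                       instant_priority = 2)
  res <- resolve_instants(list(dimerize), c(P = 5, D = 0))
  expect_equal(res[["P"]], 1L)
  expect_equal(res[["D"]], 2L)

  # trimer system under max-order-first priority: 7 monomers ->
  # 2 trimers + 1 monomer, no dimers left
  p <- expression_params(k_M = 1, d_M = 1, k_P = 1)
  trimer_rxns <- Filter(function(r) is.infinite(r$rate),
                        build_homomer_system(p, multimer_params(3)))
  res <- resolve_instants(trimer_rxns, c(P1 = 7, P1x2 = 0, P1x3 = 0))
  expect_equal(res[["P1x3"]], 2L)
  expect_equal(res[["P1"]], 1L)
  expect_equal(res[["P1x2"]], 0L)

  # no instant reactions: identity
  mod <- list(reaction(c(A = 1), c(B = 1), rate = 1))
  expect_equal(resolve_instants(mod, c(A = 4, B = 0))[["A"]], 4L)
})

test_that("delay distributions sample with the stated moments", {
  set.seed(42)
  n <- 1e5
  # gamma parameterized by (alpha_M, k_M): mean 1/k_M, CV alpha_M^(-1/2)
  d <- transcription_delay(alpha_M = 4, k_M = 1)
  x <- draw_delay(d, n)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 1) / (sd(x) / sqrt(n)), 3)
  cv <- sd(x) / mean(x)
  expect_lt(abs(cv - 0.5), 0.01)

  d2 <- transcription_delay(alpha_M = 1, k_M = 2)
  y <- draw_delay(d2, n)
  expect_lt(abs(mean(y) - 0.5) / (sd(y) / sqrt(n)), 3)
  expect_lt(abs(sd(y) / mean(y) - 1), 0.02)

  expect_identical(draw_delay(delay_none(), 10), rep(0, 10))
  expect_error(transcription_delay(alpha_M = -1, k_M = 2), "alpha_M")
  expect_error(transcription_delay(alpha_M = 1, k_M = 0), "k_M")
  expect_error(delay_gamma(0, 1), "shape")
})

test_that("invalid rate laws are rejected with the reaction named", {
  bad <- list(reaction(character(), c(A = 1),
                       rate = function(counts) NaN, name = "badrate"))
  expect_error(simulate_reactions(bad, c(A = 0), t_end = 1, seed = 1),
               "badrate")
  expect_error(reaction(c(A = 1), c(B = 1), rate = -2), "rate")
  expect_error(reaction(c(A = -1), c(B = 1), rate = 1), "nonnegative")
  expect_error(reaction(character(), character(), rate = 1),
               "at least one")
})

test_that("state-dependent R-function rates are honored", {
  # self-limiting birth: propensity 5 when A < 3, else 0
  mod <- list(
    reaction(character(), c(A = 1),
             rate = function(counts) if (counts[["A"]] < 3) 5 else 0,
             name = "capped"))
  tr <- simulate_reactions(mod, c(A = 0), t_end = 50, seed = 2)
  expect_equal(max(species_series(tr, "A")), 3L)
})

test_that("stationary distribution matches the master-equation oracle", {
  # small homodimer system with finite association/dissociation rates;
  # counts stay far below the truncation box
  kM <- 1; dM <- 1; kP <- 1; dP <- 1; a <- 0.5; u <- 1
  orc <- ctmc_stationary_mpd(kM, dM, kP, dP, a, u,
                             Mmax = 12, Pmax = 16, Dmax = 7)
  p <- expression_params(k_M = kM, d_M = dM, k_P = kP, alpha_M = 1,
                         d_P = dP)
  mod <- build_homomer_system(p, multimer_params(2, a = a, u = u))
  tr <- simulate_reactions(mod, t_end = 2e4, sample_interval = 2,
                           seed = 11)
  M <- species_series(tr, "M1")
  P <- species_series(tr, "P1")
  D <- species_series(tr, "P1x2")
  expect_true(max(M) <= 12 && max(P) <= 16 && max(D) <= 7)
  gof <- chisq_vs_ctmc(orc$id(M, P, D), orc$pi)
  expect_gt(gof$p.value, 0.01)
})
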