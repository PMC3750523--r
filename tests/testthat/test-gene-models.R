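# Structure and statistics of the reaction-system builders, and the
# transcription-interval fitting machinery.

test_that("parameter constructors validate their domains", {
  expect_error(expression_params(k_M = 0, d_M = 1, k_P = 1), "k_M")
  expect_error(expression_params(k_M = 1, d_M = -1, k_P = 1), "d_M")
  expect_error(expression_params(k_M = 1, d_M = 1, k_P = 1, tau_P = -1),
               "tau_P")
  expect_error(multimer_params(0), "N")
  expect_error(multimer_params(2, u = -1), "u")
  expect_error(toggle_params(C = 0), "C")
})

test_that("monomer gene reaches the analytic stationary means", {
  p <- expression_params(k_M = 10, d_M = 1, k_P = 10, alpha_M = 1)
  tr <- simulate_reactions(build_monomer_gene(p), t_end = 4000, seed = 21)
  m <- series_stats(species_series(tr, "M1"))
  pr <- series_stats(species_series(tr, "P1"))
  expect_lt(abs(m$mean - 10) / m$se_mean, 3)       # k_M / d_M
  expect_lt(abs(pr$mean - 100) / pr$se_mean, 3.5)  # k_M k_P / (d_M d_P)
  # alpha_M = 1: Poisson mRNA, Fano factor 1
  mm <- species_series(tr, "M1")
  expect_lt(abs(var(mm) / mean(mm) - 1), 0.1)
})

test_that("alpha_M > 1 gives sub-Poissonian mRNA statistics", {
  v <- vapply(c(1, 10), function(a) {
    p <- expression_params(k_M = 10, d_M = 1, k_P = 1, alpha_M = a)
    tr <- simulate_reactions(build_monomer_gene(p), t_end = 4000,
                             seed = 9)
    var(species_series(tr, "M1"))
  }, numeric(1))
  expect_lt(v[2], v[1])          # variance shrinks with alpha_M
  expect_lt(v[2], 10)            # strictly sub-Poissonian (mean 10)
})

test_that("homomer builder enumerates the association lattice", {
  p <- expression_params(k_M = 1, d_M = 1, k_P = 1)

  m2 <- build_homomer_system(p, multimer_params(2, a = 1, u = 0.5))
  extra <- m2[-(1:4)]  # beyond the 4 monomer-gene reactions
  kinds <- vapply(extra, function(r) sub("_.*", "", r$name), character(1))
  expect_equal(as.integer(table(kinds)[c("assoc", "dissoc", "decay")]),
               c(1L, 1L, 1L))

  m4 <- build_homomer_system(p, multimer_params(4))
  assoc <- Filter(function(r) grepl("^assoc", r$name), m4)
  expect_setequal(
    vapply(assoc, function(r) r$name, character(1)),
    c("assoc_P1+P1", "assoc_P1+P1x2", "assoc_P1+P1x3",
      "assoc_P1x2+P1x2"))  # (n,k) in {(2,1),(3,1),(4,1),(4,2)}

  # degradation of the trimer proceeds at 3 * d_P
  m3 <- build_homomer_system(p, multimer_params(3))
  deg3 <- Filter(function(r) r$name == "decay_P1x3", m3)[[1]]
  expect_equal(deg3$rate, 3 * p$d_P)
  expect_equal(names(deg3$products), "P1x2")

  expect_error(build_homomer_system(p, multimer_params(1)), "N >= 2")
})

test_that("with zero association the homomer reduces to the monomer", {
  p <- expression_params(k_M = 5, d_M = 1, k_P = 2, alpha_M = 1)
  mono <- simulate_reactions(build_monomer_gene(p), t_end = 2000,
                             seed = 17)
  homo <- simulate_reactions(
    build_homomer_system(p, multimer_params(2, a = 0, u = 0)),
    t_end = 2000, seed = 17)
  expect_true(all(species_series(homo, "P1x2") == 0))
  s1 <- series_stats(species_series(mono, "X1"))
  s2 <- series_stats(species_series(homo, "X1"))
  expect_lt(abs(s1$mean - s2$mean) /
              sqrt(s1$se_mean^2 + s2$se_mean^2), 3)
})

test_that("heterodimer construction degrades one subunit at a time", {
  p <- expression_params(k_M = 2, d_M = 1, k_P = 2)
  mod <- build_heterodimer_system(p, p, a12 = Inf, u12 = 0)
  d1 <- Filter(function(r) r$name == "decay_P12_subunit1", mod)[[1]]
  # the dimer loses subunit 1 and yields the surviving monomer P2
  expect_equal(names(d1$products), "P2")
  expect_equal(sum(d1$products), 1L)
  expect_equal(names(d1$propensity), "P12")

  # symmetric parameters: the two totals agree statistically
  tr <- simulate_reactions(mod, t_end = 2000, seed = 23)
  s1 <- series_stats(species_series(tr, "X1"))
  s2 <- series_stats(species_series(tr, "X2"))
  expect_lt(abs(s1$mean - s2$mean) /
              sqrt(s1$se_mean^2 + s2$se_mean^2), 3)
})

test_that("instant association at high expression pairs almost all monomers", {
  p <- expression_params(k_M = 10, d_M = 1, k_P = 10)
  tr <- simulate_reactions(build_heterodimer_system(p, p), t_end = 2000,
                           seed = 29)
  mu_dimer <- mean(species_series(tr, "P12"))
  mu_x1 <- mean(species_series(tr, "X1"))
  expect_gt(mu_dimer / mu_x1, 0.85)  # nearly all protein dimerized
})

test_that("toggle repression follows the promoter occupancy law", {
  tp <- toggle_params(C = 1, N = 2)
  mod <- build_toggle_switch(tp)
  # derived constants: k'_M = 5 N d_M = 60, K = 25 C
  expect_equal(tp$k_M_max, 60)
  expect_equal(tp$K, 25)
  state0 <- c(M1 = 0, P1 = 0, P1x2 = 0, M2 = 0, P2 = 0, P2x2 = 0)
  a0 <- propensities(mod, state0)
  expect_equal(unname(a0["transcription_1"]), 60)  # no repressor: k'_M
  aK <- propensities(mod, replace(state0, "P2x2", 25))
  expect_equal(unname(aK["transcription_1"]), 30)  # P = K: k'_M / 2
  # C -> infinity: repression vanishes even at high repressor counts
  big <- build_toggle_switch(toggle_params(C = 1e12, N = 2))
  ab <- propensities(big, replace(state0, "P2x2", 1000))
  expect_equal(unname(ab["transcription_1"]),
               toggle_params(C = 1e12, N = 2)$k_M_max, tolerance = 1e-6)

  expect_error(build_toggle_switch(toggle_params(C = 1, alpha_M = 2)),
               "alpha_M = 1")
})

test_that("gamma interval fit recovers generating parameters", {
  set.seed(301)
  x <- rgamma(1e4, shape = 2.27, scale = 1070)
  f <- fit_interval_models(x)
  expect_lt(abs(f$gamma$shape - 2.27) / 2.27, 0.1)
  expect_lt(abs(f$gamma$scale - 1070) / 1070, 0.1)
  expect_equal(f$preferred, "gamma")

  # exponential data: gamma family contains it, shape -> 1
  set.seed(302)
  z <- rexp(1e4)
  fz <- fit_interval_models(z)
  se_shape <- fz$gamma$shape / sqrt(length(z))  # rough asymptotic scale
  expect_lt(abs(fz$gamma$shape - 1), 5 * se_shape)
})

test_that("three-exponential data prefers the hypoexponential model", {
  set.seed(303)
  y <- rhypoexp(1e4, c(1, 5, 25))
  f <- fit_interval_models(y)
  expect_gte(f$hypoexp$loglik, f$gamma$loglik)
  expect_equal(f$preferred, "hypoexp")
  # rate recovery for well-separated stages
  expect_equal(f$hypoexp$rates, c(1, 5, 25), tolerance = 0.25)
})

test_that("interval fitting rejects unusable samples", {
  expect_error(fit_interval_models(rep(2, 100)), "degenerate")
  expect_error(fit_interval_models(c(1, 2, 3)), "at least 10")
  expect_error(fit_interval_models(c(rep(1.5, 20), -1)), "positive")
})

test_that("hypoexponential density integrates to one and matches moments", {
  rates <- c(0.5, 2, 7)
  expect_equal(integrate(dhypoexp, 0, Inf, rates = rates)$value, 1,
               tolerance = 1e-6)
  set.seed(304)
  x <- rhypoexp(2e4, rates)
  expect_equal(mean(x), sum(1 / rates), tolerance = 0.05)
})
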