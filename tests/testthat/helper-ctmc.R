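# Independent master-equation oracle for the small homodimer system with
# exponential (alpha_M = 1) transcription, finite association/dissociation,
# and no delays.  The continuous-time Markov chain on (M, P, D) is built
# directly from the closed-form propensities -- production of M at k_M
# (renewal of Exp(1/k_M) intervals = Poisson process), M decay at d_M*M,
# translation at k_P*M, monomer decay at d_P*P, dimerization at
# a*P*(P-1)/2, dissociation at u*D, and dimer-subunit decay at 2*d_P*D --
# and its stationary distribution solved by dense linear algebra on a
# truncated state space.  It shares no code with the simulation engine.
ctmc_stationary_mpd <- function(kM, dM, kP, dP, a, u, Mmax, Pmax, Dmax) {
  dims <- c(Mmax + 1, Pmax + 1, Dmax + 1)
  nst <- prod(dims)
  id <- function(M, P, D) M + (Mmax + 1) * (P + (Pmax + 1) * D) + 1
  Q <- matrix(0, nst, nst)
  for (M in 0:Mmax) for (P in 0:Pmax) for (D in 0:Dmax) {
    s <- id(M, P, D)
    if (M < Mmax) Q[s, id(M + 1, P, D)] <- Q[s, id(M + 1, P, D)] + kM
    if (M > 0) Q[s, id(M - 1, P, D)] <- Q[s, id(M - 1, P, D)] + dM * M
    if (P < Pmax) Q[s, id(M, P + 1, D)] <- Q[s, id(M, P + 1, D)] + kP * M
    if (P > 0) Q[s, id(M, P - 1, D)] <- Q[s, id(M, P - 1, D)] + dP * P
    if (P >= 2 && D < Dmax)
      Q[s, id(M, P - 2, D + 1)] <- Q[s, id(M, P - 2, D + 1)] +
        a * P * (P - 1) / 2
    if (D > 0 && P <= Pmax - 2)
      Q[s, id(M, P + 2, D - 1)] <- Q[s, id(M, P + 2, D - 1)] + u * D
    if (D > 0)
      Q[s, id(M, P + 1, D - 1)] <- Q[s, id(M, P + 1, D - 1)] + 2 * dP * D
  }
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[nst, ] <- 1
  pi <- solve(A, c(rep(0, nst - 1), 1))
  list(pi = pmax(pi, 0), id = id, nst = nst)
}

# chi-square goodness of fit of observed state ids against stationary
# probabilities, pooling cells with expected count below 5
chisq_vs_ctmc <- function(state_ids, pi) {
  n <- length(state_ids)
  obs <- tabulate(state_ids, nbins = length(pi))
  expd <- pi * n
  keep <- expd >= 5
  o <- c(obs[keep], sum(obs[!keep]))
  e <- c(expd[keep], sum(expd[!keep]))
  x2 <- sum((o - e)^2 / e)
  df <- length(o) - 1
  list(statistic = x2, df = df,
       p.value = pchisq(x2, df, lower.tail = FALSE))
}
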