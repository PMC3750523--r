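#' Gene expression parameters
#'
#' Parameter vector of the stochastic gene expression model.  Time is in
#' units of the mean protein lifetime, i.e. `d_P = 1` by convention.
#' Transcription is a renewal process whose intervals are gamma distributed
#' with mean `1 / k_M` and CV `alpha_M^(-1/2)`: `alpha_M = 1` gives Poisson
#' mRNA numbers `M ~ Poi(k_M / d_M)`, `alpha_M > 1` sub-Poissonian and
#' `alpha_M < 1` super-Poissonian mRNA statistics.
#'
#' @param k_M Mean transcription rate (transcripts per protein lifetime).
#' @param d_M mRNA degradation rate.
#' @param k_P Translation initiation rate per mRNA molecule.
#' @param alpha_M Gamma shape of transcription initiation intervals.
#' @param tau_P Protein maturation delay: a nonnegative number (0 disables
#'   it) or a [delay_distribution][delay_none] such as `delay_tnorm()`.
#' @param d_P Protein degradation rate (1 by convention).
#' @return An `expression_params` object.
#' @export
expression_params <- function(k_M, d_M, k_P, alpha_M = 1, tau_P = 0,
                              d_P = 1) {
  for (nm in c("k_M", "d_M", "k_P", "alpha_M", "d_P")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive finite number")
  }
  if (inherits(tau_P, "delay_distribution")) {
    # distributional maturation delay, kept as-is
  } else if (!is.numeric(tau_P) || length(tau_P) != 1L ||
             !is.finite(tau_P) || tau_P < 0) {
    stop("tau_P must be a nonnegative number or a delay_distribution")
  }
  structure(list(k_M = k_M, d_M = d_M, k_P = k_P, alpha_M = alpha_M,
                 tau_P = tau_P, d_P = d_P),
            class = "expression_params")
}

#' Multimerization parameters
#'
#' @param N Multimer order (`>= 1`; 1 means no multimerization).
#' @param a Association rate for every homomer pair; `Inf` (default, per the
#'   reference parameterization) makes association instantaneous.
#' @param u Dissociation rate for every homomer split (default 0).
#' @return A `multimer_params` object.
#' @export
multimer_params <- function(N, a = Inf, u = 0) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be an integer >= 1")
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("association rate a must be nonnegative (Inf allowed)")
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0)
    stop("dissociation rate u must be a nonnegative finite number")
  structure(list(N = as.integer(N), a = a, u = u),
            class = "multimer_params")
}

#' Species names used by the model builders
#'
#' Gene `i` uses `S<i>` (free transcription start site), `M<i>` (mRNA),
#' `P<i>` (free monomer), `P<i>x<k>` (order-`k` homomer, `k >= 2`),
#' `X<i>` (bookkeeping counter of all gene-`i` protein subunits regardless
#' of form), and `P12` for the heterodimer.
#'
#' @param i Gene index.
#' @param k Homomer order.
#' @return Species name string.
#' @export
multimer_species <- function(i, k) {
  if (k == 1) paste0("P", i) else paste0("P", i, "x", k)
}

# reactions 1-4 for one gene; X<i> counts every living subunit of gene i
monomer_reactions <- function(p, i = 1, track_total = TRUE) {
  S <- paste0("S", i); M <- paste0("M", i)
  P <- paste0("P", i); X <- paste0("X", i)
  tau_S <- transcription_delay(p$alpha_M, p$k_M)
  tau_P <- if (inherits(p$tau_P, "delay_distribution")) p$tau_P
           else if (p$tau_P > 0) delay_fixed(p$tau_P) else NULL
  transl_prod <- if (track_total) stats::setNames(c(1L, 1L, 1L),
                                                  c(M, P, X))
                 else stats::setNames(c(1L, 1L), c(M, P))
  deg_reac <- if (track_total) stats::setNames(c(1L, 1L), c(P, X))
              else stats::setNames(1L, P)
  list(
    reaction(stats::setNames(1L, S), stats::setNames(c(1L, 1L), c(S, M)),
             rate = Inf, delay = tau_S, delayed = c(S, M),
             shared_delay = TRUE, name = paste0("transcription_", i),
             instant_priority = -1L),
    reaction(stats::setNames(1L, M), character(), rate = p$d_M,
             name = paste0("mrna_decay_", i)),
    reaction(stats::setNames(1L, M), transl_prod, rate = p$k_P,
             delay = tau_P,
             delayed = if (is.null(tau_P)) NULL else setdiff(
               names(transl_prod), M),
             name = paste0("translation_", i)),
    reaction(deg_reac, character(), rate = p$d_P,
             propensity = stats::setNames(1L, P),
             name = paste0("protein_decay_", i))
  )
}

# reactions 9-11 for one gene: association/dissociation over all (n, k)
# with 2 <= n <= N, k <= n/2, and the n*d_P degradation chain
homomer_reactions <- function(i, N, a, u, d_P, track_total = TRUE) {
  out <- list()
  X <- paste0("X", i)
  for (n in 2:N) {
    for (k in seq_len(n %/% 2)) {
      lo <- multimer_species(i, k)
      hi <- multimer_species(i, n - k)
      full <- multimer_species(i, n)
      reac <- if (k == n - k) stats::setNames(2L, lo)
              else stats::setNames(c(1L, 1L), c(lo, hi))
      out[[length(out) + 1L]] <- reaction(
        reac, stats::setNames(1L, full), rate = a,
        name = sprintf("assoc_%s+%s", lo, hi), instant_priority = n)
      out[[length(out) + 1L]] <- reaction(
        stats::setNames(1L, full), reac, rate = u,
        name = sprintf("dissoc_%s", full))
    }
    deg_reac <- if (track_total)
      stats::setNames(c(1L, 1L), c(multimer_species(i, n), X))
    else stats::setNames(1L, multimer_species(i, n))
    out[[length(out) + 1L]] <- reaction(
      deg_reac, stats::setNames(1L, multimer_species(i, n - 1)),
      rate = n * d_P, propensity = stats::setNames(1L,
                                                   multimer_species(i, n)),
      name = sprintf("decay_%s", multimer_species(i, n)))
  }
  out
}

#' Build the single-gene (monomer) expression model
#'
#' Delayed transcription (the start site `S` is consumed at initiation and
#' released, together with the transcript `M`, after a shared
#' gamma-distributed interval so the promoter is occupied for the full
#' duration), first-order mRNA decay, translation at rate `k_P * M`, and
#' first-order protein decay.  At stationarity the mean mRNA level is
#' `k_M / d_M` and the mean protein level `k_M * k_P / (d_M * d_P)`.
#'
#' The returned model carries an `initial` attribute (`S = 1`, all else 0)
#' that [simulate_reactions()] picks up automatically, and a bookkeeping
#' species `X<i>` counting all living protein subunits of the gene.
#'
#' @param p [expression_params()].
#' @param gene Gene index used in species names.
#' @return List of [reaction()]s with an `initial` attribute.
#' @export
build_monomer_gene <- function(p, gene = 1) {
  stopifnot(inherits(p, "expression_params"))
  model <- monomer_reactions(p, gene)
  attr(model, "initial") <- stats::setNames(1L, paste0("S", gene))
  model
}

#' Build the homomer (order-N multimer) expression model
#'
#' The monomer gene of [build_monomer_gene()] plus, for every
#' `2 <= n <= N` and `k <= n/2`, the association
#' `P_k + P_(n-k) -> P_n` (rate `a`, instant when `a = Inf`, fired
#' highest-order-first), the reverse dissociation at rate `u`, and the
#' degradation `P_n -> P_(n-1)` at rate `n * d_P` (any one of the `n`
#' subunits degrades).  The counter `X<i>` tracks
#' `sum_k k * P_(i x k)` exactly via production/degradation bookkeeping.
#'
#' @param p [expression_params()].
#' @param m [multimer_params()] with `N >= 2`.
#' @param gene Gene index used in species names.
#' @return List of [reaction()]s with an `initial` attribute.
#' @export
build_homomer_system <- function(p, m, gene = 1) {
  stopifnot(inherits(p, "expression_params"), inherits(m, "multimer_params"))
  if (m$N < 2) stop("homomer system requires multimer order N >= 2")
  model <- c(monomer_reactions(p, gene),
             homomer_reactions(gene, m$N, m$a, m$u, p$d_P))
  attr(model, "initial") <- stats::setNames(1L, paste0("S", gene))
  model
}

#' Build the heterodimer model
#'
#' Two independently transcribed genes (each with its own promoter) whose
#' monomers `P1` and `P2` associate into the heterodimer `P12` at rate
#' `a12` and dissociate at rate `u12`.  Degradation of either subunit while
#' dimerized releases the surviving monomer (`P12 -> P2` at gene 1's `d_P`,
#' `P12 -> P1` at gene 2's).  `X1 = P1 + P12` and `X2 = P2 + P12` are
#' tracked exactly.
#'
#' @param p1,p2 [expression_params()] for the two genes.
#' @param a12 Association rate (`Inf` for instantaneous).
#' @param u12 Dissociation rate.
#' @return List of [reaction()]s with an `initial` attribute.
#' @export
build_heterodimer_system <- function(p1, p2, a12 = Inf, u12 = 0) {
  stopifnot(inherits(p1, "expression_params"),
            inherits(p2, "expression_params"))
  if (!is.numeric(a12) || length(a12) != 1L || is.na(a12) || a12 < 0)
    stop("a12 must be nonnegative (Inf allowed)")
  if (!is.numeric(u12) || length(u12) != 1L || !is.finite(u12) || u12 < 0)
    stop("u12 must be a nonnegative finite number")
  model <- c(
    monomer_reactions(p1, 1), monomer_reactions(p2, 2),
    list(
      reaction(c(P1 = 1, P2 = 1), c(P12 = 1), rate = a12,
               name = "assoc_P1+P2", instant_priority = 2L),
      reaction(c(P12 = 1), c(P1 = 1, P2 = 1), rate = u12,
               name = "dissoc_P12"),
      reaction(c(P12 = 1, X1 = 1), c(P2 = 1), rate = p1$d_P,
               propensity = c(P12 = 1), name = "decay_P12_subunit1"),
      reaction(c(P12 = 1, X2 = 1), c(P1 = 1), rate = p2$d_P,
               propensity = c(P12 = 1), name = "decay_P12_subunit2")
    ))
  attr(model, "initial") <- c(S1 = 1L, S2 = 1L)
  model
}

#' Toggle switch parameters
#'
#' Two mutually repressing genes whose order-`N` homomers act as
#' repressors.  The reference parameterization (in protein-lifetime units):
#' `d_M = 6 * d_P`, expected transcript number
#' `k_M / (N * d_M) = mean_transcripts = 5`, `alpha_M = 1`, expected
#' proteins per transcript `k_P / d_P = proteins_per_transcript = 5`, and
#' repression dissociation constant
#' `K = C * (k_M / (N * d_M)) * (k_P / d_P)`, with `C` the inverse
#' repression strength.  `k_M` is scaled by `N` so the mean number of
#' regulatory multimers is comparable across orders.
#'
#' @param C Inverse repression strength, `> 0`.
#' @param N Repressor homomer order (`>= 1`).
#' @param d_P Protein degradation rate.
#' @param d_M mRNA degradation rate.
#' @param mean_transcripts Target mean transcript number `k_M / (N * d_M)`.
#' @param proteins_per_transcript Target `k_P / d_P`.
#' @param alpha_M Transcription interval shape; must be 1 (see
#'   [build_toggle_switch()]).
#' @param a,u Multimer association/dissociation rates.
#' @return A `toggle_params` object with derived `k_M_max` and `K`.
#' @export
toggle_params <- function(C, N = 2, d_P = 1, d_M = 6 * d_P,
                          mean_transcripts = 5, proteins_per_transcript = 5,
                          alpha_M = 1, a = Inf, u = 0) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("C must be a single positive number")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be an integer >= 1")
  k_M_max <- mean_transcripts * N * d_M
  k_P <- proteins_per_transcript * d_P
  K <- C * mean_transcripts * proteins_per_transcript
  structure(list(C = C, N = as.integer(N), K = K, k_M_max = k_M_max,
                 expr = expression_params(k_M = k_M_max, d_M = d_M,
                                          k_P = k_P, alpha_M = alpha_M,
                                          d_P = d_P),
                 multimer = multimer_params(N, a = a, u = u)),
            class = "toggle_params")
}

#' Build the multimer-regulated toggle switch
#'
#' Two genes, each repressed by the order-`N` homomer of the other: the
#' effective transcription rate of gene `j` is
#' `k_M_max / (1 + P_(i x N) / K)`, re-evaluated from the current repressor
#' count after every event.  This state-dependent (Markovian) treatment of
#' transcription requires exponential initiation intervals: for
#' `alpha_M = 1` the delayed renewal formulation and the propensity
#' formulation coincide in law, whereas for `alpha_M != 1` a time-varying
#' rate is not well defined event-wise, so such parameters are rejected.
#'
#' @param t [toggle_params()].
#' @return List of [reaction()]s (initial state all zero).
#' @export
build_toggle_switch <- function(t) {
  stopifnot(inherits(t, "toggle_params"))
  if (t$expr$alpha_M != 1)
    stop("the toggle switch requires alpha_M = 1: a state-dependent ",
         "transcription rate is only well defined for memoryless ",
         "(exponential) initiation")
  model <- list()
  for (j in 1:2) {
    i <- 3L - j
    M <- paste0("M", j); P <- paste0("P", j)
    rep_sp <- multimer_species(i, t$N)
    model <- c(model, list(
      reaction(character(), stats::setNames(1L, M),
               rate = rate_repression(t$k_M_max, t$K, rep_sp),
               name = paste0("transcription_", j)),
      reaction(stats::setNames(1L, M), character(), rate = t$expr$d_M,
               name = paste0("mrna_decay_", j)),
      reaction(stats::setNames(1L, M), stats::setNames(c(1L, 1L), c(M, P)),
               rate = t$expr$k_P, name = paste0("translation_", j)),
      reaction(stats::setNames(1L, P), character(), rate = t$expr$d_P,
               name = paste0("protein_decay_", j))
    ))
    if (t$N >= 2)
      model <- c(model, homomer_reactions(j, t$N, t$multimer$a,
                                          t$multimer$u, t$expr$d_P,
                                          track_total = FALSE))
  }
  model  # all species start at zero

}

#' Evaluate reaction propensities at a given state
#'
#' Returns the propensity of every reaction at the state `counts`
#' (mass-action with combinatorial factors, repression laws evaluated at the
#' repressor count, user rate functions called on the state).  Instant
#' reactions report `Inf` when applicable and 0 otherwise.
#'
#' @param model List of [reaction()]s.
#' @param counts Named integer state vector.
#' @return Named numeric vector of propensities.
#' @export
propensities <- function(model, counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  getc <- function(s) if (s %in% names(counts)) counts[[s]] else 0
  vapply(model, function(rx) {
    if (is_instant(rx)) {
      ok <- all(vapply(names(rx$reactants),
                       function(s) getc(s) >= rx$reactants[[s]],
                       logical(1)))
      return(if (ok) Inf else 0)
    }
    if (inherits(rx$rate, "rate_repression"))
      return(rx$rate$k_max / (1 + getc(rx$rate$repressor) / rx$rate$K))
    if (is.function(rx$rate)) {
      a <- rx$rate(counts)
      if (!is.finite(a) || a < 0)
        stop("non-finite or negative propensity in reaction '", rx$name,
             "'")
      return(a)
    }
    stoich <- if (!is.null(rx$propensity)) rx$propensity else rx$reactants
    a <- rx$rate
    for (s in names(stoich)) {
      x <- getc(s); v <- stoich[[s]]
      if (x < v) return(0)
      a <- a * prod((x - seq_len(v) + 1) / seq_len(v))
    }
    a
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(model, function(r) r$name, character(1)))
}
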