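#' Delay distributions for delayed product release
#'
#' Reaction products can be released a random time after the reaction fires.
#' `delay_none()` releases immediately, `delay_fixed()` after a deterministic
#' lag, `delay_gamma()` after a gamma-distributed lag, and `delay_tnorm()`
#' after a normal lag truncated at zero.  `transcription_delay()` is the
#' parameterization used for transcription initiation: a gamma with shape
#' `alpha_M` and scale `1 / (alpha_M * k_M)`, so the mean interval between
#' transcripts is `1 / k_M` and the coefficient of variation (sd / mean) is
#' `alpha_M^(-1/2)`.  Integer `alpha_M` corresponds to a sequence of
#' `alpha_M` exponential initiation steps.
#'
#' @param tau Fixed delay (time units), `>= 0`.
#' @param shape,scale Gamma shape and scale, both `> 0`.
#' @param mean,sd Location and spread of the truncated normal, `sd > 0`.
#' @param alpha_M Gamma shape of the initiation-interval distribution.
#' @param k_M Mean transcription rate (1 / mean interval).
#' @return An object of class `delay_distribution`.
#' @examples
#' d <- transcription_delay(alpha_M = 4, k_M = 2)
#' mean(draw_delay(d, 1000))  # ~ 0.5
#' @export
delay_none <- function() {
  structure(list(family = "degenerate", p1 = 0, p2 = 0),
            class = "delay_distribution")
}

#' @rdname delay_none
#' @export
delay_fixed <- function(tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau >= 0)
  structure(list(family = "degenerate", p1 = tau, p2 = 0),
            class = "delay_distribution")
}

#' @rdname delay_none
#' @export
delay_gamma <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0)
    stop("gamma delay requires shape > 0")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("gamma delay requires scale > 0")
  structure(list(family = "gamma", p1 = shape, p2 = scale),
            class = "delay_distribution")
}

#' @rdname delay_none
#' @export
delay_tnorm <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L, is.finite(mean), is.finite(sd), sd > 0)
  structure(list(family = "tnorm", p1 = mean, p2 = sd),
            class = "delay_distribution")
}

#' @rdname delay_none
#' @export
transcription_delay <- function(alpha_M, k_M) {
  if (!is.numeric(alpha_M) || length(alpha_M) != 1L || !is.finite(alpha_M) ||
      alpha_M <= 0)
    stop("alpha_M must be a positive number")
  if (!is.numeric(k_M) || length(k_M) != 1L || !is.finite(k_M) || k_M <= 0)
    stop("k_M must be a positive number")
  delay_gamma(shape = alpha_M, scale = 1 / (alpha_M * k_M))
}

#' Sample release delays
#'
#' @param d A [delay_distribution][delay_none] object.
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative delays.
#' @export
draw_delay <- function(d, n = 1L) {
  stopifnot(inherits(d, "delay_distribution"))
  switch(d$family,
    degenerate = rep(d$p1, n),
    gamma = rgamma(n, shape = d$p1, scale = d$p2),
    tnorm = {
      x <- rnorm(n, d$p1, d$p2)
      while (any(neg <- x < 0)) x[neg] <- rnorm(sum(neg), d$p1, d$p2)
      x
    },
    stop("unknown delay family: ", d$family)
  )
}

#' @export
print.delay_distribution <- function(x, ...) {
  cat(switch(x$family,
    degenerate = if (x$p1 == 0) "<no delay>" else
      sprintf("<fixed delay %g>", x$p1),
    gamma = sprintf("<gamma delay: shape %g, scale %g>", x$p1, x$p2),
    tnorm = sprintf("<truncated-normal delay: mean %g, sd %g>", x$p1, x$p2)
  ), "\n")
  invisible(x)
}

#' Repression rate law
#'
#' Transcription propensity of a gene repressed by a multimer:
#' `k_max / (1 + P / K)`, where `P` is the current copy number of the
#' repressor species and `K` the dissociation constant of repressor-promoter
#' binding.  Re-evaluated after every simulation event.
#'
#' @param k_max Maximal (unrepressed) transcription rate.
#' @param K Dissociation constant, `> 0`.
#' @param repressor Name of the repressor species.
#' @return A rate-law object usable as the `rate` of [reaction()].
#' @export
rate_repression <- function(k_max, K, repressor) {
  stopifnot(is.numeric(k_max), k_max > 0, is.finite(k_max),
            is.numeric(K), K > 0, is.finite(K),
            is.character(repressor), length(repressor) == 1L)
  structure(list(k_max = k_max, K = K, repressor = repressor),
            class = "rate_repression")
}

#' Define a stochastic reaction
#'
#' One reaction of a delayed-SSA model: integer stoichiometries for reactants
#' and products, a rate law, and an optional release delay applied to a
#' subset of the products.  The rate may be a nonnegative mass-action rate
#' constant (propensity `k * prod_s choose(x_s, nu_s)`), `Inf` for an
#' *instant* reaction fired deterministically the moment its reactants are
#' available, a [rate_repression()] law, or an arbitrary R function of the
#' named state vector returning the full propensity.
#'
#' @param reactants,products Named integer vectors of stoichiometric counts
#'   (either may be empty, not both).
#' @param rate Rate law (see Details).
#' @param name Reaction label used in error messages and event logs.
#' @param delay A [delay_distribution][delay_none]; `NULL` means all products
#'   are released immediately.
#' @param delayed Character vector naming which products the delay applies
#'   to; defaults to all products.
#' @param shared_delay If `TRUE` (default) one delay is drawn per firing and
#'   shared by all delayed products (e.g. a transcript and the promoter it
#'   frees); if `FALSE` each delayed product molecule gets an independent
#'   draw.
#' @param propensity Optional named integer vector overriding the reactant
#'   stoichiometry in the mass-action propensity; used for bookkeeping
#'   reactants (such as total-subunit counters) that must be consumed without
#'   entering the rate law.
#' @param instant_priority Integer priority among simultaneously applicable
#'   instant reactions (higher fires first); ties broken by lexical order of
#'   the first product species.
#' @return An object of class `reaction_spec`.
#' @examples
#' # birth-death pair: constitutive production, first-order decay
#' list(
#'   reaction(character(), c(M = 1), rate = 10, name = "birth"),
#'   reaction(c(M = 1), character(), rate = 1, name = "death")
#' )
#' @export
reaction <- function(reactants = character(), products = character(),
                     rate, name = NULL, delay = NULL, delayed = NULL,
                     shared_delay = TRUE, propensity = NULL,
                     instant_priority = 0L) {
  reactants <- check_stoich(reactants, "reactants")
  products <- check_stoich(products, "products")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("a reaction needs at least one reactant or product")
  if (inherits(rate, "rate_repression") || is.function(rate)) {
    # state-dependent rate law, validated at simulation time
  } else {
    if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
      stop("rate must be a single nonnegative number, Inf, a function, ",
           "or a rate_repression() law")
  }
  if (!is.null(delay)) stopifnot(inherits(delay, "delay_distribution"))
  if (is.null(delayed)) {
    delayed <- if (is.null(delay)) character() else names(products)
  } else {
    if (!all(delayed %in% names(products)))
      stop("'delayed' names species that are not products")
    if (is.null(delay)) stop("'delayed' given without a 'delay'")
  }
  if (!is.null(propensity)) propensity <- check_stoich(propensity,
                                                       "propensity")
  if (is.null(name))
    name <- paste0(fmt_side(reactants), " -> ", fmt_side(products))
  structure(
    list(reactants = reactants, products = products, rate = rate,
         name = name, delay = delay, delayed = delayed,
         shared_delay = isTRUE(shared_delay), propensity = propensity,
         instant_priority = as.integer(instant_priority)),
    class = "reaction_spec")
}

check_stoich <- function(x, what) {
  if (length(x) == 0L) return(stats::setNames(integer(), character()))
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " must be a named vector of species counts")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x)))
    stop(what, " stoichiometries must be nonnegative integers")
  v <- tapply(as.integer(x), names(x), sum)  # merge duplicate species
  stats::setNames(as.integer(v), names(v))
}

fmt_side <- function(stoich) {
  if (length(stoich) == 0L) return("0")
  paste(ifelse(stoich > 1L, paste0(stoich, " ", names(stoich)),
               names(stoich)), collapse = " + ")
}

is_instant <- function(rx) is.numeric(rx$rate) && is.infinite(rx$rate)

#' @export
print.reaction_spec <- function(x, ...) {
  rate_lab <- if (inherits(x$rate, "rate_repression")) {
    sprintf("%g/(1 + %s/%g)", x$rate$k_max, x$rate$repressor, x$rate$K)
  } else if (is.function(x$rate)) "<function>" else format(x$rate)
  cat(sprintf("%s  [rate %s]", x$name, rate_lab))
  if (!is.null(x$delay) && !(x$delay$family == "degenerate" &&
                             x$delay$p1 == 0))
    cat(sprintf("  delay on {%s}", paste(x$delayed, collapse = ", ")))
  cat("\n")
  invisible(x)
}

# Priority order of instant reactions: higher instant_priority first, ties
# by lexical order of the first product species, then definition order.
instant_ordering <- function(model) {
  idx <- which(vapply(model, is_instant, logical(1)))
  if (length(idx) == 0L) return(integer())
  prio <- vapply(model[idx], function(r) r$instant_priority, integer(1))
  first_prod <- vapply(model[idx], function(r) {
    if (length(r$products)) sort(names(r$products))[1] else ""
  }, character(1))
  idx[order(-prio, first_prod, seq_along(idx))]
}

#' Resolve instant reactions to their fixpoint
#'
#' Repeatedly fires every applicable `Inf`-rate reaction, in priority order
#' (higher `instant_priority` first, ties by lexical order of the first
#' product), until none applies.  Delayed products of instant reactions are
#' returned on a waitlist rather than added to the state.
#'
#' @param model List of [reaction()] objects (non-instant entries ignored).
#' @param counts Named nonnegative integer vector of species counts.
#' @param max_firings Safety bound; exceeding it signals a cyclic cascade.
#' @return The updated counts vector.  Any delayed instant products are
#'   attached as a `waitlist` attribute (data frame of delay, species,
#'   count).
#' @examples
#' dimerize <- reaction(c(P = 2), c(D = 1), rate = Inf)
#' resolve_instants(list(dimerize), c(P = 5, D = 0))  # P = 1, D = 2
#' @export
resolve_instants <- function(model, counts, max_firings = 1e6) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  ord <- instant_ordering(model)
  wl <- list()
  fired <- 0L
  repeat {
    progressed <- FALSE
    for (j in ord) {
      rx <- model[[j]]
      need <- rx$reactants
      missing <- setdiff(names(need), names(counts))
      if (length(missing))
        counts[missing] <- 0L
      if (all(counts[names(need)] >= need)) {
        counts[names(need)] <- counts[names(need)] - need
        imm <- setdiff(names(rx$products), rx$delayed)
        for (s in imm) counts[s] <- sum(counts[s], 0L, na.rm = TRUE) +
            rx$products[[s]]
        for (s in rx$delayed)
          wl[[length(wl) + 1L]] <- data.frame(
            delay = draw_delay(rx$delay), species = s,
            count = rx$products[[s]])
        fired <- fired + 1L
        if (fired > max_firings)
          stop("instant reaction cascade did not terminate (cycle?)")
        progressed <- TRUE
        break
      }
    }
    if (!progressed) break
  }
  if (length(wl)) attr(counts, "waitlist") <- do.call(rbind, wl)
  counts
}
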