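#' Read and write reaction models as YAML
#'
#' A small declarative schema for delayed-SSA models, so models can be
#' shared and run from the command line.  The document is a map with an
#' optional `initial` map (species: count) and a `reactions` list; each
#' reaction has `reactants` and `products` maps, a `rate` (number,
#' `.inf`/"instant", or a map `{type: repression, k_max, K, repressor}`),
#' and optionally `delay` (`{family: degenerate|gamma|tnorm, ...}` with
#' family-specific parameters), `delayed` (product subset), `shared_delay`,
#' `propensity`, `name`, `instant_priority`.  Arbitrary R-function rates
#' are not representable in YAML.
#'
#' @param path YAML file path.
#' @param model List of [reaction()]s.
#' @param initial Optional named initial counts written alongside.
#' @return `read_model_yaml`: list of reactions with an `initial`
#'   attribute; `write_model_yaml`: `path`, invisibly.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$reactions)) stop("YAML model needs a 'reactions' list")
  to_stoich <- function(x) {
    if (is.null(x) || length(x) == 0L)
      return(stats::setNames(integer(), character()))
    stats::setNames(as.integer(unlist(x)), names(x))
  }
  model <- lapply(doc$reactions, function(rx) {
    rate <- rx$rate
    if (is.character(rate) && tolower(rate) %in% c("instant", "inf")) {
      rate <- Inf
    } else if (is.list(rate)) {
      if (!identical(rate$type, "repression"))
        stop("unknown rate type: ", rate$type)
      rate <- rate_repression(rate$k_max, rate$K, rate$repressor)
    }
    delay <- NULL
    if (!is.null(rx$delay)) {
      d <- rx$delay
      delay <- switch(d$family,
        degenerate = if (is.null(d$tau) || d$tau == 0) delay_none()
                     else delay_fixed(d$tau),
        gamma = delay_gamma(d$shape, d$scale),
        tnorm = delay_tnorm(d$mean, d$sd),
        stop("unknown delay family: ", d$family))
    }
    reaction(to_stoich(rx$reactants), to_stoich(rx$products), rate = rate,
             name = rx$name, delay = delay,
             delayed = if (!is.null(rx$delayed)) unlist(rx$delayed),
             shared_delay = !isFALSE(rx$shared_delay),
             propensity = if (!is.null(rx$propensity))
               to_stoich(rx$propensity),
             instant_priority = if (!is.null(rx$instant_priority))
               rx$instant_priority else 0L)
  })
  if (!is.null(doc$initial))
    attr(model, "initial") <- stats::setNames(
      as.integer(unlist(doc$initial)), names(doc$initial))
  model
}

#' @rdname read_model_yaml
#' @export
write_model_yaml <- function(model, path, initial = NULL) {
  if (is.null(initial)) initial <- attr(model, "initial")
  ser_rate <- function(rate) {
    if (inherits(rate, "rate_repression"))
      return(list(type = "repression", k_max = rate$k_max, K = rate$K,
                  repressor = rate$repressor))
    if (is.function(rate))
      stop("R-function rates cannot be written to YAML")
    if (is.infinite(rate)) "instant" else rate
  }
  ser_delay <- function(d) {
    if (is.null(d)) return(NULL)
    switch(d$family,
           degenerate = list(family = "degenerate", tau = d$p1),
           gamma = list(family = "gamma", shape = d$p1, scale = d$p2),
           tnorm = list(family = "tnorm", mean = d$p1, sd = d$p2))
  }
  doc <- list(
    initial = if (!is.null(initial)) as.list(initial),
    reactions = lapply(model, function(rx) {
      out <- list(name = rx$name,
                  reactants = as.list(rx$reactants),
                  products = as.list(rx$products),
                  rate = ser_rate(rx$rate))
      if (!is.null(rx$delay)) {
        out$delay <- ser_delay(rx$delay)
        out$delayed <- as.list(rx$delayed)
        out$shared_delay <- rx$shared_delay
      }
      if (!is.null(rx$propensity)) out$propensity <- as.list(rx$propensity)
      if (rx$instant_priority != 0L)
        out$instant_priority <- rx$instant_priority
      out
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
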