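#' Simulate a delayed stochastic reaction model
#'
#' Statistically exact event-driven simulation of a list of [reaction()]s
#' under the delayed SSA: the next event is either the firing of a reaction,
#' chosen by the direct method from the current propensities, or the release
#' of a delayed product from a time-ordered waitlist, whichever comes first.
#' Propensities are re-evaluated after every event, so state-dependent rate
#' laws are handled exactly.  Instant (`Inf`-rate) reactions are fired as a
#' deterministic fixpoint after every state change (see
#' [resolve_instants()]).
#'
#' The state is sampled on the grid `0, dt, 2*dt, ..., t_end`; the sample at
#' a grid time is the state just before any event at exactly that time.
#' Time is measured in units of the protein lifetime (protein degradation
#' rate = 1 by convention), and the transient is included: sampling starts
#' at time zero.
#'
#' @param model List of [reaction()] objects.
#' @param initial Named integer vector of initial copy numbers; species that
#'   appear in the model but not here start at 0.  Defaults to the model's
#'   `initial` attribute (set by the gene-model builders) when present.
#' @param t_end Simulation end time, `> 0`.
#' @param sample_interval Sampling grid spacing `dt`, `> 0`.
#' @param seed Integer seed; if non-`NULL` the global RNG state is set (and
#'   restored afterwards) so that identical `(model, initial, seed)` give
#'   bit-identical trajectories.
#' @param record_events If `TRUE`, also return the firing time and reaction
#'   index of every event (memory-heavy for long runs).
#' @param step_limit Abort if more than this many events fire.
#' @return A `trajectory` object: list with `time` (sampling grid), `counts`
#'   (integer matrix, samples x species), `firings` (events per reaction),
#'   `pending` (delayed products still on the waitlist at `t_end`), `seed`,
#'   and optionally `events`.
#' @examples
#' bd <- list(
#'   reaction(character(), c(M = 1), rate = 10, name = "birth"),
#'   reaction(c(M = 1), character(), rate = 1, name = "death")
#' )
#' tr <- simulate_reactions(bd, c(M = 0), t_end = 100, seed = 1)
#' mean(species_series(tr, "M"))  # ~ 10
#' @export
simulate_reactions <- function(model, initial = NULL, t_end,
                               sample_interval = 1, seed = NULL,
                               record_events = FALSE, step_limit = 2e9) {
  stopifnot(is.list(model), all(vapply(model, inherits, logical(1),
                                       "reaction_spec")))
  if (is.null(initial)) initial <- attr(model, "initial")
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0)
    stop("t_end must be a positive number")
  if (!is.numeric(sample_interval) || sample_interval <= 0)
    stop("sample_interval must be positive")

  species <- model_species(model, initial)
  nspec <- length(species)
  nrxn <- length(model)
  if (nrxn == 0L && nspec == 0L) stop("empty model with no species")

  init <- stats::setNames(integer(nspec), species)
  if (!is.null(initial)) {
    if (is.null(names(initial)) || any(names(initial) == ""))
      stop("initial counts must be named")
    if (any(initial < 0) || any(initial != round(initial)))
      stop("initial counts must be nonnegative integers")
    init[names(initial)] <- as.integer(initial)
  }

  reac <- prod_ <- prop <- dela <- matrix(0L, nspec, nrxn,
                                          dimnames = list(species, NULL))
  rate_type <- integer(nrxn)
  rate_const <- numeric(nrxn)
  rep_K <- rep(1, nrxn)
  rep_spec <- integer(nrxn)
  rate_funs <- vector("list", nrxn)
  delay_family <- integer(nrxn)
  delay_p1 <- delay_p2 <- numeric(nrxn)
  delay_shared <- logical(nrxn)
  fam_code <- c(degenerate = 1L, gamma = 2L, tnorm = 3L)

  for (j in seq_len(nrxn)) {
    rx <- model[[j]]
    reac[names(rx$reactants), j] <- rx$reactants
    prod_[names(rx$products), j] <- rx$products
    prop[, j] <- reac[, j]
    if (!is.null(rx$propensity)) {
      prop[, j] <- 0L
      prop[names(rx$propensity), j] <- rx$propensity
    }
    if (inherits(rx$rate, "rate_repression")) {
      rate_type[j] <- 2L
      rate_const[j] <- rx$rate$k_max
      rep_K[j] <- rx$rate$K
      if (!rx$rate$repressor %in% species)
        stop("repressor species '", rx$rate$repressor,
             "' not in the model (reaction '", rx$name, "')")
      rep_spec[j] <- match(rx$rate$repressor, species) - 1L
    } else if (is.function(rx$rate)) {
      rate_type[j] <- 3L
      rate_funs[[j]] <- rx$rate
    } else if (is_instant(rx)) {
      rate_type[j] <- 1L
    } else {
      rate_type[j] <- 0L
      rate_const[j] <- rx$rate
    }
    if (!is.null(rx$delay) && length(rx$delayed)) {
      dela[rx$delayed, j] <- prod_[rx$delayed, j]
      delay_family[j] <- fam_code[[rx$delay$family]]
      delay_p1[j] <- rx$delay$p1
      delay_p2[j] <- rx$delay$p2
      delay_shared[j] <- rx$shared_delay
    }
  }

  names_ <- vapply(model, function(r) r$name, character(1))
  inst <- instant_ordering(model) - 1L

  run <- function() sim_engine(
    reac, prod_, prop, dela, rate_type, rate_const, rep_K, rep_spec,
    rate_funs, delay_family, delay_p1, delay_p2, delay_shared,
    as.integer(inst), names_, species, init, t_end, sample_interval,
    record_events, step_limit)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  res <- run()

  grid <- seq(0, by = sample_interval,
              length.out = nrow(res$counts))
  counts <- res$counts
  colnames(counts) <- species
  out <- list(time = grid, counts = counts,
              firings = stats::setNames(res$firings, names_),
              pending = stats::setNames(res$pending, species),
              n_events = res$n_events, seed = seed,
              sample_interval = sample_interval)
  if (record_events)
    out$events <- data.frame(time = res$event_times,
                             reaction = names_[res$event_reaction])
  structure(out, class = "trajectory")
}

# species in order of first appearance: initial counts first, then reactions
model_species <- function(model, initial = NULL) {
  nm <- character()
  if (!is.null(initial)) nm <- names(initial)
  for (rx in model) {
    nm <- c(nm, names(rx$reactants), names(rx$products))
    if (inherits(rx$rate, "rate_repression")) nm <- c(nm, rx$rate$repressor)
  }
  unique(nm)
}

#' Extract one species' count series from a trajectory
#'
#' @param traj A `trajectory` from [simulate_reactions()].
#' @param species Species name.
#' @return Integer vector aligned with `traj$time`.
#' @export
species_series <- function(traj, species) {
  stopifnot(inherits(traj, "trajectory"))
  if (!species %in% colnames(traj$counts))
    stop("species '", species, "' not in trajectory")
  traj$counts[, species]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples x %d species, t in [0, %g], %g events>\n",
              nrow(x$counts), ncol(x$counts), max(x$time), x$n_events))
  cat("species:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$time, times = ncol(x$counts)),
    species = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts))
}

#' Write a trajectory to disk
#'
#' Writes tidy `(time, species, count)` rows as CSV (or columnar Parquet if
#' the arrow package is installed), plus a JSON metadata sidecar
#' (`<path>.meta.json`) recording the seed, sampling interval, species, and
#' a content hash of the model if supplied.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @param format `"csv"` or `"parquet"`.
#' @param model Optional model list; hashed into the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "parquet"),
                             model = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  format <- match.arg(format)
  df <- as.data.frame(traj)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("parquet output requires the 'arrow' package")
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  meta <- list(
    seed = traj$seed, sample_interval = traj$sample_interval,
    t_end = max(traj$time), n_samples = nrow(traj$counts),
    species = colnames(traj$counts), n_events = traj$n_events,
    model_hash = if (!is.null(model)) model_hash(model) else NULL)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

# 32-bit FNV-1a over the serialized model; provenance only, not cryptographic
model_hash <- function(model) {
  bytes <- as.integer(serialize(model, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), b)
    h_lo <- h %% 65536
    h_hi <- h %/% 65536
    h <- (h_lo * 16777619 +
            ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
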