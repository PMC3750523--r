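#' Configuration for parameter sweeps
#'
#' The reference protocol varies `d_M`, `k_M`, `k_P` logarithmically in
#' `[0.1, 10]` and `alpha_M` in `{1, 2, 3, 5, 10}`, running each point for
#' 1e5 time units sampled every time unit.  The default here is a
#' scaled-down version — one point per decade and 1e4 time units — which
#' preserves every qualitative ordering while keeping a full sweep in
#' minutes; pass denser grids and the full length for the reference-scale
#' computation.
#'
#' @param k_M,d_M,k_P Rate grids (per protein lifetime).
#' @param alpha_M Transcription-interval shape grid.
#' @param t_end Simulation length per point (time units).
#' @param sample_interval Sampling grid spacing.
#' @param replicates Independent runs per grid point (default 1: one long
#'   run per point, as in the reference protocol).
#' @param seed Base seed; each row's seed is derived deterministically from
#'   it and recorded, so any row is reproducible in isolation.
#' @param batches Batch count for batch-means Monte Carlo standard errors.
#' @param check_conservation If `TRUE`, verify the exact subunit-count
#'   identities (`X1 = sum_k k * P1xk`, `Y1 = X1 - P1x2`) at every sample
#'   of every run and record the result per row.
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(k_M = c(0.1, 1, 10), d_M = c(0.1, 1, 10),
                         k_P = c(0.1, 1, 10), alpha_M = 1, t_end = 1e4,
                         sample_interval = 1, replicates = 1L, seed = 1L,
                         batches = 20L, check_conservation = TRUE) {
  stopifnot(length(k_M) > 0, length(d_M) > 0, length(k_P) > 0,
            length(alpha_M) > 0, t_end > 0, sample_interval > 0,
            replicates >= 1)
  structure(list(k_M = k_M, d_M = d_M, k_P = k_P, alpha_M = alpha_M,
                 t_end = t_end, sample_interval = sample_interval,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), batches = as.integer(batches),
                 check_conservation = isTRUE(check_conservation)),
            class = "sweep_config")
}

sweep_grid <- function(cfg) {
  g <- expand.grid(k_M = cfg$k_M, d_M = cfg$d_M, k_P = cfg$k_P,
                   alpha_M = cfg$alpha_M,
                   replicate = seq_len(cfg$replicates),
                   KEEP.OUT.ATTRS = FALSE)
  g$seed <- row_seed(cfg$seed, seq_len(nrow(g)))
  g
}

# deterministic per-row seed stream, kept within 32-bit integer range
row_seed <- function(base, row) {
  as.integer((as.numeric(base) * 7919 + 104729 * as.numeric(row)) %%
               2147483647)
}

# run one model and return pooled + batch statistics for chosen species
run_point <- function(model, cfg, seed, species) {
  tr <- simulate_reactions(model, t_end = cfg$t_end,
                           sample_interval = cfg$sample_interval,
                           seed = seed)
  stats <- lapply(species, function(s)
    series_stats(species_series(tr, s), batches = cfg$batches))
  names(stats) <- species
  list(traj = tr, stats = stats)
}

# exact integer identity X_i = sum_k k * P_(i x k) over all sampled times
conservation_ok <- function(tr, gene = 1, N = 2, hetero = FALSE) {
  X <- species_series(tr, paste0("X", gene))
  if (hetero) {
    total <- species_series(tr, paste0("P", gene)) +
      species_series(tr, "P12")
  } else {
    total <- species_series(tr, paste0("P", gene))
    if (N >= 2)
      for (k in 2:N)
        total <- total + k * species_series(tr, multimer_species(gene, k))
  }
  all(X == total)
}

gain_cols <- function(prefix, tstat, nstat, statistic) {
  if (statistic == "mean") {
    g <- gain(tstat$mean, nstat$mean, tstat$se_mean, nstat$se_mean, "mean")
  } else {
    if (!is.finite(tstat$eta) || !is.finite(nstat$eta) || nstat$eta <= 0)
      return(stats::setNames(list(NA_real_, NA_real_),
                             paste0(prefix, c("", "_se"))))
    g <- gain(tstat$eta, nstat$eta, tstat$se_eta, nstat$se_eta, "eta")
  }
  stats::setNames(list(g$gain, g$se), paste0(prefix, c("", "_se")))
}

#' Homodimer sweep: gains of the dimer and of all functional forms
#'
#' For every grid point, simulates the monomer gene (null model) and the
#' homodimer system (tested model) with a shared per-row seed, and reports
#' mean and noise (`eta`) gains of the dimer `P1x2` and of the total
#' functional count `Y1 = P1 + P1x2` relative to the monomer `X1`.
#' Reproduces the computation behind the homodimer mean-gain and
#' noise-gain figures of the reference analysis.
#'
#' @param cfg A [sweep_config()].
#' @return A tibble, one row per grid point, with the statistics, gains,
#'   batch-means standard errors, the conservation-check flag, and the seed
#'   that reproduces the row.
#' @export
run_homodimer_sweep <- function(cfg = sweep_config()) {
  grid <- sweep_grid(cfg)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- c(as.list(g), list(ok = TRUE, error = NA_character_))
    tryCatch({
      p <- expression_params(k_M = g$k_M, d_M = g$d_M, k_P = g$k_P,
                             alpha_M = g$alpha_M)
      null <- run_point(build_monomer_gene(p), cfg, g$seed, "X1")
      m2 <- multimer_params(2)
      test <- run_point(build_homomer_system(p, m2), cfg, g$seed,
                        c("P1x2", "X1"))
      y1 <- species_series(test$traj, "P1") +
        species_series(test$traj, "P1x2")
      y1s <- series_stats(y1, batches = cfg$batches)
      ns <- null$stats$X1
      out <- c(out, list(
        mu_X1_null = ns$mean, eta_X1_null = ns$eta,
        mu_dimer = test$stats$P1x2$mean, eta_dimer = test$stats$P1x2$eta,
        mu_Y1 = y1s$mean, eta_Y1 = y1s$eta,
        mu_X1 = test$stats$X1$mean, eta_X1 = test$stats$X1$eta),
        gain_cols("mean_gain_dimer", test$stats$P1x2, ns, "mean"),
        gain_cols("eta_gain_dimer", test$stats$P1x2, ns, "eta"),
        gain_cols("mean_gain_Y1", y1s, ns, "mean"),
        gain_cols("eta_gain_Y1", y1s, ns, "eta"),
        list(conserved = if (cfg$check_conservation)
          conservation_ok(test$traj, N = 2) &&
            conservation_ok(null$traj, N = 1) else NA))
      out
    }, error = function(e) fail_row(out, e))
  })
  tibble::as_tibble(rbind_fill(rows))
}

fail_row <- function(out, e) {
  out$ok <- FALSE
  out$error <- conditionMessage(e)
  out
}

# minimal rbind with NA fill (rows are named lists)
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  df <- lapply(cols, function(cl) {
    vals <- lapply(rows, function(r) if (cl %in% names(r)) r[[cl]] else NA)
    unlist(vals)
  })
  names(df) <- cols
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Heterodimer sweep: heterodimer vs doubled-rate homodimer
#'
#' For every grid point, simulates (i) the heterodimer model (two genes,
#' each transcribing at `k_M`), (ii) the homodimer null with `k_M` doubled
#' to compensate for the two genes each contributing subunits, and (iii)
#' the single-gene monomer reference at `k_M`, and reports the
#' heterodimer/homodimer mean and noise ratios plus each model's gains
#' against the monomer reference `X1`.  At high expression the doubled-rate
#' homodimer's noise gain approaches one half (the doubled transcription
#' rate halves `eta` while dimerization adds no noise).
#'
#' @param cfg A [sweep_config()].
#' @return A tibble, one row per grid point.
#' @export
run_heterodimer_sweep <- function(cfg = sweep_config()) {
  grid <- sweep_grid(cfg)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- c(as.list(g), list(ok = TRUE, error = NA_character_))
    tryCatch({
      p <- expression_params(k_M = g$k_M, d_M = g$d_M, k_P = g$k_P,
                             alpha_M = g$alpha_M)
      p2 <- expression_params(k_M = 2 * g$k_M, d_M = g$d_M, k_P = g$k_P,
                              alpha_M = g$alpha_M)
      het <- run_point(build_heterodimer_system(p, p), cfg, g$seed,
                       c("P12", "X1"))
      hom <- run_point(build_homomer_system(p2, multimer_params(2)), cfg,
                       g$seed, c("P1x2", "X1"))
      mono <- run_point(build_monomer_gene(p), cfg, g$seed, "X1")
      ns <- mono$stats$X1
      out <- c(out, list(
        mu_X1_null = ns$mean, eta_X1_null = ns$eta,
        mu_hetero = het$stats$P12$mean, eta_hetero = het$stats$P12$eta,
        mu_homo = hom$stats$P1x2$mean, eta_homo = hom$stats$P1x2$eta,
        mu_X1_hetero = het$stats$X1$mean,
        eta_X1_hetero = het$stats$X1$eta),
        gain_cols("mean_gain_hetero", het$stats$P12, ns, "mean"),
        gain_cols("eta_gain_hetero", het$stats$P12, ns, "eta"),
        gain_cols("mean_gain_homo", hom$stats$P1x2, ns, "mean"),
        gain_cols("eta_gain_homo", hom$stats$P1x2, ns, "eta"),
        list(
          mean_ratio_het_hom = if (hom$stats$P1x2$mean > 0)
            het$stats$P12$mean / hom$stats$P1x2$mean else NA_real_,
          eta_ratio_het_hom = if (is.finite(hom$stats$P1x2$eta) &&
                                  is.finite(het$stats$P12$eta) &&
                                  hom$stats$P1x2$eta > 0)
            het$stats$P12$eta / hom$stats$P1x2$eta else NA_real_,
          conserved = if (cfg$check_conservation)
            conservation_ok(het$traj, 1, hetero = TRUE) &&
              conservation_ok(het$traj, 2, hetero = TRUE) &&
              conservation_ok(hom$traj, N = 2) else NA))
      out
    }, error = function(e) fail_row(out, e))
  })
  tibble::as_tibble(rbind_fill(rows))
}

#' Higher-order homomer sweep
#'
#' For every grid point and every order `N` in `orders`, simulates the
#' order-`N` homomer system against the monomer null and reports gains of
#' the multimer `P1xN` and of the total functional count
#' `Y1 = P1 + ... + P1xN`.  With `compensate = TRUE` the tested model's
#' `k_M` is scaled by `N` so the multimer mean matches the monomer mean at
#' high expression (the compensated comparison of the reference analysis).
#'
#' @param cfg A [sweep_config()].
#' @param orders Multimer orders (`>= 2`).
#' @param compensate Scale tested-model `k_M` by `N`?
#' @return A tibble, one row per (grid point, order).
#' @export
run_higher_order_sweep <- function(cfg = sweep_config(),
                                   orders = c(2, 3, 4, 5),
                                   compensate = FALSE) {
  stopifnot(all(orders >= 2))
  grid <- sweep_grid(cfg)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- expression_params(k_M = g$k_M, d_M = g$d_M, k_P = g$k_P,
                           alpha_M = g$alpha_M)
    null <- tryCatch(run_point(build_monomer_gene(p), cfg, g$seed, "X1"),
                     error = function(e) NULL)
    for (N in orders) {
      out <- c(as.list(g), list(N = N, ok = TRUE, error = NA_character_))
      rows[[length(rows) + 1L]] <- tryCatch({
        if (is.null(null)) stop("null model failed at this grid point")
        pt <- if (compensate)
          expression_params(k_M = N * g$k_M, d_M = g$d_M, k_P = g$k_P,
                            alpha_M = g$alpha_M) else p
        test <- run_point(build_homomer_system(pt, multimer_params(N)),
                          cfg, g$seed,
                          c(multimer_species(1, N), "X1"))
        top <- test$stats[[multimer_species(1, N)]]
        y1 <- Reduce(`+`, lapply(seq_len(N), function(k)
          species_series(test$traj, multimer_species(1, k))))
        y1s <- series_stats(y1, batches = cfg$batches)
        ns <- null$stats$X1
        c(out, list(
          mu_X1_null = ns$mean, eta_X1_null = ns$eta,
          mu_multimer = top$mean, eta_multimer = top$eta,
          mu_Y1 = y1s$mean, eta_Y1 = y1s$eta,
          mu_X1 = test$stats$X1$mean, eta_X1 = test$stats$X1$eta),
          gain_cols("mean_gain_multimer", top, ns, "mean"),
          gain_cols("eta_gain_multimer", top, ns, "eta"),
          gain_cols("mean_gain_Y1", y1s, ns, "mean"),
          gain_cols("eta_gain_Y1", y1s, ns, "eta"),
          list(conserved = if (cfg$check_conservation)
            conservation_ok(test$traj, N = N) else NA))
      }, error = function(e) fail_row(out, e))
    }
  }
  tibble::as_tibble(rbind_fill(rows))
}

#' Cross-correlation sweep: regulatory control vs response time
#'
#' For every grid point and order, simulates the homomer system on a fine
#' sampling grid and computes the cross-correlation between the total
#' expressed subunit count `X1` (the quantity transcriptional regulation
#' acts on) and the multimer count `P1xN`, reporting the zero-lag
#' correlation and its half-life.  `N = 1` degenerates to the
#' autocorrelation of `X1` (zero-lag exactly 1).
#'
#' @param cfg A [sweep_config()]; use a fine `sample_interval` (the
#'   reference protocol samples every 0.1 time units).
#' @param orders Multimer orders (`>= 1`).
#' @param max_lag Largest lag for the correlation grid (time units).
#' @return A tibble with `zero_lag` and `half_life` per (grid point, order).
#' @export
run_crosscorr_sweep <- function(cfg = sweep_config(sample_interval = 0.1,
                                                   t_end = 2e3),
                                orders = c(2, 3, 5), max_lag = 10) {
  grid <- sweep_grid(cfg)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- expression_params(k_M = g$k_M, d_M = g$d_M, k_P = g$k_P,
                           alpha_M = g$alpha_M)
    for (N in orders) {
      out <- c(as.list(g), list(N = N, ok = TRUE, error = NA_character_))
      rows[[length(rows) + 1L]] <- tryCatch({
        model <- if (N == 1) build_monomer_gene(p)
                 else build_homomer_system(p, multimer_params(N))
        tr <- simulate_reactions(model, t_end = cfg$t_end,
                                 sample_interval = cfg$sample_interval,
                                 seed = g$seed)
        x <- species_series(tr, "X1")
        y <- if (N == 1) x else species_series(tr, multimer_species(1, N))
        cc <- cross_correlation(x, y, max_lag = max_lag,
                                dt = cfg$sample_interval)
        c(out, list(mu_X1 = mean(x), mu_multimer = mean(y),
                    zero_lag = cc$zero_lag, half_life = cc$half_life))
      }, error = function(e) fail_row(out, e))
    }
  }
  tibble::as_tibble(rbind_fill(rows))
}

#' Toggle switch sweep: mean switching time vs repression strength
#'
#' For every order `N` and inverse repression strength `C`, builds the
#' multimer-regulated toggle switch with the reference parameterization
#' (see [toggle_params()]), simulates `n_samples` state samples at
#' interval `dt`, and measures the mean switching time between the states
#' `P1xN > P2xN` and `P1xN < P2xN`.  Rows where fewer than two switches
#' occur within the run are flagged rather than failing the sweep.
#'
#' @param orders Repressor homomer orders.
#' @param C_grid Inverse repression strengths.  The reference grid is
#'   `{a * 10^b : a in 1..9, b in -4..4}`; the default is a scaled-down
#'   three-point version spanning the same range.
#' @param n_samples Number of state samples per run (reference: 1e6).
#' @param dt Sampling interval (reference: 1/30 time units).
#' @param seed Base seed.
#' @return A tibble with `mean_switching_time` and `n_switches` per
#'   `(N, C)`.
#' @export
run_toggle_sweep <- function(orders = c(1, 2, 3),
                             C_grid = c(1e-3, 1, 1e3),
                             n_samples = 1e5, dt = 1 / 30, seed = 1L) {
  rows <- list()
  idx <- 0L
  for (N in orders) for (C in C_grid) {
    idx <- idx + 1L
    s <- row_seed(seed, idx)
    out <- list(N = N, C = C, seed = s, ok = TRUE, error = NA_character_)
    rows[[length(rows) + 1L]] <- tryCatch({
      tp <- toggle_params(C = C, N = N)
      tr <- simulate_reactions(build_toggle_switch(tp),
                               t_end = n_samples * dt,
                               sample_interval = dt, seed = s)
      sw <- mean_switching_time(
        species_series(tr, multimer_species(1, N)),
        species_series(tr, multimer_species(2, N)), dt)
      c(out, list(mean_switching_time = sw$mean_switching_time,
                  n_switches = sw$n_switches))
    }, error = function(e) fail_row(
      c(out, list(mean_switching_time = NA_real_,
                  n_switches = NA_integer_)), e))
  }
  tibble::as_tibble(rbind_fill(rows))
}

#' Write a sweep result with a provenance manifest
#'
#' Writes the result tibble as CSV plus a JSON manifest (`<stem>.json`)
#' recording the sweep name, package version, timestamp, and any
#' configuration supplied.
#'
#' @param result Tibble from one of the `run_*_sweep()` functions.
#' @param path Output CSV path.
#' @param name Sweep name recorded in the manifest.
#' @param config Optional [sweep_config()] (stored in the manifest).
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(result, path, name = "sweep",
                               config = NULL) {
  utils::write.csv(result, path, row.names = FALSE)
  manifest <- list(
    name = name,
    package = "multinoise",
    version = as.character(utils::packageVersion("multinoise")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = nrow(result),
    config = if (!is.null(config)) unclass(config) else NULL)
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(path),
                                        ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
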