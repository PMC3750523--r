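#' Per-gene protein statistics records
#'
#' Validates a table of per-gene population statistics: mean protein copy
#' number per cell (`mu`), squared coefficient of variation (`eta`),
#' essentiality flag, and the number of homogeneous subunits of the
#' functional form (1 for monomeric proteins).
#'
#' @param gene Character gene identifiers.
#' @param essential Logical essentiality flags.
#' @param subunits Integer homogeneous-subunit counts, `>= 1`.
#' @param mu Positive mean protein copy numbers.
#' @param eta Nonnegative squared CVs.
#' @return A tibble of class `protein_records`.
#' @export
protein_records <- function(gene, essential, subunits, mu, eta) {
  n <- length(gene)
  if (n == 0L) stop("empty record table")
  stopifnot(length(essential) == n, length(subunits) == n,
            length(mu) == n, length(eta) == n)
  if (anyDuplicated(gene)) stop("duplicate gene identifiers")
  if (!is.logical(essential) || anyNA(essential))
    stop("essential must be logical without NAs")
  if (any(subunits < 1) || any(subunits != round(subunits)))
    stop("subunits must be integers >= 1")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(eta)) || any(eta < 0))
    stop("eta must be nonnegative")
  out <- tibble::tibble(gene = as.character(gene),
                        essential = essential,
                        subunits = as.integer(subunits),
                        mu = as.numeric(mu), eta = as.numeric(eta))
  class(out) <- c("protein_records", class(out))
  out
}

#' Summarize protein statistics by essentiality and multimer order
#'
#' Groups genes by (essentiality, homogeneous-subunit count) and reports,
#' per group, the percentage of genes within its essentiality class and
#' the medians of the mean protein number (`med_mu`) and of the noise
#' (`med_eta`).  Subunit counts with no genes in a class appear with
#' `percent = 0` and unavailable (`NA`) medians, mirroring the "n/a" cells
#' of genome-wide multimerization tables.
#'
#' @param records A [protein_records()] table (or data frame with the same
#'   columns).
#' @param subunit_levels Subunit counts to tabulate; defaults to
#'   `1:max(records$subunits)`.
#' @return A tibble with columns `essential`, `subunits`, `n`, `percent`,
#'   `med_mu`, `med_eta`.  Percentages within each essentiality class sum
#'   to 100.
#' @export
summarize_multimers <- function(records, subunit_levels = NULL) {
  if (is.null(records) || nrow(records) == 0L) stop("empty record table")
  stopifnot(all(c("essential", "subunits", "mu", "eta") %in%
                  names(records)))
  if (is.null(subunit_levels))
    subunit_levels <- seq_len(max(records$subunits))
  rows <- list()
  for (ess in c(TRUE, FALSE)) {
    cls <- records[records$essential == ess, ]
    for (k in subunit_levels) {
      grp <- cls[cls$subunits == k, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        essential = ess, subunits = as.integer(k), n = nrow(grp),
        percent = if (nrow(cls)) 100 * nrow(grp) / nrow(cls) else
          NA_real_,
        med_mu = if (nrow(grp)) median(grp$mu) else NA_real_,
        med_eta = if (nrow(grp)) median(grp$eta) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic genome-wide protein-statistics table
#'
#' A reproducible synthetic stand-in for genome-wide measurements of
#' per-gene protein abundance and cell-to-cell variability.  The generative
#' model mirrors the qualitative structure reported for *E. coli*:
#' essential genes are drawn with higher mean levels and a subunit
#' distribution skewed toward multimers; the noise decreases with the mean
#' (low-copy-number noise `~ 1/mu`) down to a noise floor attributed to
#' extrinsic fluctuations.  It is synthetic data for exercising
#' [summarize_multimers()], not a reconstruction of any measured dataset.
#'
#' @param n_genes Number of genes.
#' @param essential_fraction Fraction of essential genes (default 0.12,
#'   the approximate genome-wide proportion).
#' @param subunit_probs List with elements `essential` and `nonessential`:
#'   named probability vectors over subunit counts.
#' @param mu_meanlog Named vector (`essential`, `nonessential`): log-mean
#'   of the lognormal protein abundance model.
#' @param mu_sdlog Log-sd of protein abundance.
#' @param noise_floor Lower bound on `eta` for highly expressed genes.
#' @param noise_scale Low-copy-number coefficient: `eta ~ noise_floor +
#'   noise_scale / mu`, with lognormal scatter.
#' @param seed Integer seed (required: the fixture is reproducible).
#' @return A [protein_records()] tibble.
#' @export
generate_protein_fixture <- function(
    n_genes = 1000, essential_fraction = 0.12,
    subunit_probs = list(
      essential = c("1" = 0.54, "2" = 0.30, "3" = 0.04, "4" = 0.05,
                    "6" = 0.05, "7" = 0.01, "10" = 0.01),
      nonessential = c("1" = 0.73, "2" = 0.18, "3" = 0.012, "4" = 0.046,
                       "5" = 0.002, "6" = 0.018, "10" = 0.012)),
    mu_meanlog = c(essential = log(35), nonessential = log(9)),
    mu_sdlog = 1.1, noise_floor = 0.12, noise_scale = 2, seed = 1L) {
  if (!is.numeric(essential_fraction) || essential_fraction <= 0 ||
      essential_fraction >= 1)
    stop("essential_fraction must be in (0, 1)")
  for (p in subunit_probs)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("subunit probabilities must be nonnegative and sum to 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  essential <- runif(n_genes) < essential_fraction
  draw_sub <- function(p, n)
    as.integer(sample(names(p), n, replace = TRUE, prob = p))
  subunits <- integer(n_genes)
  subunits[essential] <- draw_sub(subunit_probs$essential, sum(essential))
  subunits[!essential] <- draw_sub(subunit_probs$nonessential,
                                   sum(!essential))
  # higher-order multimer genes tend to higher expression
  meanlog <- ifelse(essential, mu_meanlog[["essential"]],
                    mu_meanlog[["nonessential"]]) +
    0.25 * (subunits - 1)
  mu <- rlnorm(n_genes, meanlog = meanlog, sdlog = mu_sdlog)
  eta <- (noise_floor + noise_scale / mu) *
    rlnorm(n_genes, meanlog = 0, sdlog = 0.3)
  protein_records(gene = sprintf("g%04d", seq_len(n_genes)),
                  essential = essential, subunits = subunits,
                  mu = mu, eta = eta)
}

#' Read or write protein records as CSV
#'
#' The on-disk schema is one row per gene with columns
#' `gene, essential, subunits, mean, cv2` (`mean` = mean copy number,
#' `cv2` = squared coefficient of variation).
#'
#' @param path CSV file path.
#' @param records A [protein_records()] table.
#' @return `read_protein_records`: a validated [protein_records()] table;
#'   `write_protein_records`: `path`, invisibly.
#' @export
read_protein_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "essential", "subunits", "mean", "cv2")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  protein_records(df$gene, as.logical(df$essential), df$subunits,
                  df$mean, df$cv2)
}

#' @rdname read_protein_records
#' @export
write_protein_records <- function(records, path) {
  stopifnot(all(c("gene", "essential", "subunits", "mu", "eta") %in%
                  names(records)))
  utils::write.csv(
    data.frame(gene = records$gene, essential = records$essential,
               subunits = records$subunits, mean = records$mu,
               cv2 = records$eta),
    path, row.names = FALSE)
  invisible(path)
}
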