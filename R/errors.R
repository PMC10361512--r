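#' Summaries of prevalence prediction error
#'
#' Two headline summaries of a table of per-site relative errors: the
#' fraction of sites with error at or below a threshold (default 0.1, i.e.
#' predictions within 10%), and the mean log10 error. Sites with exactly
#' zero error count toward the fraction but are excluded from the log mean
#' (their count is reported).
#'
#' @param records a [evaluate_prevalence()] table, or a numeric vector of
#'   relative errors.
#' @param epsilon_threshold inclusive error threshold (default 0.1).
#' @return list with `fraction_le_threshold`, `mean_log10_error`, `n`,
#'   `n_zero_error` (excluded from the log mean) and `epsilon_threshold`.
#' @export
error_summary <- function(records, epsilon_threshold = 0.1) {
  eps <- if (is.data.frame(records)) {
    require_columns(records, "epsilon", "prevalence record table")
    records$epsilon
  } else records
  eps <- eps[is.finite(eps)]
  if (length(eps) == 0L)
    stop_gp("no finite relative errors to summarize", "gammaprev_domain_error")
  pos <- eps > 0
  list(fraction_le_threshold = mean(eps <= epsilon_threshold),
       mean_log10_error = if (any(pos)) mean(log10(eps[pos])) else NA_real_,
       n = length(eps), n_zero_error = sum(!pos),
       epsilon_threshold = epsilon_threshold)
}

#' Rescale error distributions for cross-species comparison
#'
#' z-scores the log10 relative errors within each species, so that error
#' distributions of different species can be overlaid on a common axis
#' (the error-distribution analogue of the frequency data collapse).
#' Zero errors are dropped before taking logs.
#'
#' @param records data frame with columns `epsilon` and optionally
#'   `species_id`, or a numeric vector of errors.
#' @return as [pool_and_rescale()]: a vector of z-scores, or a data frame
#'   `species_id`/`z` when several species are present.
#' @export
rescale_error_distribution <- function(records) {
  if (is.data.frame(records)) {
    require_columns(records, "epsilon", "error table")
    if (!is.null(records$species_id) && length(unique(records$species_id)) > 1L) {
      parts <- split(records$epsilon, records$species_id)
      return(do.call(rbind, lapply(names(parts), function(sp) {
        z <- rescale_error_distribution(parts[[sp]])
        data.frame(species_id = sp, z = as.numeric(z), stringsAsFactors = FALSE)
      })))
    }
    records <- records$epsilon
  }
  eps <- records[is.finite(records) & records > 0]
  if (length(eps) < 2L)
    stop_gp("need at least 2 positive errors per species to rescale",
            "gammaprev_domain_error")
  zscore(log10(eps))
}

#' Bin observed versus predicted prevalence
#'
#' Summarizes the observed-vs-predicted scatter by binning sites into
#' log10-spaced bins of observed prevalence and reporting the median
#' observed and predicted value per bin; sparsely populated bins (fewer
#' than `min_sites` sites) are dropped. Perfect predictions put every bin
#' pair on the identity line.
#'
#' @param records a [evaluate_prevalence()] table (`observed` > 0 rows are
#'   used).
#' @param n_bins number of log10-spaced bins (default 20).
#' @param min_sites minimum sites per reported bin (default 5).
#' @return data frame with `bin_mid`, `median_observed`,
#'   `median_predicted`, `n_sites`.
#' @export
bin_observed_vs_predicted <- function(records, n_bins = 20L, min_sites = 5L) {
  require_columns(records, c("observed", "predicted"), "prevalence record table")
  rec <- records[records$observed > 0, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_gp("no sites with positive observed prevalence", "gammaprev_domain_error")
  lo <- log10(min(rec$observed)); hi <- log10(max(rec$observed))
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- cut(log10(rec$observed), breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  parts <- split(seq_len(nrow(rec)), bin)
  out <- do.call(rbind, lapply(names(parts), function(b) {
    idx <- parts[[b]]
    data.frame(bin_mid = 10^((breaks[as.integer(b)] + breaks[as.integer(b) + 1L]) / 2),
               median_observed = stats::median(rec$observed[idx]),
               median_predicted = stats::median(rec$predicted[idx]),
               n_sites = length(idx))
  }))
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## permutation null for a Pearson correlation: shuffle y, recorrelate
perm_null_cor <- function(x, y, n_perm) {
  vapply(seq_len(n_perm),
         function(i) stats::cor(x, y[sample.int(length(y))]),
         numeric(1))
}

#' Permutation test of the error-prevalence correlation
#'
#' Pearson correlation between log10 observed prevalence and the relative
#' prediction error, with a permutation null: the errors are shuffled
#' against the prevalences `n_perm` times and the 2.5/97.5 percentiles of
#' the null correlations form the 95% interval. A significantly negative
#' correlation means predictions improve for more prevalent alleles. When
#' the table carries several species, the test is run per species.
#'
#' @param records a [evaluate_prevalence()] table with >= 10 usable sites
#'   (optionally with a `species_id` column).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param conf confidence level of the null interval (default 0.95).
#' @return data frame of class `permutation_result`, one row per species:
#'   `species_id`, `statistic` (observed r), `null_lower`, `null_upper`,
#'   `n_perm`, `n_sites`, `significant`.
#' @export
error_prevalence_correlation <- function(records, n_perm = 10000L,
                                         seed = NULL, conf = 0.95) {
  require_columns(records, c("observed", "epsilon"), "prevalence record table")
  if (!is.null(seed)) set.seed(seed)
  species <- if (!is.null(records$species_id)) records$species_id else "all"
  parts <- split(records[c("observed", "epsilon")], species)
  alpha <- (1 - conf) / 2
  out <- do.call(rbind, lapply(names(parts), function(sp) {
    rec <- parts[[sp]]
    rec <- rec[rec$observed > 0 & is.finite(rec$epsilon), , drop = FALSE]
    if (nrow(rec) < 10L)
      stop_gp("need at least 10 sites with positive observed prevalence",
              "gammaprev_domain_error")
    x <- log10(rec$observed); y <- rec$epsilon
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop_gp("correlation undefined for constant input", "gammaprev_domain_error")
    r <- stats::cor(x, y)
    null <- perm_null_cor(x, y, n_perm)
    q <- stats::quantile(null, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(species_id = sp, statistic = r, null_lower = q[1],
               null_upper = q[2], n_perm = n_perm, n_sites = nrow(rec),
               significant = (r < q[1] | r > q[2]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("permutation_result", class(out))
  out
}

#' Strain-structure threshold scan
#'
#' Tests, across species, whether the mean prevalence-prediction error
#' anti-correlates with the fraction of hosts harboring strain structure,
#' and how that correlation changes as rare alleles are excluded. For each
#' prevalence threshold `t`, each species' mean relative error is computed
#' over its sites with observed prevalence at or above `t` (a species is
#' retained at a threshold only with at least `min_sites` such sites), and
#' the Pearson correlation of these means with the per-species strain
#' fractions is compared against a permutation null in which errors are
#' shuffled within species and the threshold means recomputed.
#'
#' @param records a [evaluate_prevalence()] table with a `species_id`
#'   column covering >= 5 species.
#' @param strain_fractions data frame with `species_id` and
#'   `strain_fraction`.
#' @param thresholds increasing prevalence thresholds; default 20
#'   log10-spaced values from 0.01 to 0.5.
#' @param min_sites minimum sites a species needs at a threshold (default
#'   10).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param min_species minimum surviving species for a threshold to be
#'   defined (default 3).
#' @return data frame of class `strain_scan`: per threshold, the number of
#'   surviving species, observed correlation, null 95% window, and a
#'   significance flag; thresholds with too few species have `NA` results.
#' @export
strain_structure_scan <- function(records, strain_fractions,
                                  thresholds = 10^seq(log10(0.01), log10(0.5),
                                                      length.out = 20),
                                  min_sites = 10L, n_perm = 1000L,
                                  seed = NULL, min_species = 3L) {
  require_columns(records, c("species_id", "observed", "epsilon"),
                  "prevalence record table")
  require_columns(strain_fractions, c("species_id", "strain_fraction"),
                  "strain-structure table")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_gp("'thresholds' must be strictly increasing", "gammaprev_domain_error")
  sp_all <- unique(records$species_id)
  if (length(sp_all) < 5L)
    stop_gp("need at least 5 species for the scan", "gammaprev_domain_error")
  sf <- strain_fractions$strain_fraction[match(sp_all, strain_fractions$species_id)]
  if (any(is.na(sf)))
    stop_gp("strain fraction missing for some species", "gammaprev_domain_error")
  if (!is.null(seed)) set.seed(seed)

  parts <- split(records[c("observed", "epsilon")], records$species_id)[sp_all]
  ## per species, index sets of sites at or above each threshold
  idx_sets <- lapply(parts, function(rec)
    lapply(thresholds, function(t) which(rec$observed >= t)))

  mean_eps_at <- function(eps_list) {
    vapply(seq_along(thresholds), function(ti) {
      m <- vapply(seq_along(parts), function(si) {
        idx <- idx_sets[[si]][[ti]]
        if (length(idx) >= min_sites) mean(eps_list[[si]][idx]) else NA_real_
      }, numeric(1))
      m
    }, numeric(length(parts)))  # species x thresholds
  }

  eps_obs <- lapply(parts, `[[`, "epsilon")
  obs_mat <- mean_eps_at(eps_obs)
  cor_at <- function(mat) {
    vapply(seq_along(thresholds), function(ti) {
      ok <- is.finite(mat[, ti])
      if (sum(ok) < min_species) return(NA_real_)
      if (stats::sd(mat[ok, ti]) == 0 || stats::sd(sf[ok]) == 0) return(NA_real_)
      stats::cor(mat[ok, ti], sf[ok])
    }, numeric(1))
  }
  r_obs <- cor_at(obs_mat)

  null_mat <- matrix(NA_real_, nrow = n_perm, ncol = length(thresholds))
  for (p in seq_len(n_perm)) {
    eps_perm <- lapply(eps_obs, sample)
    null_mat[p, ] <- cor_at(mean_eps_at(eps_perm))
  }
  lo <- apply(null_mat, 2, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE))
  hi <- apply(null_mat, 2, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.975, na.rm = TRUE, names = FALSE))

  out <- data.frame(threshold = thresholds,
                    n_species = colSums(is.finite(obs_mat)),
                    statistic = r_obs, null_lower = lo, null_upper = hi,
                    significant = !is.na(r_obs) & (r_obs < lo | r_obs > hi),
                    n_perm = n_perm, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("strain_scan", class(out))
  out
}
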