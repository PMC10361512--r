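#' Across-host moments for every site
#'
#' Computes, per site, the mean allele frequency across hosts, the
#' (population) variance, the squared inverse CV `beta = fbar^2/var`, the
#' occupancy (fraction of hosts with `f > 0`) and the host count. Zeros are
#' included in the moments. Every row is checked against the Bhatia-Davis
#' bound `var <= (1 - fbar) * fbar`, which must hold for any `[0, 1]`-bounded
#' sample; a violation indicates an estimator bug and raises an error.
#'
#' @param freqs long-format frequency table with columns `site_id`,
#'   `host_id`, `f`.
#' @param include_zeros if `FALSE`, restrict to detected (nonzero)
#'   frequencies before computing moments.
#' @return data frame of class `site_moments` with columns `site_id`,
#'   `fbar`, `var`, `beta`, `occupancy`, `n_hosts`.
#' @export
compute_site_moments <- function(freqs, include_zeros = TRUE) {
  require_columns(freqs, c("site_id", "host_id", "f"), "frequency table")
  if (any(freqs$f < 0 | freqs$f > 1))
    stop_gp("frequencies must lie in [0, 1]", "gammaprev_domain_error")
  fs <- split(freqs$f, freqs$site_id)
  n <- lengths(fs)
  if (any(n < 2L))
    stop_gp("every site needs at least 2 hosts", "gammaprev_domain_error")
  occ_all <- vapply(fs, function(f) mean(f > 0), numeric(1))
  if (!include_zeros) fs <- lapply(fs, function(f) f[f > 0])
  fbar <- vapply(fs, function(f) if (length(f)) mean(f) else 0, numeric(1))
  v <- vapply(fs, function(f) if (length(f) > 1L) pop_var(f) else NA_real_,
              numeric(1))
  bound <- (1 - fbar) * fbar
  bad <- is.finite(v) & (v > bound + 1e-12)
  if (any(bad))
    stop_gp("internal error: Bhatia-Davis bound violated; moment estimator bug",
            "gammaprev_internal_error")
  out <- data.frame(site_id = names(fs), fbar = fbar, var = v,
                    beta = ifelse(is.finite(v) & v > 0, fbar^2 / v, NA_real_),
                    occupancy = occ_all, n_hosts = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("site_moments", class(out))
  out
}

#' Filter sites by occupancy
#'
#' Removes sites whose occupancy (fraction of hosts with a detected allele)
#' is below the threshold; used before the Taylor's Law fit to reduce the
#' contribution of excess zeros to the moments. The exclusion is strict
#' (`occupancy < min_occupancy`), so a site exactly at the threshold is kept.
#'
#' @param moments a [compute_site_moments()] table.
#' @param min_occupancy occupancy floor in `(0, 1]`; default 0.35.
#' @return the filtered moments table; warns if nothing survives.
#' @export
occupancy_filter <- function(moments, min_occupancy = 0.35) {
  require_columns(moments, "occupancy", "site-moments table")
  assert_number(min_occupancy, "min_occupancy", lower = 0, upper = 1)
  keep <- moments$occupancy >= min_occupancy
  if (any(!keep))
    message(sum(!keep), " site(s) removed below occupancy ", min_occupancy)
  out <- moments[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("occupancy filter removed every site; downstream fits will refuse")
  attr(out, "min_occupancy") <- min_occupancy
  out
}

#' Taylor's Law regression of variance on mean
#'
#' Ordinary least-squares fit of `log10(var)` on `log10(fbar)` across sites,
#' restricted to sites with `fbar <= fbar_max` (the mean-variance relation
#' is linear on log scales only below the regime where the Bhatia-Davis
#' bound takes over). A percentile bootstrap over sites (resample with
#' replacement, refit) gives the confidence interval on the exponent. An
#' exponent of 2 means a constant coefficient of variation across sites.
#'
#' @param moments a [compute_site_moments()] table (typically after
#'   [occupancy_filter()]).
#' @param fbar_max ceiling on the mean frequency for the fit (default 0.35).
#' @param n_bootstrap number of bootstrap resamples (default 10000).
#' @param seed optional integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class `taylor_fit`: `slope`, `intercept`, `n_sites`,
#'   `ci` (percentile interval on the slope), `fbar_max`, `min_occupancy`
#'   (if recorded upstream), `n_bootstrap`.
#' @export
taylor_fit <- function(moments, fbar_max = 0.35, n_bootstrap = 10000L,
                       seed = NULL, conf = 0.95) {
  require_columns(moments, c("fbar", "var"), "site-moments table")
  assert_number(fbar_max, "fbar_max", lower = 0, strict_lower = TRUE)
  usable <- moments$fbar > 0 & is.finite(moments$var) & moments$var > 0
  n_zero_var <- sum(moments$fbar > 0 & (!is.finite(moments$var) | moments$var <= 0))
  if (n_zero_var > 0)
    message(n_zero_var, " zero-variance site(s) excluded from the fit")
  dat <- moments[usable & moments$fbar <= fbar_max, , drop = FALSE]
  if (nrow(dat) < 10L)
    stop_gp("fewer than 10 usable sites below fbar_max; refusing to fit",
            "gammaprev_domain_error")
  x <- log10(dat$fbar); y <- log10(dat$var)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])

  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  boot <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    mx <- mean(xb); vx <- mean(xb * xb) - mx * mx
    boot[b] <- if (vx > 0) (mean(xb * yb) - mx * mean(yb)) / vx else NA_real_
  }
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(slope = slope, intercept = intercept, n_sites = n,
                 ci = ci, conf = conf, fbar_max = fbar_max,
                 min_occupancy = attr(moments, "min_occupancy"),
                 n_bootstrap = n_bootstrap),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat("Taylor's Law fit: log10(var) ~ log10(mean)\n")
  cat(sprintf("  slope %.4f  (%.0f%% bootstrap CI [%.4f, %.4f], %d resamples)\n",
              x$slope, 100 * x$conf, x$ci[1], x$ci[2], x$n_bootstrap))
  cat(sprintf("  intercept %.4f over %d sites with fbar <= %g\n",
              x$intercept, x$n_sites, x$fbar_max))
  invisible(x)
}

#' Bhatia-Davis upper bound on the variance of a bounded variable
#'
#' For a random variable confined to `[0, 1]` with mean `fbar`, the variance
#' cannot exceed `(1 - fbar) * fbar`. Above `fbar ~ 0.35` the empirical
#' mean-variance relation of allele frequencies tracks this bound rather
#' than a power law.
#'
#' @param fbar mean value(s) in `[0, 1]` (vectorized).
#' @return maximum possible variance at each mean.
#' @export
bhatia_davis_bound <- function(fbar) {
  if (any(!is.finite(fbar)) || any(fbar < 0 | fbar > 1))
    stop_gp("'fbar' must lie in [0, 1]", "gammaprev_domain_error")
  (1 - fbar) * fbar
}
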