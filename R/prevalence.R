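#' Sampling distribution of alternate-allele read counts
#'
#' Probability of observing `A` alternate-allele reads at total depth `D`
#' when the latent allele frequency is gamma distributed with mean `fbar`
#' and squared inverse CV `beta`, under Poisson read sampling:
#' \deqn{\Pr[A \mid D, \beta, \beta/\bar f] =
#'   \frac{\Gamma(\beta + A)}{A!\,\Gamma(\beta)}
#'   \left(\frac{\bar f D}{\beta + \bar f D}\right)^{A}
#'   \left(\frac{\beta}{\beta + \bar f D}\right)^{\beta}}
#' Computed in log-space via `lgamma` for numerical stability.
#'
#' @param A integer read count(s), >= 0 (vectorized).
#' @param D total sequencing depth (> 0).
#' @param fbar mean allele frequency across hosts (> 0).
#' @param beta squared inverse coefficient of variation (> 0).
#' @param log if `TRUE` return log-probabilities.
#' @return probability (or log-probability) of each count in `A`.
#' @export
#' @examples
#' sampling_pmf(0, D = 20, fbar = 0.05, beta = 1)  # (1 + 1)^-1 = 0.5
sampling_pmf <- function(A, D, fbar, beta, log = FALSE) {
  if (any(!is.finite(A)) || any(A < 0) || any(A != floor(A)))
    stop_gp("'A' must contain nonnegative integers", "gammaprev_domain_error")
  assert_number(D, "D", lower = 0, strict_lower = TRUE)
  assert_number(fbar, "fbar", lower = 0, strict_lower = TRUE)
  assert_number(beta, "beta", lower = 0, strict_lower = TRUE)
  m <- fbar * D
  logp <- lgamma(beta + A) - lgamma(A + 1) - lgamma(beta) +
    A * (base::log(m) - log1p(m / beta) - base::log(beta)) -
    beta * log1p(m / beta)
  ## A * log(m / (beta + m)) rewritten as A * (log m - log beta - log1p(m/beta))
  if (log) logp else exp(logp)
}

#' Probability of non-detection of an allele
#'
#' Probability that zero alternate-allele reads are observed at depth `D`
#' for a gamma-distributed allele: `(1 + D * fbar / beta)^(-beta)`. Equals
#' [sampling_pmf()] at `A = 0`; strictly decreasing in both `D` and `fbar`.
#' At `D = 0` nothing is sampled and the probability is 1.
#'
#' @param D total sequencing depth(s), >= 0 (vectorized).
#' @param fbar mean allele frequency across hosts (> 0).
#' @param beta squared inverse coefficient of variation (> 0).
#' @return probability of observing no alternate reads at each depth.
#' @export
absence_probability <- function(D, fbar, beta) {
  if (any(!is.finite(D)) || any(D < 0))
    stop_gp("'D' must contain nonnegative finite depths", "gammaprev_domain_error")
  assert_number(fbar, "fbar", lower = 0, strict_lower = TRUE)
  assert_number(beta, "beta", lower = 0, strict_lower = TRUE)
  exp(-beta * log1p(D * fbar / beta))
}

#' Predicted prevalence of an allele across hosts
#'
#' Expected fraction of `M` hosts in which the allele is detected (at least
#' one alternate read), averaging the per-host presence probability over the
#' observed per-host depths:
#' `1 - (1/M) * sum_m Pr[0 | D_m, beta, beta/fbar]`.
#'
#' @param D_by_host numeric vector of per-host sequencing depths.
#' @param fbar mean allele frequency across hosts (> 0).
#' @param beta squared inverse coefficient of variation (> 0).
#' @return predicted prevalence in `[0, 1]`.
#' @export
#' @examples
#' predicted_prevalence(100, fbar = 0.05, beta = 1)  # 1 - 1/6 = 5/6
predicted_prevalence <- function(D_by_host, fbar, beta) {
  if (length(D_by_host) == 0L)
    stop_gp("'D_by_host' must contain at least one host", "gammaprev_domain_error")
  1 - mean(absence_probability(D_by_host, fbar, beta))
}

#' Predicted prevalence under a minor-allele detection cutoff
#'
#' When the processing pipeline only reports alleles with at least
#' `A_cutoff` supporting reads, read counts below the cutoff are observed
#' as zeros. The prediction accounts for this truncation by summing the
#' sampling distribution up to (and excluding) the cutoff:
#' `1 - (1/M) * sum_m sum_{A=0}^{A_cutoff-1} Pr[A | D_m, beta, beta/fbar]`.
#' With `A_cutoff = 1` this reduces exactly to [predicted_prevalence()].
#'
#' @inheritParams predicted_prevalence
#' @param A_cutoff minimum alternate-read count for detection (>= 1).
#' @return predicted prevalence in `[0, 1]`; never exceeds the untruncated
#'   prediction.
#' @export
predicted_prevalence_truncated <- function(D_by_host, fbar, beta, A_cutoff = 10L) {
  if (length(D_by_host) == 0L)
    stop_gp("'D_by_host' must contain at least one host", "gammaprev_domain_error")
  assert_number(A_cutoff, "A_cutoff", lower = 1)
  a <- seq.int(0L, A_cutoff - 1L)
  below <- vapply(D_by_host, function(d) sum(sampling_pmf(a, d, fbar, beta)),
                  numeric(1))
  1 - mean(pmin(below, 1))
}

#' Observed prevalence of an allele
#'
#' Fraction of hosts in which the allele was detected, i.e. has a nonzero
#' (post-filter) frequency.
#'
#' @param f_by_host numeric vector of per-host allele frequencies, with 0
#'   encoding non-detection.
#' @return observed prevalence in `[0, 1]`.
#' @export
observed_prevalence <- function(f_by_host) {
  if (length(f_by_host) == 0L)
    stop_gp("'f_by_host' must contain at least one host", "gammaprev_domain_error")
  mean(f_by_host > 0)
}

#' Relative error of a prevalence prediction
#'
#' `|observed - predicted| / observed`; requires a strictly positive
#' observed value (all-absent sites are excluded upstream).
#'
#' @param observed observed prevalence(s), > 0.
#' @param predicted predicted prevalence(s).
#' @return relative error(s), >= 0.
#' @export
relative_error <- function(observed, predicted) {
  if (any(observed <= 0))
    stop_gp("relative error undefined for observed prevalence <= 0",
            "gammaprev_domain_error")
  abs(observed - predicted) / observed
}

#' Mean frequency versus predicted prevalence curve
#'
#' Evaluates the (truncated) prevalence prediction along a grid of mean
#' frequencies at fixed `beta` and per-host depths; prevalence is monotone
#' nondecreasing in the mean frequency.
#'
#' @param fbar_grid increasing grid of mean frequencies (> 0).
#' @param beta squared inverse coefficient of variation (> 0).
#' @param D_by_host numeric vector of per-host depths.
#' @param A_cutoff detection cutoff (>= 1); 1 gives the untruncated form.
#' @return data frame with columns `fbar` and `prevalence`.
#' @export
prevalence_curve <- function(fbar_grid, beta, D_by_host, A_cutoff = 1L) {
  if (length(fbar_grid) == 0L)
    stop_gp("'fbar_grid' must be nonempty", "gammaprev_domain_error")
  prev <- vapply(fbar_grid, function(fb)
    predicted_prevalence_truncated(D_by_host, fb, beta, A_cutoff), numeric(1))
  data.frame(fbar = fbar_grid, prevalence = prev)
}

#' Per-site moments used for prevalence prediction
#'
#' Computes, for every site, the across-host mean frequency and squared
#' inverse CV used as the gamma's empirical parameters. Moments are taken
#' over ALL hosts, zeros included: under the SLM-plus-sampling model a zero
#' is a sampling artifact of an always-present strain. Population
#' (divide-by-n) moments are used. Sites where no allele was ever detected,
#' or whose across-host variance is zero (beta undefined), are excluded
#' with a message.
#'
#' @param freqs long-format frequency table with columns `site_id`,
#'   `host_id`, `f` (and optionally `D`).
#' @param include_zeros if `FALSE`, moments are computed over detected
#'   (nonzero) frequencies only; the default `TRUE` matches the
#'   macroecological convention.
#' @return data frame with columns `site_id`, `fbar`, `var`, `beta`,
#'   `occupancy`, `n_hosts`.
#' @export
site_moments_for_prediction <- function(freqs, include_zeros = TRUE) {
  require_columns(freqs, c("site_id", "host_id", "f"), "frequency table")
  mom <- compute_site_moments(freqs, include_zeros = include_zeros)
  drop_zero <- mom$fbar <= 0
  drop_var <- !drop_zero & (mom$var <= 0 | !is.finite(mom$beta))
  if (any(drop_zero))
    message(sum(drop_zero), " all-zero site(s) excluded (no detections)")
  if (any(drop_var))
    message(sum(drop_var), " zero-variance site(s) excluded (beta undefined)")
  mom[!(drop_zero | drop_var), , drop = FALSE]
}

#' Predict and score allelic prevalence for every site
#'
#' The central pipeline step: for each site, estimates the gamma parameters
#' from across-host moments (or takes them from supplied ground truth),
#' computes the truncated and untruncated prevalence predictions from the
#' per-host depths, and scores them against the observed prevalence via the
#' relative error. Hosts with depth below `D_min` are excluded from both the
#' observed and the predicted prevalence so the two condition on the same
#' host set.
#'
#' @param freqs long-format frequency table (`site_id`, `host_id`, `f`, `D`),
#'   typically from [apply_detection_filter()]; zeros encode non-detection.
#' @param A_cutoff detection cutoff used for the truncated prediction;
#'   defaults to the cutoff recorded by [apply_detection_filter()], else 1.
#' @param D_min minimum per-host depth; defaults to the recorded value, else 0.
#' @param moments where the gamma parameters come from: `"observed"`
#'   (estimated from `freqs`, the zero-free-parameter route used on real
#'   data), `"truth"` (per-site `fbar`/`beta` from `truth_sites`), or
#'   `"latent"` (estimated from the latent pre-sampling frequencies in
#'   `truth_latent`).
#' @param truth_sites data frame with `site_id`, `true_fbar`, `true_beta`
#'   (required for `moments = "truth"`).
#' @param truth_latent long data frame with `site_id`, `host_id`, `f_latent`
#'   (required for `moments = "latent"`).
#' @param include_zeros passed to [site_moments_for_prediction()].
#' @return data frame of class `prevalence_record` with columns `site_id`,
#'   `observed`, `predicted`, `predicted_untruncated`, `epsilon`, `fbar`,
#'   `beta`, `n_hosts`. Sites with zero observed prevalence or undefined
#'   moments are dropped with a message.
#' @export
evaluate_prevalence <- function(freqs,
                                A_cutoff = NULL, D_min = NULL,
                                moments = c("observed", "truth", "latent"),
                                truth_sites = NULL, truth_latent = NULL,
                                include_zeros = TRUE) {
  moments <- match.arg(moments)
  require_columns(freqs, c("site_id", "host_id", "f", "D"), "frequency table")
  A_cutoff <- A_cutoff %||% attr(freqs, "A_cutoff") %||% 1L
  D_min <- D_min %||% attr(freqs, "D_min") %||% 0L

  keep <- freqs$D >= D_min
  if (!all(keep)) {
    message(sum(!keep), " observation(s) below D_min excluded from evaluation")
    freqs <- freqs[keep, , drop = FALSE]
  }

  params <- switch(moments,
    observed = {
      mom <- site_moments_for_prediction(freqs, include_zeros = include_zeros)
      data.frame(site_id = mom$site_id, fbar = mom$fbar, beta = mom$beta)
    },
    truth = {
      if (is.null(truth_sites))
        stop_gp("moments = 'truth' requires 'truth_sites'", "gammaprev_domain_error")
      require_columns(truth_sites, c("site_id", "true_fbar", "true_beta"),
                      "ground-truth site table")
      data.frame(site_id = truth_sites$site_id,
                 fbar = truth_sites$true_fbar, beta = truth_sites$true_beta)
    },
    latent = {
      if (is.null(truth_latent))
        stop_gp("moments = 'latent' requires 'truth_latent'", "gammaprev_domain_error")
      require_columns(truth_latent, c("site_id", "host_id", "f_latent"),
                      "latent frequency table")
      lat <- truth_latent
      names(lat)[names(lat) == "f_latent"] <- "f"
      mom <- site_moments_for_prediction(lat, include_zeros = TRUE)
      data.frame(site_id = mom$site_id, fbar = mom$fbar, beta = mom$beta)
    })

  split_f <- split(freqs[c("f", "D")], freqs$site_id)
  site_ids <- intersect(names(split_f), as.character(params$site_id))
  params <- params[match(site_ids, as.character(params$site_id)), , drop = FALSE]

  res <- lapply(seq_along(site_ids), function(i) {
    sf <- split_f[[site_ids[i]]]
    fb <- params$fbar[i]; be <- params$beta[i]
    if (!is.finite(fb) || !is.finite(be) || fb <= 0 || be <= 0) return(NULL)
    obs <- observed_prevalence(sf$f)
    if (obs <= 0) return(NULL)
    pred_u <- predicted_prevalence(sf$D, fb, be)
    pred_t <- if (A_cutoff > 1L)
      predicted_prevalence_truncated(sf$D, fb, be, A_cutoff) else pred_u
    data.frame(site_id = site_ids[i], observed = obs, predicted = pred_t,
               predicted_untruncated = pred_u,
               epsilon = relative_error(obs, pred_t),
               fbar = fb, beta = be, n_hosts = nrow(sf))
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " site(s) dropped (zero observed prevalence or invalid moments)")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(site_id = character(), observed = numeric(),
                      predicted = numeric(), predicted_untruncated = numeric(),
                      epsilon = numeric(), fbar = numeric(), beta = numeric(),
                      n_hosts = integer())
  rownames(out) <- NULL
  attr(out, "A_cutoff") <- A_cutoff
  attr(out, "D_min") <- D_min
  attr(out, "moments") <- moments
  class(out) <- c("prevalence_record", class(out))
  out
}
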