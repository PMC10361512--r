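#' Pool and rescale log frequencies for a data collapse
#'
#' The rescaling behind the across-species data collapse of allele-frequency
#' distributions: for each species, pool all nonzero frequencies, take
#' log10, and convert each value to a standard score (z-score). Distributions
#' that differ only in their moments then fall on a common curve. For the
#' mean-frequency variant, values equal to 1 can be excluded to limit the
#' effect of the bounded support.
#'
#' @param x numeric vector of frequencies, or a data frame with a column
#'   `f` and optionally `species_id`.
#' @param exclude_f1 drop values equal to 1 before rescaling (default
#'   `FALSE`).
#' @return if `x` is a vector (or has a single species): numeric z-scores
#'   with attribute `n_zero_dropped`; otherwise a data frame with columns
#'   `species_id` and `z`. Within each species the output has mean 0 and
#'   standard deviation 1.
#' @export
pool_and_rescale <- function(x, exclude_f1 = FALSE) {
  if (is.data.frame(x)) {
    require_columns(x, "f", "frequency table")
    if (!is.null(x$species_id) && length(unique(x$species_id)) > 1L) {
      parts <- split(x$f, x$species_id)
      out <- do.call(rbind, lapply(names(parts), function(sp) {
        z <- pool_and_rescale(parts[[sp]], exclude_f1 = exclude_f1)
        data.frame(species_id = sp, z = as.numeric(z),
                   stringsAsFactors = FALSE)
      }))
      return(out)
    }
    x <- x$f
  }
  n_zero <- sum(x == 0)
  v <- x[x > 0]
  if (exclude_f1) v <- v[v < 1]
  if (length(v) < 2L)
    stop_gp("need at least 2 nonzero frequencies to rescale",
            "gammaprev_domain_error")
  if (n_zero > 0)
    message(n_zero, " zero frequencies dropped before rescaling")
  z <- zscore(log10(v))
  attr(z, "n_zero_dropped") <- n_zero
  z
}

## log-gamma density: distribution of X when exp((X - location)/scale) is
## standard gamma with the given shape. If f ~ Gamma(shape k, rate r) then
## log10(f) is loggamma(shape k, location -log10(r), scale 1/ln(10)).
dloggamma <- function(x, shape, location = 0, scale = 1, log = FALSE) {
  z <- (x - location) / scale
  lp <- shape * z - exp(z) - lgamma(shape) - base::log(scale)
  if (log) lp else exp(lp)
}

#' Maximum-likelihood fit of a log-frequency distribution
#'
#' Fits the distribution of log10-transformed nonzero frequencies under one
#' of two families: `"gamma"` fits the loggamma family (3 parameters:
#' shape, location, scale — the law of the log of a gamma variable), and
#' `"lognormal"` fits a Gaussian (2 parameters) on the log values. Fitting
#' on the log scale matches how the rescaled distributions are examined.
#'
#' @param values numeric vector of log10 frequencies (>= 10 values).
#' @param family `"gamma"` or `"lognormal"`.
#' @return object of class `gp_fit`: `family`, `par` (named parameter
#'   vector), `logL` (maximized log-likelihood), `k` (number of free
#'   parameters), `n`, and a `data_id` fingerprint used by [aic_compare()].
#' @export
fit_log_frequency_distribution <- function(values, family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10L)
    stop_gp("need at least 10 values to fit", "gammaprev_domain_error")
  data_id <- c(n = n, mean = mean(values), var = stats::var(values))

  if (family == "lognormal") {
    ## Gaussian on log10 values; ML closed form (1/n variance)
    m <- mean(values)
    s <- sqrt(pop_var(values))
    if (s == 0)
      stop_gp("degenerate data: zero variance", "gammaprev_domain_error")
    logL <- sum(stats::dnorm(values, m, s, log = TRUE))
    par <- c(mean = m, sd = s)
    k <- 2L
  } else {
    m <- mean(values); v <- pop_var(values)
    if (v == 0)
      stop_gp("degenerate data: zero variance", "gammaprev_domain_error")
    nll <- function(theta) {
      shape <- exp(theta[1]); scale <- exp(theta[3])
      -sum(dloggamma(values, shape, theta[2], scale, log = TRUE))
    }
    ## moment-matched starts over a shape grid: mean = loc + scale*digamma,
    ## var = scale^2 * trigamma. The shape is bounded above because the
    ## loggamma tends to a Gaussian as shape -> Inf; on near-Gaussian data
    ## the ML solution sits at that boundary.
    best <- NULL
    for (shape0 in c(0.5, 1, 2, 5, 20)) {
      scale0 <- sqrt(v / trigamma(shape0))
      loc0 <- m - scale0 * digamma(shape0)
      fit <- try(stats::optim(c(log(shape0), loc0, log(scale0)), nll,
                              method = "L-BFGS-B",
                              lower = c(-7, -Inf, log(1e-8)),
                              upper = c(log(1e6), Inf, 20),
                              control = list(maxit = 1000, factr = 1e4)),
                 silent = TRUE)
      if (inherits(fit, "try-error") || fit$convergence != 0) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
      stop_gp("loggamma fit failed to converge from every start",
              "gammaprev_fit_error")
    par <- c(shape = exp(best$par[1]), location = best$par[2],
             scale = exp(best$par[3]))
    logL <- -best$value
    k <- 3L
  }
  structure(list(family = family, par = par, logL = logL, k = k, n = n,
                 data_id = data_id),
            class = "gp_fit")
}

#' Compare distribution fits by AIC
#'
#' Akaike Information Criterion comparison of [fit_log_frequency_distribution()]
#' results fitted on identical data: `AIC = 2k - 2 logL`; the lowest value
#' wins.
#'
#' @param fits list of `gp_fit` objects (>= 2), all fit on the same data.
#' @return data frame with columns `family`, `k`, `logL`, `AIC`, `delta`
#'   (AIC minus the winner's); attribute `winner` names the winning family,
#'   attribute `margin` gives the winner's AIC advantage.
#' @export
aic_compare <- function(fits) {
  if (length(fits) < 2L)
    stop_gp("need at least 2 fits to compare", "gammaprev_domain_error")
  stopifnot(all(vapply(fits, inherits, logical(1), "gp_fit")))
  ids <- vapply(fits, function(f) paste(signif(f$data_id, 12), collapse = "|"),
                character(1))
  if (length(unique(ids)) != 1L)
    stop_gp("fits were not computed on identical data", "gammaprev_domain_error")
  aic <- vapply(fits, function(f) 2 * f$k - 2 * f$logL, numeric(1))
  out <- data.frame(family = vapply(fits, `[[`, character(1), "family"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    AIC = aic, delta = aic - min(aic),
                    stringsAsFactors = FALSE)
  ord <- order(out$AIC)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "winner") <- out$family[1]
  attr(out, "margin") <- if (nrow(out) > 1) out$AIC[2] - out$AIC[1] else NA_real_
  out
}

#' Empirical survival curve
#'
#' Step-function survival probabilities `P(X >= x)` evaluated at the sorted
#' distinct values of the input; no smoothing. Ties collapse into a single
#' step; the curve is monotone nonincreasing from 1 down to the fraction of
#' observations tied with the maximum.
#'
#' @param values nonempty numeric vector.
#' @return data frame with columns `value` and `survival`.
#' @export
survival_curve <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop_gp("'values' must be nonempty and finite", "gammaprev_domain_error")
  v <- sort(unique(values))
  n <- length(values)
  ## P(X >= v_i) = 1 - ecdf at the previous distinct value
  surv <- 1 - c(0, cumsum(tabulate(match(sort(values), v)))[-length(v)]) / n
  data.frame(value = v, survival = surv)
}
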