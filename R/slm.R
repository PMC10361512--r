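#' Stochastic Logistic Model parameters
#'
#' Container for the three parameters of the Stochastic Logistic Model (SLM)
#' of strain frequency dynamics: df = (f/tau)(1 - f/K) dt + sqrt(sigma/tau) f dW
#' (Ito convention). `1/tau` is the intrinsic growth rate, `K` the carrying
#' capacity expressed as a relative frequency, and `sigma` the squared
#' coefficient of variation of growth-rate fluctuations.
#'
#' @param tau intrinsic growth timescale (> 0).
#' @param K carrying capacity as a relative frequency, in (0, 1).
#' @param sigma coefficient of variation of growth-rate fluctuations; must be
#'   in (0, 2) for a stationary gamma distribution to exist.
#' @return an object of class `slm_params`.
#' @export
#' @examples
#' slm_params(tau = 1, K = 0.5, sigma = 1)
slm_params <- function(tau = 1, K, sigma) {
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  assert_number(K, "K", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (sigma >= 2)
    stop_gp("sigma >= 2: no stationary gamma (shape 2/sigma - 1 must be positive)",
            "gammaprev_domain_error")
  structure(list(tau = tau, K = K, sigma = sigma), class = "slm_params")
}

#' Gamma distribution parameters (shape/rate)
#'
#' @param shape,rate strictly positive gamma parameters.
#' @return an object of class `gamma_params` with elements `shape` and `rate`.
#' @export
gamma_params <- function(shape, rate) {
  assert_number(shape, "shape", lower = 0, strict_lower = TRUE)
  assert_number(rate, "rate", lower = 0, strict_lower = TRUE)
  structure(list(shape = shape, rate = rate), class = "gamma_params")
}

#' Stationary distribution of the Stochastic Logistic Model
#'
#' The stationary solution of the SLM is a gamma distribution with
#' shape `2/sigma - 1` and rate `2/(K * sigma)`. Its mean is
#' `K (1 - sigma/2)` and its squared coefficient of variation is
#' `sigma / (2 - sigma)`.
#'
#' @param params an [slm_params()] object.
#' @return a [gamma_params()] object.
#' @export
#' @examples
#' slm_stationary(slm_params(K = 0.5, sigma = 1))  # shape 1, rate 4
slm_stationary <- function(params) {
  stopifnot(inherits(params, "slm_params"))
  gamma_params(shape = 2 / params$sigma - 1,
               rate  = 2 / (params$K * params$sigma))
}

#' Gamma parameters from across-host frequency moments
#'
#' Moment parameterization of the gamma allele-frequency distribution: the
#' mean frequency `fbar` and the squared inverse coefficient of variation
#' `beta = fbar^2 / var` map to shape `beta` and rate `beta / fbar`. This is
#' the zero-free-parameter form used for all prevalence predictions.
#'
#' @param fbar mean allele frequency across hosts (> 0).
#' @param beta squared inverse coefficient of variation (> 0).
#' @return a [gamma_params()] object with mean `fbar` and CV^-2 `beta`.
#' @export
#' @examples
#' gamma_from_moments(fbar = 0.1, beta = 1)  # exponential with mean 0.1
gamma_from_moments <- function(fbar, beta) {
  assert_number(fbar, "fbar", lower = 0, strict_lower = TRUE)
  assert_number(beta, "beta", lower = 0, strict_lower = TRUE)
  gamma_params(shape = beta, rate = beta / fbar)
}

#' Moments of a gamma distribution
#'
#' Inverse of [gamma_from_moments()]: returns the mean `fbar = shape/rate`
#' and the squared inverse CV `beta = shape`.
#'
#' @param params a [gamma_params()] object.
#' @return list with elements `fbar` and `beta`.
#' @export
gamma_moments <- function(params) {
  stopifnot(inherits(params, "gamma_params"))
  list(fbar = params$shape / params$rate, beta = params$shape)
}

#' Simulate the Stochastic Logistic Model by Euler-Maruyama
#'
#' Integrates df = (f/tau)(1 - f/K) dt + sqrt(sigma/tau) f dW (Ito) with an
#' Euler-Maruyama scheme. Steps that would take the frequency to or below
#' zero are reflected (f <- |f|) and values above one are capped at one;
#' both event counts are reported. Post-burn-in samples are distributed per
#' [slm_stationary()] up to discretization error.
#'
#' Values above one can optionally be capped (`cap_at_one = TRUE`) when a
#' strictly bounded frequency path is wanted; the default leaves the brief
#' excursions above one untouched, because the analytic stationary solution
#' is the unbounded gamma and capping would truncate its upper tail (about
#' 1.8% of the mass at K = 0.5, sigma = 1).
#'
#' @param params an [slm_params()] object.
#' @param f0 initial frequency in (0, 1); defaults to the carrying capacity.
#' @param dt time step; should be much smaller than `tau` (default `tau/100`).
#' @param n_steps number of post-burn-in steps to record (per replicate,
#'   after thinning).
#' @param burn_in number of initial steps discarded (default `50 * tau / dt`).
#' @param seed optional integer seed.
#' @param n_rep number of independent replicate trajectories (vectorized).
#' @param thin record every `thin`-th step (default 1, the full path).
#' @param cap_at_one cap the path at 1 (default `FALSE`; see above).
#' @return list with `samples` (an `n_steps` x `n_rep` matrix of recorded
#'   frequencies), `n_reflected`, `n_capped` (excursions above one, capped
#'   or not), and the step size used.
#' @export
simulate_slm <- function(params, f0 = params$K, dt = params$tau / 100,
                         n_steps = 1000L, burn_in = ceiling(50 * params$tau / dt),
                         seed = NULL, n_rep = 1L, thin = 1L,
                         cap_at_one = FALSE) {
  stopifnot(inherits(params, "slm_params"))
  assert_number(f0, "f0", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (dt >= params$tau)
    warning("dt >= tau: Euler-Maruyama discretization will be unreliable")
  if (!is.null(seed)) set.seed(seed)

  tau <- params$tau; K <- params$K; sig <- params$sigma
  noise_sd <- sqrt(sig / tau) * sqrt(dt)
  f <- rep(f0, n_rep)
  n_reflected <- 0L; n_capped <- 0L
  out <- matrix(NA_real_, nrow = n_steps, ncol = n_rep)
  total <- burn_in + n_steps * thin
  row <- 0L
  for (step in seq_len(total)) {
    drift <- (f / tau) * (1 - f / K) * dt
    f <- f + drift + if (sig > 0) noise_sd * f * stats::rnorm(n_rep) else 0
    neg <- f <= 0
    if (any(neg)) {
      n_reflected <- n_reflected + sum(neg)
      f[neg] <- abs(f[neg])
      ## a reflected zero would be absorbing under multiplicative noise
      f[f == 0] <- .Machine$double.eps
    }
    hi <- f > 1
    if (any(hi)) {
      n_capped <- n_capped + sum(hi)
      if (cap_at_one) f[hi] <- 1
    }
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- f
    }
  }
  list(samples = out, n_reflected = n_reflected, n_capped = n_capped,
       dt = dt, burn_in = burn_in, thin = thin)
}

#' Maximum attainable frequency under positive selection
#'
#' For an allele sweeping from low frequency under selection coefficient
#' `s > 0` for `t` generations in a population of size `N`, the maximum
#' frequency it can have reached is `(exp(s t) - 1) / (2 N s)`. As `t -> 0`
#' this reduces to `t / (2N)`.
#'
#' @param s selection coefficient (> 0).
#' @param t elapsed time in generations (> 0).
#' @param N population size (>= 1).
#' @return the maximum frequency; a warning is issued if it exceeds 1 (the
#'   low-frequency regime no longer applies).
#' @export
f_max <- function(s, t, N) {
  assert_number(s, "s", lower = 0, strict_lower = TRUE)
  assert_number(t, "t", lower = 0, strict_lower = TRUE)
  assert_number(N, "N", lower = 1)
  fm <- expm1(s * t) / (2 * N * s)
  if (fm > 1)
    warning("f_max > 1: parameters leave the f << 1 regime the model assumes")
  fm
}

#' Mutation-selection balance parameters
#'
#' Parameters of the linearized single-locus model of allele-frequency
#' dynamics under forward/backward mutation (`mu`, `upsilon`), selection
#' (`s`) and genetic drift in a population of size `N`. The sign of `s`
#' selects the regime: purifying selection (`s < 0`) or an ongoing sweep
#' (`s > 0`, which additionally requires the elapsed time `t`).
#'
#' @param N population size (>= 1).
#' @param mu forward mutation rate per generation (>= 0).
#' @param s selection coefficient (nonzero).
#' @param t elapsed time in generations (required when `s > 0`).
#' @param upsilon backward mutation rate (>= 0); not used by the linearized
#'   stationary forms but carried for completeness.
#' @return an object of class `evo_params`.
#' @export
evo_params <- function(N, mu, s, t = NULL, upsilon = 0) {
  assert_number(N, "N", lower = 1)
  assert_number(mu, "mu", lower = 0)
  assert_number(upsilon, "upsilon", lower = 0)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s == 0)
    stop_gp("'s' must be a single nonzero number", "gammaprev_domain_error")
  if (s > 0) {
    if (is.null(t))
      stop_gp("the s > 0 regime requires the elapsed time 't'", "gammaprev_domain_error")
    assert_number(t, "t", lower = 0, strict_lower = TRUE)
  }
  structure(list(N = N, mu = mu, upsilon = upsilon, s = s, t = t),
            class = "evo_params")
}

#' Gamma allele-frequency distribution under mutation-selection balance
#'
#' Two single-locus evolutionary regimes predict a gamma distribution of
#' allele frequencies in the low-frequency limit:
#' purifying selection (`s < 0`), Gamma(shape `2 N mu`, rate `2 N |s|`) with
#' mean `mu / |s|`; and an ongoing sweep (`s > 0`),
#' Gamma(shape `2 N mu`, rate `1 / f_max`) with mean `2 N mu f_max`, where
#' `f_max` is given by [f_max()]. The shape, hence the squared inverse CV,
#' equals `2 N mu` in both regimes.
#'
#' @param params an [evo_params()] object with `s != 0`.
#' @return a [gamma_params()] object.
#' @export
evo_gamma_params <- function(params) {
  stopifnot(inherits(params, "evo_params"))
  if (params$s == 0)
    stop_gp("neutral case (s = 0) has no gamma stationary form here",
            "gammaprev_domain_error")
  shape <- 2 * params$N * params$mu
  if (params$s < 0) {
    gamma_params(shape = shape, rate = 2 * params$N * abs(params$s))
  } else {
    fm <- f_max(params$s, params$t, params$N)
    gamma_params(shape = shape, rate = 1 / fm)
  }
}

#' Simulate the linearized evolutionary Langevin equation
#'
#' Euler-Maruyama integration of df = (sign(s) |s| f + mu) dt + sqrt(f/N) dW,
#' the low-frequency (f << 1) limit of single-locus dynamics with mutation,
#' selection and drift. For `s < 0` the long-run samples follow the
#' purifying-selection gamma of [evo_gamma_params()].
#'
#' @param params an [evo_params()] object.
#' @param f0 initial frequency (should be << 1).
#' @param dt time step in generations.
#' @param n_steps number of post-burn-in steps to record per replicate.
#' @param burn_in steps discarded before recording (default 0).
#' @param seed optional integer seed.
#' @param n_rep number of replicate trajectories.
#' @param thin record every `thin`-th step.
#' @return list as in [simulate_slm()]; a warning is issued if any
#'   trajectory reaches f >= 0.5 (outside the f << 1 regime).
#' @export
simulate_evo_langevin <- function(params, f0, dt, n_steps, burn_in = 0L,
                                  seed = NULL, n_rep = 1L, thin = 1L) {
  stopifnot(inherits(params, "evo_params"))
  assert_number(f0, "f0", lower = 0, upper = 1)
  if (!is.null(seed)) set.seed(seed)
  s <- params$s; mu <- params$mu; N <- params$N
  sqdt <- sqrt(dt)
  f <- rep(f0, n_rep)
  n_reflected <- 0L
  hit_half <- FALSE
  out <- matrix(NA_real_, nrow = n_steps, ncol = n_rep)
  total <- burn_in + n_steps * thin
  row <- 0L
  for (step in seq_len(total)) {
    f <- f + (s * f + mu) * dt + sqrt(pmax(f, 0) / N) * sqdt * stats::rnorm(n_rep)
    neg <- f < 0
    if (any(neg)) {
      n_reflected <- n_reflected + sum(neg)
      f[neg] <- abs(f[neg])
    }
    if (!hit_half && any(f >= 0.5)) hit_half <- TRUE
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- f
    }
  }
  if (hit_half)
    warning("trajectory reached f >= 0.5: outside the f << 1 regime")
  list(samples = out, n_reflected = n_reflected, dt = dt,
       burn_in = burn_in, thin = thin)
}
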