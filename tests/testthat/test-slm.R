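test_that("the SLM stationary distribution is the expected gamma", {
  gp <- slm_stationary(slm_params(K = 0.5, sigma = 1))
  expect_equal(gp$shape, 1)
  expect_equal(gp$rate, 4)

  ## mean K(1 - sigma/2) and CV^2 = sigma/(2 - sigma)
  gp2 <- slm_stationary(slm_params(K = 0.1, sigma = 0.4))
  expect_equal(gp2$shape / gp2$rate, 0.08)
  expect_equal(1 / gp2$shape, 0.25)

  expect_error(slm_params(K = 0.5, sigma = 2), "no stationary gamma")
  expect_error(slm_params(K = 1.2, sigma = 0.5), "K")
})

test_that("moment parameterization and shape/rate form are inverses", {
  gp <- gamma_from_moments(fbar = 0.1, beta = 1)
  expect_equal(gp$shape, 1)
  expect_equal(gp$rate, 10)
  ## variance fbar^2 / beta
  gp2 <- gamma_from_moments(0.25, 4)
  expect_equal(gp2$shape / gp2$rate^2, 0.015625)

  set.seed(1)
  for (i in 1:20) {
    p <- slm_params(K = runif(1, 0.01, 0.99), sigma = runif(1, 0.05, 1.9))
    gp <- slm_stationary(p)
    mom <- gamma_moments(gp)
    back <- gamma_from_moments(mom$fbar, mom$beta)
    expect_equal(back$shape, gp$shape)
    expect_equal(back$rate, gp$rate)
  }
  expect_error(gamma_from_moments(-0.1, 1), "fbar")
  expect_error(gamma_from_moments(0.1, 0), "beta")
})

test_that("the noiseless SLM relaxes to its carrying capacity", {
  p <- slm_params(K = 0.3, sigma = 1e-8)
  sim <- simulate_slm(p, f0 = 0.02, n_steps = 1, burn_in = 3000, seed = 1)
  expect_equal(as.numeric(sim$samples), 0.3, tolerance = 1e-3)
})

test_that("post-burn-in SLM samples follow the stationary gamma", {
  p <- slm_params(K = 0.3, sigma = 0.5)
  sim <- simulate_slm(p, n_steps = 60, burn_in = 5000, seed = 17,
                      n_rep = 400, thin = 100)
  s <- as.vector(sim$samples)
  expect_equal(mean(s), 0.3 * (1 - 0.25), tolerance = 0.02)
  gp <- slm_stationary(p)
  ks <- suppressWarnings(
    stats::ks.test(s, stats::pgamma, shape = gp$shape, rate = gp$rate))
  expect_lt(unname(ks$statistic), 0.03)
  expect_equal(sim$n_reflected, 0L)
})

test_that("a coarse time step is flagged", {
  p <- slm_params(K = 0.3, sigma = 0.5)
  expect_warning(simulate_slm(p, dt = 2, n_steps = 5, burn_in = 0, seed = 1),
                 "dt >= tau")
})

test_that("f_max follows its closed form and limits", {
  expect_equal(f_max(s = 0.01, t = 100, N = 1e4), (exp(1) - 1) / 200)
  ## t -> 0 first-order expansion: t / (2N)
  expect_equal(f_max(s = 1e-3, t = 1e-4, N = 100), 1e-4 / 200, tolerance = 1e-6)
  fm <- vapply(c(10, 50, 100, 200), function(t) f_max(0.01, t, 1e4), numeric(1))
  expect_true(all(diff(fm) > 0))
  expect_warning(f_max(s = 0.1, t = 200, N = 10), "f_max > 1")
})

test_that("mutation-selection balance gammas have the documented moments", {
  neg <- evo_gamma_params(evo_params(N = 1e4, mu = 1e-5, s = -1e-3))
  expect_equal(neg$shape / neg$rate, 0.01)   # mean mu/|s|
  expect_equal(neg$shape, 2 * 1e4 * 1e-5)    # shape 2 N mu

  pos_par <- evo_params(N = 1e4, mu = 1e-5, s = 0.01, t = 100)
  pos <- evo_gamma_params(pos_par)
  fm <- f_max(0.01, 100, 1e4)
  expect_equal(pos$shape / pos$rate, 2 * 1e4 * 1e-5 * fm)  # mean 2 N mu f_max
  expect_equal(pos$shape, neg$shape)

  expect_error(evo_params(N = 1e4, mu = 1e-5, s = 0), "nonzero")
  expect_error(evo_params(N = 1e4, mu = 1e-5, s = 0.01), "requires the elapsed time")
})

test_that("the purifying-selection Langevin equation matches its gamma", {
  par <- evo_params(N = 1e3, mu = 5e-4, s = -0.05)
  sim <- simulate_evo_langevin(par, f0 = 0.01, dt = 0.2, n_steps = 50,
                               burn_in = 2000, seed = 23, n_rep = 500, thin = 50)
  s <- as.vector(sim$samples)
  expect_equal(mean(s), 5e-4 / 0.05, tolerance = 0.05)
  gp <- evo_gamma_params(par)
  ks <- suppressWarnings(
    stats::ks.test(s, stats::pgamma, shape = gp$shape, rate = gp$rate))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("without mutation the purifying trajectory decays toward zero", {
  par <- evo_params(N = 1e6, mu = 0, s = -0.1)
  sim <- simulate_evo_langevin(par, f0 = 0.05, dt = 0.1, n_steps = 1,
                               burn_in = 1000, seed = 3, n_rep = 50)
  expect_lt(mean(sim$samples), 0.001)
})

test_that("a beneficial allele grows exponentially while rare", {
  par <- evo_params(N = 1e9, mu = 0, s = 0.05, t = 1)
  steps <- 400L  # 40 generations at dt = 0.1
  sim <- simulate_evo_langevin(par, f0 = 0.001, dt = 0.1, n_steps = 1,
                               burn_in = steps, seed = 11, n_rep = 200)
  expect_equal(mean(sim$samples), 0.001 * exp(0.05 * 40), tolerance = 0.05)
})
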