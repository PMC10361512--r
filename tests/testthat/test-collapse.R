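test_that("rescaled log frequencies are standard scores", {
  set.seed(8)
  f <- rgamma(500, 1, 20)
  z <- pool_and_rescale(f)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("rescaling is invariant to multiplicative shifts of the frequencies", {
  set.seed(9)
  f <- rgamma(300, 2, 40)
  expect_equal(as.numeric(pool_and_rescale(f)),
               as.numeric(pool_and_rescale(0.37 * f)))
})

test_that("zeros are dropped with a count and too-few values error", {
  f <- c(0, 0, 0.01, 0.1, 0.5)
  expect_message(z <- pool_and_rescale(f), "2 zero frequencies")
  expect_equal(attr(z, "n_zero_dropped"), 2L)
  expect_length(z, 3L)
  expect_error(suppressMessages(pool_and_rescale(c(0, 0, 0.1))), "at least 2")
})

test_that("species drawn from one law collapse onto a common curve", {
  set.seed(10)
  ## same beta, very different mean scales
  z1 <- pool_and_rescale(rgamma(1e4, 1, rate = 1 / 0.01))
  z2 <- pool_and_rescale(rgamma(1e4, 1, rate = 1 / 0.2))
  ks <- suppressWarnings(stats::ks.test(z1, z2))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a frequency table with species ids is rescaled per species", {
  set.seed(11)
  df <- data.frame(species_id = rep(c("a", "b"), each = 200),
                   f = c(rgamma(200, 1, 50), rgamma(200, 2, 10)))
  z <- pool_and_rescale(df)
  for (sp in c("a", "b")) {
    expect_equal(mean(z$z[z$species_id == sp]), 0, tolerance = 1e-9)
    expect_equal(sd(z$z[z$species_id == sp]), 1, tolerance = 1e-9)
  }
})

test_that("the Gaussian family fit recovers its own parameters", {
  set.seed(12)
  v <- rnorm(1e5, -1.5, 0.6)
  fit <- fit_log_frequency_distribution(v, "lognormal")
  expect_equal(unname(fit$par["mean"]), -1.5, tolerance = 0.01)
  expect_equal(unname(fit$par["sd"]), 0.6, tolerance = 0.01)
  expect_equal(fit$k, 2L)
})

test_that("the loggamma family fit recovers the gamma shape", {
  set.seed(13)
  v <- log10(rgamma(1e5, 2, 20))
  fit <- fit_log_frequency_distribution(v, "gamma")
  expect_equal(unname(fit$par["shape"]), 2, tolerance = 0.1)
  ## the closed-form map fixes location and scale too
  expect_equal(unname(fit$par["scale"]), 1 / log(10), tolerance = 0.05)
  expect_equal(unname(fit$par["location"]), -log10(20), tolerance = 0.05)
  expect_equal(fit$k, 3L)
})

test_that("the fitted likelihood dominates perturbed parameter vectors", {
  set.seed(14)
  v <- log10(rgamma(2000, 1.5, 30))
  fit <- fit_log_frequency_distribution(v, "gamma")
  at <- function(shape, loc, scale)
    sum(gammaprev:::dloggamma(v, shape, loc, scale, log = TRUE))
  p <- fit$par
  for (bump in c(0.9, 1.1)) {
    expect_gte(fit$logL, at(p["shape"] * bump, p["location"], p["scale"]))
    expect_gte(fit$logL, at(p["shape"], p["location"] + 0.05 * (bump - 1) * 10, p["scale"] * bump))
  }
})

test_that("AIC comparison prefers fewer parameters at equal likelihood", {
  mk <- function(family, k, logL)
    structure(list(family = family, par = c(a = 1), logL = logL, k = k,
                   n = 100L, data_id = c(n = 100, mean = 0, var = 1)),
              class = "gp_fit")
  cmp <- aic_compare(list(mk("gamma", 3L, -500), mk("lognormal", 2L, -500)))
  expect_equal(attr(cmp, "winner"), "lognormal")
  expect_equal(attr(cmp, "margin"), 2)
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$logL)
  bad <- mk("lognormal", 2L, -400); bad$data_id["mean"] <- 5
  expect_error(aic_compare(list(mk("gamma", 3L, -500), bad)), "identical data")
})

test_that("AIC recovers the generating family in both directions", {
  set.seed(15)
  vg <- log10(rgamma(2e4, 1, 15))
  cg <- aic_compare(list(fit_log_frequency_distribution(vg, "gamma"),
                         fit_log_frequency_distribution(vg, "lognormal")))
  expect_equal(attr(cg, "winner"), "gamma")
  vl <- rnorm(2e4, -1.2, 0.5)
  cl <- aic_compare(list(fit_log_frequency_distribution(vl, "gamma"),
                         fit_log_frequency_distribution(vl, "lognormal")))
  expect_equal(attr(cl, "winner"), "lognormal")
})

test_that("survival curves step down through the sorted data", {
  sc <- survival_curve(c(4, 1, 3, 2))
  expect_equal(sc$value, 1:4)
  expect_equal(sc$survival, c(1, 0.75, 0.5, 0.25))

  set.seed(16)
  r <- survival_curve(rnorm(500))
  expect_true(all(diff(r$survival) < 0))
  expect_equal(r$survival[1], 1)

  tied <- survival_curve(c(1, 2, 2, 3))
  expect_equal(tied$value, c(1, 2, 3))
  expect_equal(tied$survival, c(1, 0.75, 0.25))
})
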