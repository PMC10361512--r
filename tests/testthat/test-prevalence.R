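test_that("site moments for prediction use all-host population moments", {
  fr <- freq_table(matrix(c(0.2, 0, 0, 0.2), ncol = 1))
  mom <- site_moments_for_prediction(fr)
  expect_equal(mom$fbar, 0.1)
  expect_equal(mom$var, 0.01)
  expect_equal(mom$beta, 1)
  expect_equal(mom$occupancy, 0.5)
})

test_that("degenerate sites are excluded from prediction moments", {
  fr <- freq_table(cbind(c(0.1, 0.1, 0.1),   # constant nonzero: zero variance
                         c(0, 0, 0),          # never detected
                         c(0.1, 0.3, 0)))
  expect_message(mom <- site_moments_for_prediction(fr), "zero-variance")
  expect_equal(mom$site_id, "s003")
})

test_that("moment estimates recover the gamma they were drawn from", {
  set.seed(41)
  f <- matrix(rgamma(500 * 50, shape = 2, rate = 2 / 0.05), nrow = 500)
  mom <- site_moments_for_prediction(freq_table(f))
  expect_equal(median(mom$beta), 2, tolerance = 0.1)
  expect_equal(median(mom$fbar), 0.05, tolerance = 0.05)
})

test_that("the read-count sampling pmf has its closed-form properties", {
  ## A = 0 reduces to (1 + D fbar / beta)^-beta; fbar D = 1, beta = 1 -> 1/2
  expect_equal(sampling_pmf(0, D = 20, fbar = 0.05, beta = 1), 0.5)
  ## normalization
  expect_lt(abs(sum(sampling_pmf(0:5000, D = 100, fbar = 0.05, beta = 2)) - 1),
            1e-10)
  expect_error(sampling_pmf(-1, 10, 0.1, 1), "nonnegative")
})

test_that("the sampling pmf agrees with the negative binomial oracle", {
  ## the gamma-Poisson mixture is a negative binomial with size beta and
  ## mean fbar * D; dnbinom is the independent reference
  grid <- expand.grid(D = c(20, 100, 400), fbar = c(0.01, 0.1), beta = c(0.5, 1, 5))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      a <- 0:30
      expect_equal(sampling_pmf(a, D, fbar, beta),
                   dnbinom(a, size = beta, mu = fbar * D), tolerance = 1e-12)
    })
  }
})

test_that("absence probability is the zero class and behaves in its limits", {
  expect_equal(absence_probability(0, 0.1, 1), 1)
  D <- c(20, 50, 200)
  for (d in D)
    expect_equal(absence_probability(d, 0.03, 2), sampling_pmf(0, d, 0.03, 2))
  ## strictly decreasing in D and fbar
  expect_true(all(diff(absence_probability(D, 0.03, 2)) < 0))
  expect_gt(absence_probability(50, 0.01, 2), absence_probability(50, 0.05, 2))
  ## beta -> Inf limit: Poisson absence exp(-D fbar)
  expect_equal(absence_probability(50, 0.05, 1e6), exp(-50 * 0.05),
               tolerance = 1e-4)
})

test_that("predicted prevalence matches hand arithmetic and limits", {
  expect_equal(predicted_prevalence(100, fbar = 0.05, beta = 1), 5 / 6)
  expect_equal(predicted_prevalence(rep(1e12, 5), 0.05, 1), 1, tolerance = 1e-6)
  expect_lt(predicted_prevalence(rep(50, 5), 1e-9, 1), 1e-6)
  expect_error(predicted_prevalence(numeric(0), 0.05, 1), "at least one host")
})

test_that("the truncated prediction honors the cutoff contract", {
  D <- c(25, 40, 80, 200)
  expect_equal(predicted_prevalence_truncated(D, 0.05, 1, A_cutoff = 1),
               predicted_prevalence(D, 0.05, 1))
  expect_lte(predicted_prevalence_truncated(D, 0.05, 1, A_cutoff = 10),
             predicted_prevalence(D, 0.05, 1))
  ## partial-sum oracle via the negative binomial CDF
  for (ac in c(2, 10)) {
    oracle <- 1 - mean(pnbinom(ac - 1, size = 1.5, mu = 0.07 * D))
    expect_equal(predicted_prevalence_truncated(D, 0.07, 1.5, ac), oracle,
                 tolerance = 1e-12)
  }
})

test_that("observed prevalence counts detected hosts", {
  expect_equal(observed_prevalence(c(0, 0.1, 0.3, 0)), 0.5)
  expect_equal(observed_prevalence(c(0, 0, 0)), 0)
  expect_equal(observed_prevalence(c(0.2, 0.9)), 1)
})

test_that("relative error is relative to the observation", {
  expect_equal(relative_error(0.5, 0.5), 0)
  expect_equal(relative_error(0.5, 0.25), 0.5)
  expect_equal(relative_error(0.2, 0.3), 0.5)
  expect_error(relative_error(0, 0.3), "undefined")
})

test_that("the mean-frequency prevalence curve is monotone and consistent", {
  D <- c(25, 40, 80)
  curve <- prevalence_curve(10^seq(-3, log10(0.3), length.out = 25),
                            beta = 1, D_by_host = D, A_cutoff = 10)
  expect_true(all(diff(curve$prevalence) >= 0))
  expect_lt(curve$prevalence[1], 1e-3)
  site_pred <- predicted_prevalence_truncated(D, curve$fbar[10], 1, 10)
  expect_equal(curve$prevalence[10], site_pred)
})

test_that("evaluate_prevalence scores sites against both prediction forms", {
  coh <- small_mixed_cohort()
  fr <- polarize(apply_detection_filter(coh$counts))
  rec <- suppressMessages(evaluate_prevalence(fr))
  expect_s3_class(rec, "prevalence_record")
  expect_true(all(rec$predicted <= rec$predicted_untruncated + 1e-12))
  expect_true(all(rec$observed > 0 & rec$observed <= 1))
  expect_true(all(rec$predicted >= 0 & rec$predicted <= 1))
  expect_equal(rec$epsilon, abs(rec$observed - rec$predicted) / rec$observed)
  expect_equal(attr(rec, "A_cutoff"), 10L)
})

test_that("prediction moments can come from ground truth instead of data", {
  coh <- small_mixed_cohort()
  fr <- apply_detection_filter(coh$counts, D_min = 1, A_cutoff = 1)
  rec <- suppressMessages(
    evaluate_prevalence(fr, moments = "truth", truth_sites = coh$truth_sites))
  m <- match(rec$site_id, coh$truth_sites$site_id)
  expect_equal(rec$fbar, coh$truth_sites$true_fbar[m])
  expect_error(evaluate_prevalence(fr, moments = "truth"), "truth_sites")
})
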