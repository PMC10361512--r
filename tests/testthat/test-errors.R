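test_that("error summaries report the inclusive fraction and log mean", {
  s <- error_summary(c(0.05, 0.5))
  expect_equal(s$fraction_le_threshold, 0.5)
  expect_equal(error_summary(0.1)$fraction_le_threshold, 1)  # <= is inclusive
  expect_equal(error_summary(c(0.01, 1.0))$mean_log10_error, -1)
  z <- error_summary(c(0, 0.1))
  expect_equal(z$n_zero_error, 1L)
  expect_equal(z$mean_log10_error, -1)
  expect_error(error_summary(numeric(0)), "no finite")
})

test_that("error distributions rescale to standard scores per species", {
  set.seed(51)
  df <- data.frame(species_id = rep(c("a", "b"), each = 100),
                   epsilon = c(rlnorm(100, -2, 1), rlnorm(100, -0.5, 0.3)))
  z <- rescale_error_distribution(df)
  for (sp in c("a", "b")) {
    expect_equal(mean(z$z[z$species_id == sp]), 0, tolerance = 1e-9)
    expect_equal(sd(z$z[z$species_id == sp]), 1, tolerance = 1e-9)
  }
  expect_error(rescale_error_distribution(c(0, 0.1)), "at least 2 positive")
})

test_that("prevalence binning sits on the identity line for perfect predictions", {
  set.seed(52)
  obs <- 10^runif(300, -2, 0)
  perfect <- data.frame(observed = obs, predicted = obs)
  b <- bin_observed_vs_predicted(perfect, n_bins = 10)
  expect_equal(b$median_predicted, b$median_observed)
  expect_true(all(b$n_sites >= 5))

  under <- data.frame(observed = obs, predicted = obs / 2)
  b2 <- bin_observed_vs_predicted(under, n_bins = 10)
  expect_equal(b2$median_predicted, b2$median_observed / 2)
})

test_that("sparse bins are dropped by the occupancy rule", {
  rec <- data.frame(observed = c(rep(0.011, 20), 0.5),
                    predicted = c(rep(0.011, 20), 0.4))
  b <- bin_observed_vs_predicted(rec, n_bins = 10, min_sites = 5)
  expect_false(any(b$n_sites < 5))
  expect_false(any(abs(b$median_observed - 0.5) < 1e-9))
})

test_that("a deterministic error-prevalence relation is detected", {
  obs <- 10^seq(-2, 0, length.out = 40)
  rec <- data.frame(observed = obs, epsilon = 1 / (1 + 10 * obs))
  res <- error_prevalence_correlation(rec, n_perm = 500, seed = 1)
  expect_lt(res$statistic, 0)
  expect_true(res$significant)
  expect_lt(res$statistic, res$null_lower)
})

test_that("degenerate correlation inputs are refused", {
  rec <- data.frame(observed = rep(0.5, 20), epsilon = runif(20))
  expect_error(error_prevalence_correlation(rec, n_perm = 50), "constant")
  small <- data.frame(observed = runif(5), epsilon = runif(5))
  expect_error(error_prevalence_correlation(small, n_perm = 50), "at least 10")
})

test_that("per-species correlations are returned when species are present", {
  set.seed(53)
  rec <- data.frame(species_id = rep(c("a", "b"), each = 50),
                    observed = 10^runif(100, -2, 0), epsilon = runif(100))
  res <- error_prevalence_correlation(rec, n_perm = 200, seed = 2)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$species_id, c("a", "b"))
})

test_that("the strain scan enforces its species and site rules", {
  set.seed(54)
  mk_rec <- function(sp, n, eps_scale) {
    data.frame(species_id = sp, observed = 10^runif(n, -2, 0),
               epsilon = rlnorm(n, log(eps_scale), 0.5))
  }
  rec <- do.call(rbind, lapply(1:6, function(i)
    mk_rec(paste0("sp", i), 80, 0.1 * i)))
  sf <- data.frame(species_id = paste0("sp", 1:6),
                   strain_fraction = seq(0.6, 0.1, length.out = 6))
  scan <- strain_structure_scan(rec, sf, thresholds = c(0.02, 0.1, 0.3),
                                n_perm = 100, seed = 3)
  expect_equal(nrow(scan), 3L)
  expect_true(all(scan$n_species <= 6))

  ## a species with only 9 sites above a threshold is excluded there
  rec9 <- rbind(rec, data.frame(species_id = "sp7",
                                observed = c(rep(0.35, 9), rep(0.001, 200)),
                                epsilon = rlnorm(209, -1, 0.5)))
  sf9 <- rbind(sf, data.frame(species_id = "sp7", strain_fraction = 0.9))
  scan9 <- strain_structure_scan(rec9, sf9, thresholds = c(0.3),
                                 n_perm = 50, seed = 4, min_sites = 10)
  scan9b <- strain_structure_scan(rec9, sf9, thresholds = c(0.3),
                                  n_perm = 50, seed = 4, min_sites = 9)
  expect_equal(scan9$n_species, scan9b$n_species - 1L)
  expect_false(isTRUE(all.equal(scan9$statistic, scan9b$statistic)))

  expect_error(strain_structure_scan(mk_rec("only", 50, 0.1), sf), "at least 5 species")
})

test_that("identical strain fractions leave the scan undefined, not significant", {
  set.seed(55)
  rec <- do.call(rbind, lapply(1:5, function(i)
    data.frame(species_id = paste0("sp", i), observed = 10^runif(60, -2, 0),
               epsilon = rlnorm(60, -1, 0.5))))
  sf <- data.frame(species_id = paste0("sp", 1:5), strain_fraction = 0.3)
  scan <- strain_structure_scan(rec, sf, thresholds = c(0.02, 0.1),
                                n_perm = 50, seed = 5)
  expect_true(all(is.na(scan$statistic)))
  expect_false(any(scan$significant, na.rm = TRUE))
})

test_that("ensembles with evo sites tied to strain absence show the scan trend", {
  ens <- suppressWarnings(generate_ensemble(
    cohort_spec(M = 182L, S_strain = 300L, S_evo = 500L),
    strain_fractions = seq(0.1, 0.65, length.out = 8), seed = 61))
  fr <- polarize(apply_detection_filter(ens$counts))
  recs <- do.call(rbind, lapply(split(fr, fr$species_id), function(d) {
    r <- suppressMessages(evaluate_prevalence(d, A_cutoff = 10, D_min = 20))
    r <- as.data.frame(unclass(r))
    r$species_id <- d$species_id[1]
    r
  }))
  scan <- strain_structure_scan(recs, ens$strain_fractions,
                                n_perm = 200, seed = 62)
  ## species with more strain structure carry fewer evolutionary alleles,
  ## hence lower mean error. Evolutionary alleles sit at low observed
  ## prevalence, so the anti-correlation lives at the low thresholds and
  ## washes out once those sites fall out of the threshold set.
  low <- scan$statistic[1:4]
  expect_true(all(is.finite(low)))
  expect_true(all(low < 0))
})
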