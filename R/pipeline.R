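#' Pipeline configuration
#'
#' A single configuration object governs every pipeline stage so that the
#' filters and resampling settings are stated once and logged with each
#' artifact.
#'
#' @param out_dir directory for stage artifacts (created if needed).
#' @param input optional path to an external count TSV; when `NULL` the
#'   `frequencies` stage consumes the `simulate` stage's output.
#' @param D_min minimum per-host depth (default 20).
#' @param A_cutoff minor-allele detection cutoff (default 10).
#' @param occupancy_min occupancy floor for the Taylor analysis (default
#'   0.35).
#' @param fbar_max mean-frequency ceiling for the Taylor fit (default 0.35).
#' @param n_bootstrap bootstrap resamples for the Taylor CI (default 10000).
#' @param n_perm permutations for the null windows (default 10000).
#' @param seed integer random seed used by every stochastic stage.
#' @param cohort a [cohort_spec()] for the `simulate` stage.
#' @param n_species number of species the `simulate` stage generates; with
#'   more than one, a multi-species ensemble with graded strain fractions
#'   is produced (needed by `strain-scan`).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL,
                            D_min = 20L, A_cutoff = 10L,
                            occupancy_min = 0.35, fbar_max = 0.35,
                            n_bootstrap = 10000L, n_perm = 10000L,
                            seed = 1L, cohort = cohort_spec(),
                            n_species = 1L) {
  assert_number(D_min, "D_min", lower = 1)
  assert_number(A_cutoff, "A_cutoff", lower = 1)
  assert_number(occupancy_min, "occupancy_min", lower = 0, upper = 1,
                strict_lower = TRUE)
  assert_number(fbar_max, "fbar_max", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(n_bootstrap, "n_bootstrap", lower = 1)
  assert_number(n_perm, "n_perm", lower = 1)
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(out_dir = out_dir, input = input, D_min = as.integer(D_min),
                 A_cutoff = as.integer(A_cutoff),
                 occupancy_min = occupancy_min, fbar_max = fbar_max,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 cohort = cohort, n_species = as.integer(n_species)),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "frequencies", "collapse", "taylor",
                     "prevalence", "errors", "strain-scan")

stage_artifact <- function(config, name) file.path(config$out_dir, name)

need_artifact <- function(config, name, produced_by) {
  path <- stage_artifact(config, name)
  if (!file.exists(path))
    stop_gp(sprintf("missing artifact '%s'; run stage '%s' first",
                    name, produced_by),
            "gammaprev_dependency_error")
  path
}

write_stage_log <- function(config, stage, extra = list()) {
  log <- c(list(stage = stage,
                package = "gammaprev",
                version = as.character(utils::packageVersion("gammaprev")),
                r_version = paste(R.version$major, R.version$minor, sep = "."),
                seed = config$seed,
                D_min = config$D_min, A_cutoff = config$A_cutoff,
                occupancy_min = config$occupancy_min,
                fbar_max = config$fbar_max,
                n_bootstrap = config$n_bootstrap, n_perm = config$n_perm,
                n_species = config$n_species),
           extra)
  yaml::write_yaml(log, stage_artifact(config, paste0(stage, "_log.yaml")))
}

#' Run one pipeline stage
#'
#' Executes a named stage of the analysis pipeline against the artifact
#' directory of `config`, writing its TSV outputs plus a YAML log recording
#' the configuration, seed and package version. Identical configuration and
#' seed produce byte-identical outputs. Stages consume the artifacts of
#' earlier stages and raise a dependency error naming the stage to run
#' first when one is missing.
#'
#' Stages: `simulate` (synthetic cohort or ensemble), `frequencies`
#' (detection filter + polarization), `collapse` (rescaled distributions and
#' gamma-vs-lognormal AIC), `taylor` (site moments, occupancy filter,
#' Taylor's Law fit), `prevalence` (per-site predictions and errors),
#' `errors` (error summaries and the error-prevalence permutation test),
#' `strain-scan` (cross-species strain-structure threshold scan; requires a
#' multi-species simulate).
#'
#' @param stage one of the stage names above.
#' @param config a [pipeline_config()].
#' @return invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config) {
  if (length(stage) != 1L || !stage %in% pipeline_stages)
    stop_gp(sprintf("unknown stage '%s'; expected one of: %s",
                    paste(stage, collapse = ","),
                    paste(pipeline_stages, collapse = ", ")),
            "gammaprev_usage_error")
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- switch(stage,
    simulate = stage_simulate(config),
    frequencies = stage_frequencies(config),
    collapse = stage_collapse(config),
    taylor = stage_taylor(config),
    prevalence = stage_prevalence(config),
    errors = stage_errors(config),
    `strain-scan` = stage_strain_scan(config))
  write_stage_log(config, stage)
  invisible(paths)
}

stage_simulate <- function(config) {
  spec <- config$cohort
  spec$seed <- config$seed
  spec$D_min <- config$D_min
  spec$A_cutoff <- config$A_cutoff
  if (config$n_species > 1L) {
    sfs <- seq(0.1, 0.6, length.out = config$n_species)
    ens <- generate_ensemble(spec, strain_fractions = sfs, seed = config$seed)
    counts <- ens$counts
    truth_sites <- ens$truth_sites
    truth_latent <- ens$truth_latent
    strain <- data.frame(species_id = ens$strain_fractions$species_id,
                         host_id = NA, has_strains = NA)
    strain_frac <- ens$strain_fractions
  } else {
    coh <- generate_cohort(spec)
    counts <- coh$counts
    truth_sites <- coh$truth_sites
    truth_latent <- coh$truth_latent
    strain_frac <- data.frame(
      species_id = coh$strain_structure$species_id[1],
      strain_fraction = mean(coh$strain_structure$has_strains))
    strain <- coh$strain_structure
  }
  p <- c(counts = stage_artifact(config, "counts.tsv"),
         truth_sites = stage_artifact(config, "ground_truth_sites.tsv"),
         truth_latent = stage_artifact(config, "latent_frequencies.tsv"),
         strain = stage_artifact(config, "strain_structure.tsv"),
         strain_frac = stage_artifact(config, "strain_fractions.tsv"))
  write_long_table(counts, p[["counts"]])
  write_long_table(truth_sites, p[["truth_sites"]])
  write_long_table(truth_latent, p[["truth_latent"]])
  if (config$n_species == 1L) write_long_table(strain, p[["strain"]])
  write_long_table(strain_frac, p[["strain_frac"]])
  p
}

stage_frequencies <- function(config) {
  counts <- if (!is.null(config$input)) {
    read_count_table(config$input)
  } else {
    read_count_table(need_artifact(config, "counts.tsv", "simulate"))
  }
  freqs <- apply_detection_filter(counts, config$D_min, config$A_cutoff)
  freqs <- polarize(freqs)
  p <- stage_artifact(config, "frequencies.tsv")
  write_long_table(freqs, p)
  p
}

stage_collapse <- function(config) {
  freqs <- read_frequency_table(need_artifact(config, "frequencies.tsv",
                                              "frequencies"))
  z <- pool_and_rescale(freqs)
  ztab <- if (is.data.frame(z)) z else
    data.frame(species_id = "all", z = as.numeric(z))
  logf <- log10(freqs$f[freqs$f > 0])
  fits <- list(fit_log_frequency_distribution(logf, "gamma"),
               fit_log_frequency_distribution(logf, "lognormal"))
  aic <- aic_compare(fits)
  aic$winner <- attr(aic, "winner")
  p <- c(z = stage_artifact(config, "collapse_z.tsv"),
         fits = stage_artifact(config, "collapse_fits.tsv"))
  write_long_table(ztab, p[["z"]])
  write_long_table(aic, p[["fits"]])
  p
}

stage_taylor <- function(config) {
  freqs <- read_frequency_table(need_artifact(config, "frequencies.tsv",
                                              "frequencies"))
  mom <- compute_site_moments(freqs)
  filt <- occupancy_filter(mom, config$occupancy_min)
  fit <- taylor_fit(filt, fbar_max = config$fbar_max,
                    n_bootstrap = config$n_bootstrap, seed = config$seed)
  p <- c(moments = stage_artifact(config, "site_moments.tsv"),
         fit = stage_artifact(config, "taylor_fit.tsv"))
  write_long_table(as.data.frame(unclass(mom)), p[["moments"]])
  write_long_table(data.frame(slope = fit$slope, intercept = fit$intercept,
                              ci_lower = fit$ci[1], ci_upper = fit$ci[2],
                              n_sites = fit$n_sites,
                              fbar_max = fit$fbar_max,
                              occupancy_min = config$occupancy_min,
                              n_bootstrap = fit$n_bootstrap),
                   p[["fit"]])
  p
}

stage_prevalence <- function(config) {
  freqs <- read_frequency_table(need_artifact(config, "frequencies.tsv",
                                              "frequencies"))
  by_sp <- if (!is.null(freqs$species_id)) split(freqs, freqs$species_id)
           else list(all = freqs)
  rec <- do.call(rbind, lapply(names(by_sp), function(sp) {
    r <- evaluate_prevalence(by_sp[[sp]], A_cutoff = config$A_cutoff,
                             D_min = config$D_min)
    r <- as.data.frame(unclass(r))
    if (nrow(r)) r$species_id <- sp
    r
  }))
  p <- stage_artifact(config, "prevalence.tsv")
  write_long_table(rec, p)
  p
}

stage_errors <- function(config) {
  rec <- utils::read.delim(need_artifact(config, "prevalence.tsv", "prevalence"),
                           stringsAsFactors = FALSE)
  summ <- error_summary(rec)
  cor_res <- error_prevalence_correlation(rec, n_perm = config$n_perm,
                                          seed = config$seed)
  p <- c(summary = stage_artifact(config, "error_summary.tsv"),
         correlation = stage_artifact(config, "error_correlation.tsv"))
  write_long_table(as.data.frame(summ), p[["summary"]])
  write_long_table(as.data.frame(unclass(cor_res)), p[["correlation"]])
  p
}

stage_strain_scan <- function(config) {
  rec <- utils::read.delim(need_artifact(config, "prevalence.tsv", "prevalence"),
                           stringsAsFactors = FALSE)
  sf <- utils::read.delim(need_artifact(config, "strain_fractions.tsv",
                                        "simulate"),
                          stringsAsFactors = FALSE)
  scan <- strain_structure_scan(rec, sf, n_perm = min(config$n_perm, 1000L),
                                seed = config$seed)
  p <- stage_artifact(config, "strain_scan.tsv")
  write_long_table(as.data.frame(unclass(scan)), p)
  p
}
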