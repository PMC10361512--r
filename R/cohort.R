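#' Specification of a synthetic cohort
#'
#' Describes the statistical structure of a synthetic across-host
#' allele-count cohort emulating processed gut-metagenome data: a majority
#' of "strain-backed" sites whose latent frequencies follow a per-site gamma
#' with a site-independent squared inverse CV, a minority of low-prevalence
#' "evolutionary" sites following mutation-selection balance, per-host
#' coverage from a discretized lognormal truncated at the depth floor, and
#' binomial (or Poisson) read sampling. Defaults follow the study
#' conditions: 182 hosts, detection at `D >= 20` and `A >= 10`, strain-site
#' mean frequencies log-uniform over `[1e-3, 0.35]` with `beta = 1`.
#'
#' @param M number of hosts (>= 2); default 182, the median cohort size.
#' @param S_strain number of strain-backed sites.
#' @param S_evo number of evolutionary (mutation-selection-balance) sites.
#' @param fbar_range range of strain-site mean frequencies; sampled
#'   log-uniformly.
#' @param beta squared inverse CV of strain-site frequencies (scalar, or one
#'   value per strain site).
#' @param evo an [evo_params()] object for the evolutionary sites; default
#'   purifying selection with `2 N mu = 0.1` and mean `mu/|s| = 0.01`.
#' @param coverage list with `meanlog`, `sdlog` of the lognormal depth
#'   distribution (median `exp(meanlog)` = 40 by default); depths are
#'   rounded and truncated to `D >= D_min`.
#' @param sampling read-sampling model, `"binomial"` (default) or
#'   `"poisson"`.
#' @param D_min minimum per-host depth (default 20).
#' @param A_cutoff minor-allele detection cutoff (default 10).
#' @param strain_fraction per-host probability of harboring strain
#'   structure, used for the ground-truth indicator (default 0.27, the
#'   median fraction across species).
#' @param prop_nonsyn fraction of sites labelled nonsynonymous (annotation
#'   only; default 1/3).
#' @param seed integer seed making [generate_cohort()] deterministic.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(M = 182L, S_strain = 1000L, S_evo = 300L,
                        fbar_range = c(1e-3, 0.35), beta = 1,
                        evo = evo_params(N = 5e4, mu = 1e-6, s = -1e-4),
                        coverage = list(meanlog = log(40), sdlog = 0.5),
                        sampling = c("binomial", "poisson"),
                        D_min = 20L, A_cutoff = 10L,
                        strain_fraction = 0.27,
                        prop_nonsyn = 1 / 3,
                        seed = 1L) {
  sampling <- match.arg(sampling)
  assert_number(M, "M", lower = 2)
  assert_number(S_strain, "S_strain", lower = 0)
  assert_number(S_evo, "S_evo", lower = 0)
  if (S_strain + S_evo == 0)
    stop_gp("empty cohort: S_strain and S_evo are both zero", "gammaprev_domain_error")
  if (length(fbar_range) != 2L || any(fbar_range <= 0) || any(fbar_range >= 1) ||
      fbar_range[1] > fbar_range[2])
    stop_gp("'fbar_range' must be an increasing pair inside (0, 1)",
            "gammaprev_domain_error")
  if (any(beta <= 0))
    stop_gp("'beta' must be positive", "gammaprev_domain_error")
  if (!(length(beta) %in% c(1L, S_strain)))
    stop_gp("'beta' must be scalar or one value per strain site",
            "gammaprev_domain_error")
  stopifnot(inherits(evo, "evo_params"))
  assert_number(D_min, "D_min", lower = 1)
  assert_number(A_cutoff, "A_cutoff", lower = 1)
  assert_number(strain_fraction, "strain_fraction", lower = 0, upper = 1)
  structure(list(M = as.integer(M), S_strain = as.integer(S_strain),
                 S_evo = as.integer(S_evo), fbar_range = fbar_range,
                 beta = beta, evo = evo, coverage = coverage,
                 sampling = sampling, D_min = as.integer(D_min),
                 A_cutoff = as.integer(A_cutoff),
                 strain_fraction = strain_fraction,
                 prop_nonsyn = prop_nonsyn, seed = as.integer(seed)),
            class = "cohort_spec")
}

## mean and variance of min(X, 1) for X ~ Gamma(shape, rate): the law the
## clipped latent frequencies actually follow
clipped_gamma_moments <- function(shape, rate) {
  p_hi <- stats::pgamma(1, shape, rate, lower.tail = FALSE)
  m1 <- (shape / rate) * stats::pgamma(1, shape + 1, rate) + p_hi
  m2 <- (shape * (shape + 1) / rate^2) * stats::pgamma(1, shape + 2, rate) + p_hi
  list(fbar = m1, var = pmax(m2 - m1^2, 0))
}

## lognormal depths, rounded, truncated below D_min by inverse-CDF sampling
r_depth <- function(n, coverage, D_min) {
  p0 <- stats::plnorm(D_min - 0.5, coverage$meanlog, coverage$sdlog)
  u <- stats::runif(n, p0, 1)
  pmax(round(stats::qlnorm(u, coverage$meanlog, coverage$sdlog)), D_min)
}

#' Generate a synthetic allele-count cohort
#'
#' Draws a seeded cohort per a [cohort_spec()]: latent per-host frequencies
#' for strain-backed sites come from `Gamma(beta, beta/fbar)` with the
#' site's mean frequency drawn log-uniformly; latent frequencies for
#' evolutionary sites come from the mutation-selection-balance gamma of
#' [evo_gamma_params()]. Latent draws above 1 are clipped to 1 (a warning
#' is raised if the clip probability exceeds 1% at any site). Read counts
#' are then sampled per host given the latent frequency and a lognormal
#' depth. The ground truth (site parameters, latent frequencies, per-host
#' strain-structure indicators) is returned alongside the counts to enable
#' parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements
#'   `counts` (long data frame: `site_id`, `gene_id`, `site_class`,
#'   `host_id`, `A`, `D`),
#'   `truth_sites` (`site_id`, `class` strain/evo, `true_fbar`, `true_beta`
#'   — the moments of the clipped latent law actually sampled — plus the
#'   `nominal_fbar`, `nominal_beta` of the unclipped gamma),
#'   `truth_latent` (`site_id`, `host_id`, `f_latent`), and
#'   `strain_structure` (`species_id`, `host_id`, `has_strains`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  M <- spec$M
  S <- spec$S_strain + spec$S_evo

  ## per-site true parameters
  fbar_strain <- 10^stats::runif(spec$S_strain,
                                 log10(spec$fbar_range[1]),
                                 log10(spec$fbar_range[2]))
  beta_strain <- rep_len(spec$beta, spec$S_strain)
  evo_gp <- if (spec$S_evo > 0) evo_gamma_params(spec$evo) else NULL
  true_fbar <- c(fbar_strain,
                 rep(if (spec$S_evo) evo_gp$shape / evo_gp$rate else numeric(0),
                     spec$S_evo))
  true_beta <- c(beta_strain,
                 rep(if (spec$S_evo) evo_gp$shape else numeric(0), spec$S_evo))
  site_class <- rep(c("strain", "evo"), c(spec$S_strain, spec$S_evo))

  ## clip-probability guard: the gamma has support above 1 but frequencies
  ## are bounded; defaults keep the clipped mass far below 1%
  clip_p <- stats::pgamma(1, shape = true_beta, rate = true_beta / true_fbar,
                          lower.tail = FALSE)
  if (any(clip_p > 0.01))
    warning(sum(clip_p > 0.01),
            " site(s) have > 1% latent gamma mass above f = 1 (clipped)")

  ## latent frequencies, sites x hosts
  f_lat <- matrix(stats::rgamma(S * M, shape = rep(true_beta, each = M),
                                rate = rep(true_beta / true_fbar, each = M)),
                  nrow = M, ncol = S)
  f_lat <- pmin(f_lat, 1)

  ## coverage and read sampling
  D <- matrix(r_depth(S * M, spec$coverage, spec$D_min), nrow = M, ncol = S)
  A <- if (spec$sampling == "binomial") {
    matrix(stats::rbinom(S * M, size = as.vector(D), prob = as.vector(f_lat)),
           nrow = M, ncol = S)
  } else {
    matrix(pmin(stats::rpois(S * M, as.vector(D) * as.vector(f_lat)),
                as.vector(D)),
           nrow = M, ncol = S)
  }

  site_id <- sprintf("site_%05d", seq_len(S))
  host_id <- sprintf("host_%03d", seq_len(M))
  gene_id <- sprintf("gene_%03d", (seq_len(S) - 1L) %/% 150L + 1L)
  syn_class <- ifelse(stats::runif(S) < spec$prop_nonsyn,
                      "nonsynonymous", "synonymous")

  counts <- data.frame(
    site_id = rep(site_id, each = M),
    gene_id = rep(gene_id, each = M),
    site_class = rep(syn_class, each = M),
    host_id = rep(host_id, times = S),
    A = as.integer(A), D = as.integer(D),
    stringsAsFactors = FALSE)

  clip_mom <- clipped_gamma_moments(true_beta, true_beta / true_fbar)
  truth_sites <- data.frame(site_id = site_id, class = site_class,
                            true_fbar = clip_mom$fbar,
                            true_beta = clip_mom$fbar^2 / clip_mom$var,
                            nominal_fbar = true_fbar, nominal_beta = true_beta,
                            stringsAsFactors = FALSE)
  truth_latent <- data.frame(site_id = rep(site_id, each = M),
                             host_id = rep(host_id, times = S),
                             f_latent = as.vector(f_lat),
                             stringsAsFactors = FALSE)
  strain_structure <- data.frame(
    species_id = "synthetic_species",
    host_id = host_id,
    has_strains = stats::rbinom(M, 1L, spec$strain_fraction),
    stringsAsFactors = FALSE)

  list(counts = counts, truth_sites = truth_sites,
       truth_latent = truth_latent, strain_structure = strain_structure,
       spec = spec)
}

#' Generate a multi-species synthetic ensemble
#'
#' Generates one cohort per species with species-specific strain-structure
#' fractions and evolutionary-site counts, for cross-species analyses such
#' as the strain-structure threshold scan. By default the proportion of
#' evolutionary sites decreases as the strain fraction increases, the
#' regime in which prediction error is expected to anti-correlate with
#' strain structure.
#'
#' @param base_spec a [cohort_spec()] providing shared settings.
#' @param strain_fractions numeric vector, one fraction per species.
#' @param S_evo integer vector of evolutionary-site counts per species;
#'   default `round(base_spec$S_evo * (1 - strain_fractions))`.
#' @param seed integer seed; per-species seeds are derived from it.
#' @return list with the combined long `counts`, `truth_sites`,
#'   `truth_latent` and `strain_fractions` tables, each carrying a
#'   `species_id` column; site and host ids are prefixed by species so they
#'   stay globally unique.
#' @export
generate_ensemble <- function(base_spec, strain_fractions,
                              S_evo = NULL, seed = 1L) {
  stopifnot(inherits(base_spec, "cohort_spec"))
  n_sp <- length(strain_fractions)
  if (n_sp < 2L)
    stop_gp("an ensemble needs at least 2 species", "gammaprev_domain_error")
  S_evo <- S_evo %||% pmax(round(base_spec$S_evo * (1 - strain_fractions)), 0L)
  species_id <- sprintf("species_%02d", seq_len(n_sp))
  parts <- lapply(seq_len(n_sp), function(i) {
    sp <- base_spec
    sp$strain_fraction <- strain_fractions[i]
    sp$S_evo <- as.integer(S_evo[i])
    sp$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    coh <- generate_cohort(sp)
    pre <- function(x) paste0(species_id[i], ":", x)
    coh$counts$site_id <- pre(coh$counts$site_id)
    coh$counts$host_id <- pre(coh$counts$host_id)
    coh$counts$species_id <- species_id[i]
    coh$truth_sites$site_id <- pre(coh$truth_sites$site_id)
    coh$truth_sites$species_id <- species_id[i]
    coh$truth_latent$site_id <- pre(coh$truth_latent$site_id)
    coh$truth_latent$host_id <- pre(coh$truth_latent$host_id)
    coh$truth_latent$species_id <- species_id[i]
    coh
  })
  list(counts = do.call(rbind, lapply(parts, `[[`, "counts")),
       truth_sites = do.call(rbind, lapply(parts, `[[`, "truth_sites")),
       truth_latent = do.call(rbind, lapply(parts, `[[`, "truth_latent")),
       strain_fractions = data.frame(species_id = species_id,
                                     strain_fraction = strain_fractions,
                                     S_evo = S_evo,
                                     stringsAsFactors = FALSE))
}

#' Apply the depth and minor-allele detection filter
#'
#' Converts read counts to detection-filtered frequencies: `f = A/D` where
#' the depth reaches `D_min` AND the alternate-allele count reaches
#' `A_cutoff`; otherwise the allele is recorded as undetected (`f = 0`).
#' The thresholds used are recorded as attributes so prediction steps can
#' match them.
#'
#' @param counts long count table with columns `site_id`, `host_id`, `A`,
#'   `D` (other columns are carried through).
#' @param D_min minimum total depth (default 20).
#' @param A_cutoff minimum alternate-read count (default 10).
#' @return long frequency table (`site_id`, `host_id`, `f`, `D`, plus any
#'   of `species_id`, `site_class` present in the input) with attributes
#'   `D_min` and `A_cutoff`.
#' @export
apply_detection_filter <- function(counts, D_min = 20L, A_cutoff = 10L) {
  require_columns(counts, c("site_id", "host_id", "A", "D"), "count table")
  assert_number(D_min, "D_min", lower = 1)
  assert_number(A_cutoff, "A_cutoff", lower = 1)
  detected <- counts$D >= D_min & counts$A >= A_cutoff
  out <- data.frame(site_id = counts$site_id, host_id = counts$host_id,
                    f = ifelse(detected, counts$A / counts$D, 0),
                    D = counts$D, stringsAsFactors = FALSE)
  for (extra in intersect(c("species_id", "site_class", "gene_id"), names(counts)))
    out[[extra]] <- counts[[extra]]
  attr(out, "D_min") <- as.integer(D_min)
  attr(out, "A_cutoff") <- as.integer(A_cutoff)
  out
}

#' Polarize sites by the across-host major allele
#'
#' Orients every site so that the tracked allele is the across-host minor
#' allele: if the mean frequency of a site across hosts exceeds 0.5, the
#' site is flipped (`f -> 1 - f`; when read counts are present,
#' `A -> D - A`). A site whose mean is exactly 0.5 is left unchanged.
#' The operation is idempotent.
#'
#' @param x a long frequency table (`site_id`, `host_id`, `f`) or count
#'   table (`site_id`, `host_id`, `A`, `D`).
#' @return `x` with flipped sites; attribute `n_flipped` records how many.
#' @export
polarize <- function(x) {
  require_columns(x, c("site_id", "host_id"), "table")
  has_counts <- all(c("A", "D") %in% names(x))
  f <- if (has_counts) ifelse(x$D > 0, x$A / x$D, 0) else x$f
  if (is.null(f)) stop_gp("need either 'f' or 'A'/'D' columns", "gammaprev_format_error")
  if (any(f < 0 | f > 1))
    stop_gp("frequencies must lie in [0, 1]", "gammaprev_domain_error")
  site_mean <- tapply(f, x$site_id, mean)
  flip_sites <- names(site_mean)[site_mean > 0.5]
  flip <- x$site_id %in% flip_sites
  if (has_counts) {
    x$A[flip] <- x$D[flip] - x$A[flip]
  }
  if (!is.null(x$f)) {
    x$f[flip] <- 1 - x$f[flip]
  }
  attr(x, "n_flipped") <- length(flip_sites)
  x
}
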