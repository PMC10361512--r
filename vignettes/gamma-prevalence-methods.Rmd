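---
title: "Methods: the gamma allele-frequency distribution and prevalence prediction across hosts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gamma allele-frequency distribution and prevalence prediction across hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaprev)
```

## The problem

Shotgun metagenomes sampled from many unrelated human hosts yield, for each
common gut species, a table of alternate-allele read counts $A$ and total
depths $D$ at polymorphic sites. Most intermediate-frequency variants in
these data are not segregating under within-host evolutionary dynamics:
they ride on the genomes of a few co-occurring *strains*, so an allele's
within-host frequency is the relative abundance of the strain carrying it.
`gammaprev` treats the across-host distribution of an allele's frequency as
a macroecological object — an abundance fluctuation distribution — and asks
how far a minimal model of strain ecology goes in predicting it.

## The model

The Stochastic Logistic Model (SLM) describes a strain's frequency $f$
through self-limiting growth with multiplicative environmental noise
(Itô convention):

$$\mathrm{d}f = \frac{f}{\tau}\Big(1 - \frac{f}{K}\Big)\,\mathrm{d}t
  + \sqrt{\frac{\sigma}{\tau}}\, f \,\mathrm{d}W,$$

with growth timescale $\tau$, carrying capacity $K \in (0,1)$ expressed as
a relative frequency, and growth-rate fluctuation scale $\sigma$. Its
stationary distribution is a gamma,

$$f \sim \mathrm{Gamma}\!\Big(\frac{2}{\sigma} - 1,\; \frac{2}{K\sigma}\Big)
  \qquad (\sigma < 2),$$

implemented in `slm_stationary()`. Writing $\bar f$ for the across-host
mean frequency and $\beta = \bar f^2 / \sigma_f^2$ for the squared inverse
coefficient of variation, the same law reads
$f \sim \mathrm{Gamma}(\beta, \beta/\bar f)$ (`gamma_from_moments()`).
Both $\bar f$ and $\beta$ are measurable from data, which is what makes the
downstream predictions *zero-free-parameter*: nothing is statistically
fitted.

### Sampling at finite depth

Sequencing observes $A$ reads out of $D$, binomially; for $D \gg 1$,
$f \ll 1$ this is Poisson with mean $fD$. Mixing the Poisson over the gamma
gives a negative-binomial-form sampling distribution (`sampling_pmf()`):

$$\Pr[A \mid D, \beta, \beta/\bar f] =
  \frac{\Gamma(\beta + A)}{A!\,\Gamma(\beta)}
  \Big(\frac{\bar f D}{\beta + \bar f D}\Big)^{A}
  \Big(\frac{\beta}{\beta + \bar f D}\Big)^{\beta},$$

whose zero class $(1 + D\bar f/\beta)^{-\beta}$ is the probability of
non-detection (`absence_probability()`). Averaging presence over the $M$
hosts' observed depths predicts prevalence (`predicted_prevalence()`), and
when the variant-calling pipeline only reports minor alleles supported by
at least $A_\mathrm{cutoff}$ reads, the truncated form
(`predicted_prevalence_truncated()`) sums the sampling distribution up to
the cutoff. The prediction is scored against the observed prevalence
(fraction of hosts with $f > 0$) by the relative error
$\varepsilon = |\hat\varrho - \langle\varrho\rangle| / \hat\varrho$.

### Evolutionary alternatives

Two linearized ($f \ll 1$) single-locus regimes of mutation, selection and
drift also yield gamma laws (`evo_gamma_params()`): purifying selection,
$\mathrm{Gamma}(2N\mu,\, 2N|s|)$ with mean $\mu/|s|$, and an ongoing sweep,
$\mathrm{Gamma}(2N\mu,\, 1/f_\mathrm{max})$ with
$f_\mathrm{max} = (e^{st}-1)/(2Ns)$. In both the shape — hence $\beta$ —
equals $2N\mu$. (Some textual statements of $\beta$ for these regimes
circulate as $1/(2N\mu)$ or $(2N\mu)^2$; the package follows the
distributions themselves, whose shape is $2N\mu$ in either case.) These
regimes supply the package's low-prevalence "evolutionary" site class: the
plausible contaminant of strain-driven data.

## Estimation conventions

* **Moments include zeros.** $\bar f$ and $\sigma_f^2$ are computed over
  all hosts, zeros included (`site_moments_for_prediction()`): under
  SLM-plus-sampling a zero is a sampling artifact of an always-present
  strain, and the macroecological moment convention this work builds on
  does the same. Nonzero-only moments are available via
  `include_zeros = FALSE`; whether the original analyses included zeros is
  not documented, so both routes exist and the zero-inclusive one is the
  default.
* **Population variance.** Moments divide by $n$, not $n-1$, so the
  Bhatia–Davis bound $\sigma_f^2 \le (1-\bar f)\bar f$ holds exactly for
  every bounded sample and is asserted on every row as an estimator
  self-check.
* **Polarization.** Sites whose across-host mean frequency exceeds $1/2$
  are flipped ($f \to 1-f$, $A \to D-A$); a mean of exactly $1/2$ is left
  unflipped, a deterministic tie-break. The operation is idempotent.
* **Host conditioning.** Hosts with depth below $D_\mathrm{min}$ are
  excluded from observed *and* predicted prevalence, keeping the two
  conditioned on the same host set.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `D_min` | 20 reads | minimum within-host depth for an observation |
| `A_cutoff` | 10 reads | minor-allele detection cutoff; drives the truncated prediction |
| occupancy floor | 0.35 | sites detected in fewer hosts are dropped before the Taylor fit (exclusion is strict `<`) |
| `fbar_max` | 0.35 | Taylor fit ceiling; above it the Bhatia–Davis bound, not a power law, governs the mean–variance relation |
| `n_bootstrap` | 10,000 | site-resampling percentile CI on the Taylor exponent |
| `n_perm` | 10,000 | permutation null windows (95% by 2.5/97.5 percentiles) |

The Taylor regression is ordinary least squares of $\log_{10}\sigma_f^2$ on
$\log_{10}\bar f$; no estimator was named for the original fit and OLS is
the transparent choice. The bootstrap resamples *sites*, since the quoted
uncertainty is across the site scatter. Distribution fits for the AIC
comparison are done on the log scale — a 3-parameter loggamma (shape,
location, scale) against a 2-parameter Gaussian — because the collapse
diagnostics examine $\log_{10} f$; the parameter counts are recorded so the
AIC ($2k - 2\log L$) is auditable. Whether to pool all species into one fit
or fit per species was left open by the source analyses; the package pools
by default and the per-species route is a `split()` away.

## The synthetic-cohort generator

`generate_cohort()` emulates the *processed product* of the upstream
pipeline (read mapping, likelihood-based frequency estimation, strain
inference are all out of scope), with defaults fixed at the study
conditions:

* $M = 182$ hosts (the median cohort size), strain-backed site means
  log-uniform on $[10^{-3}, 0.35]$ (about two and a half decades), constant
  $\beta = 1$ across sites — which is what makes Taylor's Law with exponent
  2 emerge;
* a minority of evolutionary sites drawn from the purifying-selection gamma
  with $N = 5\times10^4$, $\mu = 10^{-6}$, $s = -10^{-4}$, i.e. shape
  $2N\mu = 0.1$ and mean $\mu/|s| = 0.01$: strongly skewed, low-prevalence
  alleles, chosen once as a plausible mutation–selection-balance regime on
  the detectable frequency scale;
* per-host depths from a discretized lognormal with median 40 truncated at
  $D \ge 20$ (only the lower bound is documented for the real data; the
  median was chosen to make sampling noise non-trivial), and binomial read
  sampling (Poisson available to match the prediction's approximation
  regime);
* a per-host Bernoulli strain-structure indicator (default fraction 0.27,
  the median across species) as ground truth for the threshold scan —
  strain-backed generation is parameterized directly by $(\bar f, \beta)$
  rather than explicit haplotypes, because under the model an allele's
  frequency *is* its strain's frequency.

Latent gamma draws above 1 are clipped. With $\beta = 1$ the clip mass
reaches $e^{-1/0.35} \approx 5.7\%$ at the top of the default mean range,
so the generator warns whenever any site exceeds 1% clip mass — including
under its own defaults; this is a real feature of pushing an unbounded law
onto $[0,1]$, not a bug. The ground-truth table therefore records the
moments of the *clipped* law (closed form via incomplete gamma functions)
as `true_fbar`/`true_beta`, alongside the nominal unclipped values:
parameter-recovery checks must compare the estimator to the distribution
that was actually sampled.

What the generator does **not** emulate: sequencing error and the
likelihood machinery that absorbs it, linkage between sites (sites are
independent given their parameters), host-specific carrying capacities,
and real strain haplotype structure. Passing tests therefore show that the
pipeline's mathematics and code are right under the model's own
assumptions — not that the model is right about any particular real
dataset.

## Numerical choices

* **SDE integration.** Euler–Maruyama with default $\mathrm{d}t = \tau/100$
  and burn-in $50\tau$, justified by stationarity diagnostics in the tests
  (grid over $K \in \{0.05, 0.2, 0.5\}$, $\sigma \in \{0.2, 0.5, 1.0\}$:
  sample mean within 2% of $K(1-\sigma/2)$, KS distance to the analytic
  gamma below 0.02 at $10^5$ samples). Steps through zero reflect
  ($f \to |f|$) with counts reported. Excursions above 1 are *not* capped
  by default: the analytic stationary law is the unbounded gamma, and at
  $K = 0.5$, $\sigma = 1$ capping would truncate ~1.8% of its mass and
  bias the mean by about $-7\%$, which would defeat the simulator's purpose
  as a numerical oracle. `cap_at_one = TRUE` restores a strictly bounded
  path when one is wanted.
* **Log-space pmf.** The sampling distribution is evaluated via `lgamma`
  and `log1p`; it sums to 1 within $10^{-10}$ and matches the
  negative-binomial reference to $10^{-12}$.
* **Loggamma fitting.** Maximum likelihood over (shape, location, scale)
  with moment-matched multi-starts and an upper shape bound of $10^6$: the
  loggamma tends to a Gaussian as shape $\to \infty$, so on near-Gaussian
  data the ML solution sits at that boundary and is handled as such rather
  than reported as non-convergence.
* **Degenerate inputs.** All-zero sites and zero-variance sites are
  excluded from moment-based prediction with messages; relative error is
  undefined at zero observed prevalence and such sites are dropped;
  correlation tests refuse constant vectors; the strain scan reports a
  threshold as undefined when fewer than 3 species survive its
  10-site-per-species rule.

## Known limitations and honest wrinkles

* The zero-free-parameter prediction evaluated with moments re-estimated
  from *sampled, unfiltered* frequencies double-counts read-level noise:
  $\mathrm{Var}(A/D) = \sigma_f^2 + \bar f/D$ under Poisson sampling, which
  deflates $\hat\beta$ and the predicted prevalence at low $\bar f D$. The
  package's fidelity checks of the sampling theory therefore use the
  generator's ground-truth moments (`moments = "truth"`), while the
  data-moments route (`moments = "observed"`, the only route available on
  real data) is exercised by the mixed-cohort analyses, where the resulting
  underprediction at low prevalence is exactly the documented failure mode.
* The OLS Taylor exponent on latent constant-$\beta$ cohorts carries a
  small ($\sim -1.3\%$) systematic bias from moment-estimation noise at
  $M = 200$ and from clipping of high-mean sites; the 10,000-resample
  percentile CI is narrower than this bias at 5,000 sites, so the CI
  brackets the point estimate, not necessarily the nominal 2.
* In the synthetic ensembles, the anti-correlation between mean error and
  strain-structure fraction is strongest at *low* prevalence thresholds and
  decays as the threshold rises, because the low-prevalence evolutionary
  sites that carry the error signal leave the threshold set; with a
  handful of species the per-threshold permutation test has little power,
  mirroring how only a majority — not all — of the 22 real species reached
  significance.
* No time-dependent solutions $p(f, t)$, no zero-inflated (competitive
  exclusion) variant, and no strain-inference reimplementation: strain
  presence is an input (real data) or ground truth (synthetic).

## Problem sizes used by the test suite

The suite runs the full stage chain on a 6-species ensemble of 60 hosts
and 270 sites per species; the headline simulation checks use 5,000 sites
by 200 hosts (Taylor), $10^5$ post-burn-in SDE samples per grid cell,
$10^6$ Monte-Carlo draws for the sampling-pmf oracle, 2,000 sites by 500
hosts (parameter recovery), 500 replicates of 50 sites with 1,000
permutations each (null calibration), and $10^5$ values per AIC recovery
run. These sizes were chosen so each check's Monte-Carlo error is well
below the tolerance it asserts.
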