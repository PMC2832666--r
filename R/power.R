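# Statistical power for the additive quantitative-trait test, analytic
# (noncentral chi-square) and by simulation.

#' Analytic power of the additive quantitative-trait test
#'
#' The genotype explains `v = 2 p (1-p) beta^2` of the total phenotypic
#' variance `sigma^2`, giving noncentrality `lambda = n v / (sigma^2 - v)`
#' for the 1-df genotype test. Power is computed from the noncentral
#' F(1, n - 3) distribution of the regression F test (intercept + genotype +
#' sex covariate), whose large-n limit is the textbook noncentral chi-square
#' form `P(chisq_1(lambda) > chisq critical at alpha)`; the F form tracks the
#' finite-sample t test that the association module actually runs. `sigma` is
#' interpreted as the *total* phenotypic SD (so the residual variance is
#' `sigma^2 - v`).
#'
#' @param n Cohort size.
#' @param freq Effect-allele frequency, in (0, 1).
#' @param beta Per-allele effect in melanin units.
#' @param sigma Total phenotypic SD in melanin units.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in \[alpha, 1).
#' @examples
#' analytic_power(120, 0.20, 1.3, 3)  # ~0.78
#' @export
analytic_power <- function(n, freq, beta, sigma, alpha = 0.05) {
  msc_assert(freq > 0 && freq < 1, "freq must be in (0, 1)")
  msc_assert(sigma > 0 && alpha > 0 && alpha < 1, "bad sigma or alpha")
  v <- 2 * freq * (1 - freq) * beta^2
  msc_assert(v < sigma^2,
             "genetic variance meets or exceeds total phenotypic variance")
  lambda <- n * v / (sigma^2 - v)
  df2 <- n - 3  # intercept + genotype + sex covariate
  crit <- stats::qf(1 - alpha, 1, df2)
  stats::pf(crit, 1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Simulated power of the additive quantitative-trait test
#'
#' Monte-Carlo cross-check of [analytic_power()]: cohorts are drawn with
#' [simulate_cohort()] and the additive regression (sex covariate included)
#' is run on each; power is the rejection fraction at `alpha`.
#'
#' @inheritParams analytic_power
#' @param reps Number of replicate cohorts (>= 100).
#' @param seed Integer seed controlling all draws.
#' @return List: `power`, `mc_se` (binomial Monte-Carlo standard error),
#'   `reps`.
#' @export
simulated_power <- function(n, freq, beta, sigma, alpha = 0.05,
                            reps = 2000L, seed = 1L) {
  msc_assert(reps >= 100, "reps must be >= 100")
  set.seed(seed)
  rej <- 0L
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(n = n, freq = freq, beta = beta, sigma = sigma,
                           seed = sample.int(.Machine$integer.max, 1))
    res <- additive_regression(coh$genotypes, coh$phenotypes, "rs_sim1",
                               effect_allele = coh$genotypes$snps$allele_b)
    if (!is.na(res$p) && res$p < alpha) rej <- rej + 1L
  }
  list(power = rej / reps, mc_se = sqrt((rej / reps) * (1 - rej / reps) / reps),
       reps = reps)
}

#' Power grid over allele frequencies and effect sizes
#'
#' @inheritParams analytic_power
#' @param freqs,betas Grid values.
#' @return `data.frame`: `freq`, `beta`, `power` (analytic).
#' @export
power_grid <- function(freqs, betas, n = 120L, sigma = 3, alpha = 0.05) {
  grid <- expand.grid(freq = freqs, beta = betas)
  grid$power <- mapply(function(p, b) analytic_power(n, p, b, sigma, alpha),
                       grid$freq, grid$beta)
  grid
}
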