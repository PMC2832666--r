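# Quantitative-trait association of SNP genotypes with melanin index:
# additive and unconstrained (model-free) linear models with covariates,
# effective-test Bonferroni correction, cohort comparison and
# stratification diagnostics. Each SNP is tested marginally.

.assoc_frame <- function(gm, pheno, snp_id, covariates) {
  j <- match(snp_id, gm$snps$snp_id)
  msc_assert(!is.na(j), sprintf("unknown SNP '%s'", snp_id))
  idx <- match(pheno$sample_id, gm$samples)
  msc_assert(!anyNA(idx), "phenotype sample(s) missing from genotype matrix")
  df <- data.frame(melanin = pheno$melanin_index,
                   dose_b = gm$calls[idx, j])
  for (cv in covariates) {
    msc_assert(cv %in% names(pheno), sprintf("covariate '%s' not in phenotypes",
                                             cv))
    df[[cv]] <- pheno[[cv]]
  }
  list(df = df[complete.cases(df), , drop = FALSE], snp = gm$snps[j, ])
}

#' Additive-model association of a SNP with melanin index
#'
#' Ordinary least squares of melanin index on the count of the effect allele
#' (0/1/2) plus covariates (sex by default). The partial R-squared of the
#' genotype term is `(SSE_reduced - SSE_full) / SS_total`, the share of total
#' phenotypic variance explained by genotype given the covariates.
#'
#' @param gm A [genotype_matrix()].
#' @param pheno A [phenotype_table()] (or data.frame with `sample_id`,
#'   `melanin_index` and the covariate columns).
#' @param snp_id SNP to test.
#' @param effect_allele The allele whose copies are counted; one of the SNP's
#'   two alleles. Swapping it flips the sign of beta only.
#' @param covariates Phenotype columns used as covariates (default `"sex"`).
#' @param min_n Minimum complete cases (default 10).
#' @return `data.frame` of class `assoc_result` with `snp_id`, `model`,
#'   `effect_allele`, `beta`, `se`, `p`, `r2_partial`, `n_used` (`NA` fields
#'   plus a `reason` for monomorphic SNPs).
#' @export
additive_regression <- function(gm, pheno, snp_id, effect_allele,
                                covariates = "sex", min_n = 10L) {
  af <- .assoc_frame(gm, pheno, snp_id, covariates)
  df <- af$df
  msc_assert(nrow(df) >= min_n,
             sprintf("fewer than %d complete cases", min_n))
  msc_assert(effect_allele %in% c(af$snp$allele_a, af$snp$allele_b),
             "effect_allele is not one of the SNP's alleles")
  df$g <- if (effect_allele == af$snp$allele_b) df$dose_b else 2L - df$dose_b
  out <- data.frame(snp_id = snp_id, model = "additive",
                    effect_allele = effect_allele, beta = NA_real_,
                    se = NA_real_, p = NA_real_, r2_partial = NA_real_,
                    n_used = nrow(df), reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(unique(df$g)) < 2) {
    out$reason <- "monomorphic SNP in complete cases"
    class(out) <- c("assoc_result", "data.frame")
    return(out)
  }
  fml <- stats::reformulate(c("g", covariates), response = "melanin")
  fit <- lm(fml, data = df)
  cf <- summary(fit)$coefficients["g", ]
  red <- lm(stats::reformulate(c(covariates, "1"), response = "melanin"),
            data = df)
  sse_full <- sum(stats::residuals(fit)^2)
  sse_red <- sum(stats::residuals(red)^2)
  ss_tot <- sum((df$melanin - mean(df$melanin))^2)
  out$beta <- cf["Estimate"]; out$se <- cf["Std. Error"]
  out$p <- cf["Pr(>|t|)"]
  out$r2_partial <- (sse_red - sse_full) / ss_tot
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Unconstrained (model-free) association of a SNP with melanin index
#'
#' Two genotype indicator terms (heterozygote and non-reference homozygote)
#' against the reference homozygote, plus covariates. All three genotype
#' classes must be present with at least `min_class` members.
#'
#' @inheritParams additive_regression
#' @param ref_genotype Reference homozygote, `"aa"` (allele_a homozygote) or
#'   `"bb"`.
#' @param min_class Minimum members per genotype class (default 2).
#' @return `data.frame` of class `assoc_result` with per-term rows
#'   (`term` in `het`, `hom`): `beta`, `se`, `p`, plus `n_used`.
#' @export
unconstrained_regression <- function(gm, pheno, snp_id,
                                     ref_genotype = c("aa", "bb"),
                                     covariates = "sex", min_class = 2L) {
  ref_genotype <- match.arg(ref_genotype)
  af <- .assoc_frame(gm, pheno, snp_id, covariates)
  df <- af$df
  cls <- table(factor(df$dose_b, levels = 0:2))
  if (any(cls < min_class))
    stop(sprintf("genotype class(es) with fewer than %d members: %s",
                 min_class, paste(names(cls)[cls < min_class], collapse = ", ")),
         call. = FALSE)
  ref_dose <- if (ref_genotype == "aa") 0L else 2L
  hom_dose <- 2L - ref_dose
  df$het <- as.integer(df$dose_b == 1L)
  df$hom <- as.integer(df$dose_b == hom_dose)
  fml <- stats::reformulate(c("het", "hom", covariates), response = "melanin")
  fit <- lm(fml, data = df)
  cf <- summary(fit)$coefficients
  out <- data.frame(snp_id = snp_id, model = "unconstrained",
                    ref_genotype = ref_genotype,
                    term = c("het", "hom"),
                    beta = cf[c("het", "hom"), "Estimate"],
                    se = cf[c("het", "hom"), "Std. Error"],
                    p = cf[c("het", "hom"), "Pr(>|t|)"],
                    n_used = nrow(df), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Additive association scan over all SNPs
#'
#' Marginal additive tests per SNP (effect allele = `allele_b` throughout),
#' mirroring the per-marker beta / p-value report layout.
#'
#' @inheritParams additive_regression
#' @return `data.frame` with one row per SNP (monomorphic SNPs carry `NA`
#'   statistics and a reason).
#' @export
assoc_scan <- function(gm, pheno, covariates = "sex") {
  do.call(rbind, lapply(gm$snps$snp_id, function(s) {
    j <- match(s, gm$snps$snp_id)
    additive_regression(gm, pheno, s, gm$snps$allele_b[j], covariates)
  }))
}

#' Effective number of independent tests
#'
#' Greedy collapse of markers linked at `r^2 >=` the threshold: SNP pairs at
#' or above the threshold are merged into one cluster (transitively), and the
#' effective test count is the number of clusters.
#'
#' @param r2 Square symmetric r-squared matrix.
#' @param threshold Collapse threshold (default 0.99).
#' @return Integer number of effective tests.
#' @export
effective_tests <- function(r2, threshold = 0.99) {
  r2 <- as.matrix(r2)
  m <- nrow(r2)
  msc_assert(m == ncol(r2), "r2 matrix must be square")
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    if (!is.na(r2[i, j]) && r2[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

#' Bonferroni correction with an effective test count
#'
#' @param p P-value(s).
#' @param m_effective Effective number of independent tests (>= 1).
#' @return `min(1, p * m_effective)`.
#' @examples
#' bonferroni(0.002, 8)  # 0.016
#' @export
bonferroni <- function(p, m_effective) {
  msc_assert(m_effective >= 1, "m_effective must be >= 1")
  pmin(1, p * m_effective)
}

#' Chi-square comparison of allele counts between two samples
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' allele counts (alleles x samples); equals the squared two-proportion
#' z statistic. A warning is issued when any expected cell is below 1, in
#' which case Fisher's exact test on the same table is returned alongside.
#'
#' @param gc1,gc2 Genotype counts `c(n_aa, n_ab, n_bb)` for the two samples.
#' @return List: `chisq`, `df`, `p`, and `p_exact` (Fisher) when expected
#'   counts are small (`NA` otherwise).
#' @examples
#' allele_count_comparison(c(18, 62, 40), c(51, 86, 70))$p  # 0.255
#' @export
allele_count_comparison <- function(gc1, gc2) {
  gc1 <- .as_counts(gc1); gc2 <- .as_counts(gc2)
  tab <- rbind(sample1 = c(a = 2 * gc1[1] + gc1[2], b = 2 * gc1[3] + gc1[2]),
               sample2 = c(a = 2 * gc2[1] + gc2[2], b = 2 * gc2[3] + gc2[2]))
  msc_assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
             "both samples must be polymorphic")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - expd)^2 / expd)
  p_exact <- NA_real_
  if (any(expd < 1)) {
    warning("expected cell count below 1; Fisher's exact p also returned",
            call. = FALSE)
    p_exact <- stats::fisher.test(tab)$p.value
  }
  list(chisq = unname(chisq), df = 1L,
       p = pchisq(chisq, df = 1, lower.tail = FALSE), p_exact = p_exact)
}

#' Heterozygote excess/deficit stratification diagnostics
#'
#' Per SNP: observed minus HWE-expected heterozygote count, the exact HWE
#' p-value, and the direction of the deviation. A pooled sample drawn from
#' subpopulations with different allele frequencies shows a systematic
#' heterozygote deficit (Wahlund effect), so a cohort-level preponderance of
#' deficit-direction SNPs is a stratification warning sign.
#'
#' @param gm A [genotype_matrix()].
#' @return List: `per_snp` data.frame (`snp_id`, `obs_het`, `exp_het`,
#'   `het_excess`, `hwe_p`, `direction`) and `n_deficit`/`n_excess` totals.
#' @export
stratification_report <- function(gm) {
  cnt <- genotype_counts(gm)
  per <- do.call(rbind, lapply(seq_len(nrow(cnt)), function(i) {
    gc <- c(cnt$n_aa[i], cnt$n_ab[i], cnt$n_bb[i])
    if (sum(gc) == 0)
      return(data.frame(snp_id = cnt$snp_id[i], obs_het = NA, exp_het = NA,
                        het_excess = NA, hwe_p = NA, direction = NA))
    e <- hwe_expected(gc)
    data.frame(snp_id = cnt$snp_id[i], obs_het = gc[2],
               exp_het = unname(e[2]), het_excess = gc[2] - unname(e[2]),
               hwe_p = hwe_exact_test(gc),
               direction = if (gc[2] < e[2]) "deficit"
                           else if (gc[2] > e[2]) "excess" else "none",
               stringsAsFactors = FALSE)
  }))
  list(per_snp = per,
       n_deficit = sum(per$direction == "deficit", na.rm = TRUE),
       n_excess = sum(per$direction == "excess", na.rm = TRUE))
}
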