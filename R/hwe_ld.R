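# Hardy-Weinberg testing and two-locus EM linkage disequilibrium.

.as_counts <- function(gc) {
  if (is.list(gc) && !is.data.frame(gc))
    gc <- c(gc$n_aa, gc$n_ab, gc$n_bb)
  gc <- as.numeric(gc)
  msc_assert(length(gc) == 3 && all(gc >= 0) && all(gc == round(gc)),
             "genotype counts must be three non-negative integers (AA, AB, BB)")
  msc_assert(sum(gc) > 0, "genotype counts sum to zero")
  gc
}

#' Allele frequency from genotype counts
#'
#' @param gc Genotype counts `c(n_aa, n_ab, n_bb)` for homozygote A,
#'   heterozygote, homozygote B.
#' @param allele `"a"` or `"b"`.
#' @return The sample frequency `(2 n_aa + n_ab) / 2n` of allele A (or its
#'   complement for B).
#' @examples
#' allele_freq(c(18, 62, 40))        # 0.408 (A)
#' allele_freq(c(18, 62, 40), "b")   # 0.592 (G)
#' @export
allele_freq <- function(gc, allele = c("a", "b")) {
  allele <- match.arg(allele)
  gc <- .as_counts(gc)
  p <- (2 * gc[1] + gc[2]) / (2 * sum(gc))
  if (allele == "a") p else 1 - p
}

#' Expected genotype counts under Hardy-Weinberg equilibrium
#'
#' @inheritParams allele_freq
#' @return Numeric `c(n p^2, 2 n p q, n q^2)` with `p` the allele-A frequency;
#'   sums to `n` exactly.
#' @examples
#' hwe_expected(c(18, 62, 40))  # 20.01 57.98 42.01
#' @export
hwe_expected <- function(gc) {
  gc <- .as_counts(gc)
  n <- sum(gc)
  p <- allele_freq(gc)
  setNames(n * c(p^2, 2 * p * (1 - p), (1 - p)^2),
           c("exp_aa", "exp_ab", "exp_bb"))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts compatible with the allele counts (same parity) are
#' enumerated, and the p-value is the sum of the conditional probabilities of
#' every configuration no more probable than the observed one (the standard
#' probability-ordered tail; no mid-p correction).
#'
#' @inheritParams allele_freq
#' @return Exact p-value in (0, 1]; monomorphic samples give 1.
#' @examples
#' hwe_exact_test(c(18, 62, 40))  # 0.571
#' hwe_exact_test(c(51, 86, 70))  # 0.024
#' @export
hwe_exact_test <- function(gc) {
  gc <- .as_counts(gc)
  n <- sum(gc)
  n_a <- 2 * gc[1] + gc[2]
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2, rare, by = 2)
  # log conditional probability of each heterozygote count given allele counts
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - rare - hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(gc[2], hets)]
  # tolerance absorbs floating-point ties between equal-probability tails
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Table of observed/expected genotype frequencies and HWE exact p
#'
#' One row per SNP of a [genotype_matrix()], mirroring the usual candidate-gene
#' report layout (observed counts, HWE-expected counts, allele frequencies,
#' exact p-value).
#'
#' @param gm A [genotype_matrix()].
#' @return `data.frame` with one row per SNP.
#' @export
hwe_table <- function(gm) {
  cnt <- genotype_counts(gm)
  res <- lapply(seq_len(nrow(cnt)), function(i) {
    gc <- c(cnt$n_aa[i], cnt$n_ab[i], cnt$n_bb[i])
    if (sum(gc) == 0)
      return(data.frame(exp_aa = NA, exp_ab = NA, exp_bb = NA,
                        freq_a = NA, freq_b = NA, hwe_p = NA))
    e <- hwe_expected(gc)
    data.frame(exp_aa = e[1], exp_ab = e[2], exp_bb = e[3],
               freq_a = allele_freq(gc), freq_b = allele_freq(gc, "b"),
               hwe_p = hwe_exact_test(gc))
  })
  cbind(cnt, do.call(rbind, res))
}

# ---- two-locus EM ----------------------------------------------------------

#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased diploid genotypes. All genotype classes except the double
#' heterozygote are phase-unambiguous; the EM iterates the expected split of
#' double heterozygotes between the AB/ab and Ab/aB resolutions. The start
#' point is linkage equilibrium (product of the allele-frequency marginals),
#' so the run is deterministic; the log-likelihood is non-decreasing.
#'
#' @param geno_a,geno_b Integer vectors of 0/1/2 counts of the "B-side" allele
#'   at each locus (e.g. columns of `gm$calls`). Individuals missing at either
#'   locus are excluded (pairwise-complete).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @return Object of class `hap_freqs`: list with `f` (named frequencies of
#'   haplotypes AB, Ab, aB, ab, where "A"/"B" denote the 0-coded alleles),
#'   `loglik`, `n_iter`, `converged`, `n`.
#' @export
em_hap_freqs <- function(geno_a, geno_b, tol = 1e-8, max_iter = 10000L) {
  keep <- !is.na(geno_a) & !is.na(geno_b)
  ga <- as.integer(geno_a[keep]); gb <- as.integer(geno_b[keep])
  n <- length(ga)
  msc_assert(n > 0, "no pairwise-complete individuals")
  msc_assert(all(ga %in% 0:2) && all(gb %in% 0:2), "genotypes must be 0/1/2")
  # 3x3 genotype table; index [i+1, j+1] = counts of B-allele copies (i, j)
  tab <- matrix(0, 3, 3)
  for (k in seq_len(n)) tab[ga[k] + 1L, gb[k] + 1L] <-
      tab[ga[k] + 1L, gb[k] + 1L] + 1
  pa <- 1 - (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * n)  # freq of A (0-coded)
  pb <- 1 - (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * n)
  f <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  # haplotype pairs contributed by each unambiguous genotype class:
  # counts of (AB, Ab, aB, ab) haplotypes, double het handled separately
  fixed <- c(AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
             Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
             aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
             ab = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3])
  n_dh <- tab[2, 2]
  loglik_fun <- function(f) {
    probs <- c(f["AB"]^2, 2 * f["AB"] * f["Ab"], f["Ab"]^2,
               2 * f["AB"] * f["aB"],
               2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"]),
               2 * f["Ab"] * f["ab"],
               f["aB"]^2, 2 * f["aB"] * f["ab"], f["ab"]^2)
    obs <- c(tab[1, 1], tab[1, 2], tab[1, 3], tab[2, 1], tab[2, 2], tab[2, 3],
             tab[3, 1], tab[3, 2], tab[3, 3])
    sum(obs[obs > 0] * log(probs[obs > 0]))
  }
  ll <- loglik_fun(f)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    d_cis <- f["AB"] * f["ab"]
    d_trans <- f["Ab"] * f["aB"]
    w <- if (d_cis + d_trans > 0) d_cis / (d_cis + d_trans) else 0.5
    hap <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- hap / (2 * n)
    names(f_new) <- names(f)
    ll_new <- loglik_fun(f_new)
    f <- f_new
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  structure(list(f = f, loglik = unname(ll), n_iter = iter,
                 converged = converged, n = n),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat("two-locus haplotype frequencies (EM):\n")
  print(round(x$f, 4))
  cat(sprintf("loglik %.4f after %d iteration(s); n = %d\n",
              x$loglik, x$n_iter, x$n))
  invisible(x)
}

#' r-squared linkage disequilibrium from haplotype frequencies
#'
#' `D = f_AB - p_A p_B`; `r^2 = D^2 / (p_A q_A p_B q_B)`. Returns `NA` when a
#' marginal is monomorphic.
#'
#' @param hf A [em_hap_freqs()] result, or a numeric vector of haplotype
#'   frequencies `c(AB, Ab, aB, ab)`.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
ld_r2 <- function(hf) {
  f <- if (inherits(hf, "hap_freqs")) hf$f else as.numeric(hf)
  msc_assert(length(f) == 4 && all(f >= -1e-12),
             "need four non-negative haplotype frequencies")
  msc_assert(abs(sum(f) - 1) < 1e-6, "haplotype frequencies must sum to 1")
  pa <- f[1] + f[2]
  pb <- f[1] + f[3]
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  d <- f[1] - pa * pb
  unname(d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Pairwise r-squared LD matrix for a set of SNPs
#'
#' EM-based `r^2` for every marker pair, pairwise-complete individuals.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_ids SNPs to include (default all).
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
ld_matrix <- function(gm, snp_ids = gm$snps$snp_id) {
  idx <- match(snp_ids, gm$snps$snp_id)
  msc_assert(!anyNA(idx), "unknown snp id in ld_matrix")
  m <- length(idx)
  out <- diag(1, m)
  dimnames(out) <- list(snp_ids, snp_ids)
  if (m < 2) return(out)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    r2 <- ld_r2(em_hap_freqs(gm$calls[, idx[i]], gm$calls[, idx[j]]))
    out[i, j] <- out[j, i] <- r2
  }
  out
}
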