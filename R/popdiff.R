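# Per-SNP differentiation (FST, LSBL) and windowed diversity statistics
# (S, pi, Tajima's D, lnRH) with genome-wide empirical p-values.
#
# Caveat documented rather than corrected: array-ascertained SNP panels bias
# absolute pi/S, but the genome-wide empirical calibration of the scan
# absorbs a uniform ascertainment shift.

#' Construct per-population allele counts
#'
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param counts SNPs x populations matrix of allele-b copy counts.
#' @param totals SNPs x populations matrix of typed chromosomes (2n).
#' @return Object of class `pop_allele_counts`.
#' @export
pop_allele_counts <- function(snps, counts, totals) {
  counts <- as.matrix(counts); totals <- as.matrix(totals)
  msc_assert(all(dim(counts) == dim(totals)), "counts/totals dims differ")
  msc_assert(nrow(counts) == nrow(snps), "counts rows != snps rows")
  msc_assert(all(totals > 0), "totals (2n) must be positive")
  msc_assert(all(counts >= 0 & counts <= totals), "counts outside [0, 2n]")
  msc_assert(!is.null(colnames(counts)), "counts must have population names")
  rownames(counts) <- rownames(totals) <- snps$snp_id
  colnames(totals) <- colnames(counts)
  structure(list(snps = as.data.frame(snps), counts = counts, totals = totals),
            class = "pop_allele_counts")
}

#' @export
print.pop_allele_counts <- function(x, ...) {
  cat(sprintf("pop_allele_counts: %d SNPs x %d populations (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' Pairwise FST per SNP
#'
#' Hudson estimator (default):
#' `[(p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1)] / [p1 q2 + p2 q1]`
#' with `n` the number of typed chromosomes. `wc84` gives the Weir-Cockerham
#' theta for allele-count (haploid-sample) data. Small negative estimates are
#' reported as computed; clamping happens only inside [lsbl()].
#'
#' @param pac A [pop_allele_counts()].
#' @param pops Length-2 character vector of population names.
#' @param estimator `"hudson"` or `"wc84"`.
#' @return `data.frame` with columns `snp_id`, `fst` (`NA` where either
#'   population has fewer than 2 typed chromosomes or the SNP is monomorphic
#'   across both).
#' @export
pairwise_fst <- function(pac, pops, estimator = c("hudson", "wc84")) {
  estimator <- match.arg(estimator)
  msc_assert(length(pops) == 2 && all(pops %in% colnames(pac$counts)),
             "pops must name two populations present in the panel")
  n1 <- pac$totals[, pops[1]]; n2 <- pac$totals[, pops[2]]
  p1 <- pac$counts[, pops[1]] / n1; p2 <- pac$counts[, pops[2]] / n2
  fst <- if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ifelse(den > 0, num / den, NA_real_)
  } else {
    nt <- n1 + n2
    nc <- (nt - (n1^2 + n2^2) / nt)  # r - 1 = 1 divides out below
    pbar <- (n1 * p1 + n2 * p2) / nt
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
    den <- msp + (nc - 1) * msg
    ifelse(den > 0, (msp - msg) / den, NA_real_)
  }
  fst[n1 <= 1 | n2 <= 1] <- NA_real_
  data.frame(snp_id = pac$snps$snp_id, fst = unname(fst),
             stringsAsFactors = FALSE)
}

#' Locus-specific branch lengths from three pairwise distances
#'
#' Decomposes pairwise FST distances among populations a, b, c into
#' population-specific branch lengths:
#' `lsbl_a = (d_ab + d_ac - d_bc) / 2` (cyclically for b and c). Inputs are
#' clamped to \[0, 1\] first (negative FST estimates become 0); negative
#' *branch lengths* are reported as computed. The reconstruction identity
#' `lsbl_a + lsbl_b = d_ab` holds exactly.
#'
#' @param d_ab,d_ac,d_bc Numeric vectors of pairwise FST values.
#' @return `data.frame` with columns `lsbl_a`, `lsbl_b`, `lsbl_c` (`NA`
#'   rows where any input distance is missing).
#' @export
lsbl <- function(d_ab, d_ac, d_bc) {
  cl <- function(d) pmin(pmax(d, 0), 1)
  d_ab <- cl(d_ab); d_ac <- cl(d_ac); d_bc <- cl(d_bc)
  data.frame(lsbl_a = (d_ab + d_ac - d_bc) / 2,
             lsbl_b = (d_ab + d_bc - d_ac) / 2,
             lsbl_c = (d_ac + d_bc - d_ab) / 2)
}

#' Per-SNP LSBL scan over a three-population panel
#'
#' @param pac A [pop_allele_counts()] with at least the three named pops.
#' @param pops Length-3 character vector (a, b, c); branch `lsbl_a` measures
#'   differentiation specific to the first one.
#' @inheritParams pairwise_fst
#' @return `data.frame`: `snp_id`, `chrom`, `pos`, the three pairwise FST
#'   values and the three branch lengths.
#' @export
lsbl_scan <- function(pac, pops, estimator = c("hudson", "wc84")) {
  estimator <- match.arg(estimator)
  msc_assert(length(pops) == 3, "lsbl_scan needs three populations")
  d_ab <- pairwise_fst(pac, pops[c(1, 2)], estimator)$fst
  d_ac <- pairwise_fst(pac, pops[c(1, 3)], estimator)$fst
  d_bc <- pairwise_fst(pac, pops[c(2, 3)], estimator)$fst
  cbind(pac$snps[c("snp_id", "chrom", "pos")],
        fst_ab = d_ab, fst_ac = d_ac, fst_bc = d_bc,
        lsbl(d_ab, d_ac, d_bc))
}

#' Sliding genomic windows
#'
#' Windows of fixed size anchored at multiples of `step` from coordinate 0
#' (0-based half-open), restricted to windows fully inside the span. A span
#' shorter than one window yields a single truncated-coverage window starting
#' at the step-floor of the span start.
#'
#' @param span Length-2 numeric, 0-based half-open `(start, end)`.
#' @param size Window size in bp (default 100000).
#' @param step Offset between consecutive window starts (default 25000).
#' @return `data.frame` with columns `start`, `end`.
#' @export
sliding_windows <- function(span, size = 100000L, step = 25000L) {
  msc_assert(size > 0 && step > 0, "size and step must be positive")
  msc_assert(length(span) == 2 && span[1] < span[2], "bad span")
  first <- step * floor(span[1] / step)
  starts <- if (span[2] - size < first) first  # span shorter than one window
            else seq.int(first, span[2] - size, by = step)
  data.frame(start = as.integer(starts), end = as.integer(starts + size))
}

#' Windowed diversity statistics for one population
#'
#' Per SNP, the unbiased expected heterozygosity is
#' `h = 2n/(2n-1) * 2 p (1-p)` with `2n` typed chromosomes. Per window:
#' `S` = number of segregating SNPs, `pi` = sum of `h` over SNPs, `H_mean` =
#' mean of `h`, the lnRH diversity estimator `theta_hat = (1/(1-H_mean))^2 - 1`,
#' and Tajima's D computed from `S`, `pi` and the window's minimum typed
#' chromosome count (a conservative choice when sample size varies by SNP).
#' Windows with fewer than `min_snps` typed SNPs are returned with `NA`
#' statistics.
#'
#' @param pac A [pop_allele_counts()].
#' @param pop Population name.
#' @param windows `data.frame` from [sliding_windows()] (0-based half-open).
#' @param min_snps Minimum typed SNPs for a window to be scored (default 10).
#' @return `data.frame`, one row per window: `start`, `end`, `n_snps`, `S`,
#'   `pi`, `H_mean`, `theta_hat`, `tajima_d`.
#' @export
window_diversity <- function(pac, pop, windows, min_snps = 10L) {
  msc_assert(pop %in% colnames(pac$counts), "unknown population")
  pos0 <- pac$snps$pos - 1L  # to 0-based
  p <- pac$counts[, pop] / pac$totals[, pop]
  n2 <- pac$totals[, pop]
  h <- (n2 / (n2 - 1)) * 2 * p * (1 - p)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    in_w <- pos0 >= windows$start[i] & pos0 < windows$end[i]
    k <- sum(in_w)
    if (k < min_snps)
      return(data.frame(start = windows$start[i], end = windows$end[i],
                        n_snps = k, S = NA_integer_, pi = NA_real_,
                        H_mean = NA_real_, theta_hat = NA_real_,
                        tajima_d = NA_real_))
    hw <- h[in_w]
    S <- sum(p[in_w] > 0 & p[in_w] < 1)
    pi <- sum(hw)
    H_mean <- mean(hw)
    theta_hat <- (1 / (1 - H_mean))^2 - 1
    td <- if (S >= 1) tajimas_d(S, pi, min(n2[in_w])) else NA_real_
    data.frame(start = windows$start[i], end = windows$end[i], n_snps = k,
               S = S, pi = pi, H_mean = H_mean, theta_hat = theta_hat,
               tajima_d = td)
  })
  do.call(rbind, out)
}

#' Tajima's D
#'
#' Standardized difference between pairwise diversity and the
#' segregating-sites estimator, using the standard constants for a sample of
#' `n_chrom` chromosomes:
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`.
#'
#' @param S Number of segregating sites (>= 1).
#' @param pi Sum of per-site pairwise diversity over the same sites.
#' @param n_chrom Number of sampled chromosomes (>= 4).
#' @return Tajima's D (scalar; vectorized over `S`/`pi`).
#' @export
tajimas_d <- function(S, pi, n_chrom) {
  msc_assert(all(n_chrom >= 4), "Tajima's D needs at least 4 chromosomes")
  k <- tajima_constants(n_chrom)
  d <- (pi - S / k["a1"]) / sqrt(k["e1"] * S + k["e2"] * S * (S - 1))
  out <- unname(d)
  out[S < 1] <- NA_real_
  out
}

#' Tajima's D normalizing constants
#'
#' @param n_chrom Number of sampled chromosomes.
#' @return Named numeric vector `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n_chrom) {
  n <- n_chrom
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Log ratio of heterozygosity-based diversity estimators (lnRH)
#'
#' For each population, mean expected heterozygosity `H` is converted to the
#' diversity estimator `theta_hat = (1/(1-H))^2 - 1`; lnRH is
#' `log(theta_1 / theta_2)`. Any constant factor applied to both estimators
#' cancels, so the literature's factor-of-1/2 variant gives identical values.
#'
#' @param h1,h2 Mean expected heterozygosities (each `< 1`).
#' @param h_floor Heterozygosities below this floor give `NA` (default 0.001).
#' @return lnRH (vectorized); positive values mean pop 1 is more diverse.
#' @export
lnrh <- function(h1, h2, h_floor = 0.001) {
  msc_assert(all(h1 < 1, na.rm = TRUE) && all(h2 < 1, na.rm = TRUE),
             "heterozygosities must be < 1")
  th <- function(h) (1 / (1 - h))^2 - 1
  out <- log(th(h1) / th(h2))
  out[is.na(h1) | is.na(h2) | h1 < h_floor | h2 < h_floor] <- NA_real_
  out
}

#' lnRH scan between two populations over shared windows
#'
#' @inheritParams window_diversity
#' @param pops Length-2 character vector; lnRH is
#'   `log(theta_pop1 / theta_pop2)`, so diversity *loss* in pop 1 gives
#'   negative values.
#' @return `data.frame`: window bounds, per-pop `H_mean`, `lnrh`.
#' @export
lnrh_scan <- function(pac, pops, windows, min_snps = 10L, h_floor = 0.001) {
  w1 <- window_diversity(pac, pops[1], windows, min_snps)
  w2 <- window_diversity(pac, pops[2], windows, min_snps)
  data.frame(start = w1$start, end = w1$end,
             H_mean_1 = w1$H_mean, H_mean_2 = w2$H_mean,
             lnrh = lnrh(w1$H_mean, w2$H_mean, h_floor))
}

#' Genome-wide empirical p-value
#'
#' Literal rank formula `PE(x) = (#values > x) / N` for the upper tail
#' (`< x` for the lower tail); ties are excluded by the strict inequality and
#' there is no +1 smoothing, so the most extreme value has p = 0.
#'
#' @param x Observed statistic(s).
#' @param dist Numeric vector: the genome-wide empirical distribution
#'   (missing values dropped).
#' @param tail `"upper"` or `"lower"`.
#' @return Empirical p-value(s) in \[0, 1\].
#' @export
empirical_p <- function(x, dist, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  dist <- dist[!is.na(dist)]
  msc_assert(length(dist) > 0, "empirical distribution is empty")
  sorted <- sort(dist)
  n <- length(sorted)
  # counts via binary search on the sorted distribution
  if (tail == "upper") {
    gt <- n - findInterval(x, sorted)          # values strictly greater
    # findInterval counts <= x; strictly greater = n - (#<= x)
    gt / n
  } else {
    lt <- findInterval(x, sorted, left.open = TRUE)
    # with left.open, counts values strictly < x
    lt / n
  }
}

#' Per-region counts of significant markers or windows
#'
#' Mirrors the usual per-gene summary triple: counts of markers with empirical
#' p below tiered thresholds. Default `"exclusive"` bins report
#' `(#p < t1, #p in [t1, t2), #p in [t2, t3))`; `"cumulative"` reports
#' `(#p < t1, #p < t2, #p < t3)`.
#'
#' @param p Empirical p-values.
#' @param chrom,pos Genomic coordinates of each p-value (`pos` 1-based for
#'   point markers; pass window midpoints for window statistics).
#' @param regions A [region_set()].
#' @param thresholds Increasing significance tiers (default 0.001, 0.01, 0.05).
#' @param mode `"exclusive"` or `"cumulative"`.
#' @return `data.frame`: one row per region with `n_markers` and one count
#'   column per threshold.
#' @export
region_significance_counts <- function(p, chrom, pos, regions,
                                       thresholds = c(0.001, 0.01, 0.05),
                                       mode = c("exclusive", "cumulative")) {
  mode <- match.arg(mode)
  msc_assert(!is.unsorted(thresholds, strictly = TRUE),
             "thresholds must be increasing")
  pos0 <- pos - 1L
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    in_r <- chrom == r$chrom & pos0 >= r$start & pos0 < r$end & !is.na(p)
    pv <- p[in_r]
    cum <- vapply(thresholds, function(t) sum(pv < t), numeric(1))
    counts <- if (mode == "cumulative") cum else c(cum[1], diff(cum))
    stats::setNames(
      data.frame(name = r$name, n_markers = length(pv), t(counts)),
      c("name", "n_markers", paste0("n_p", seq_along(thresholds))))
  })
  do.call(rbind, out)
}
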