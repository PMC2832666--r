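make_pac <- function(counts, totals, pos = NULL) {
  counts <- as.matrix(counts); totals <- as.matrix(totals)
  if (is.null(pos)) pos <- seq_len(nrow(counts)) * 1000L
  pop_allele_counts(
    data.frame(snp_id = paste0("s", seq_len(nrow(counts))), chrom = "chr1",
               pos = as.integer(pos), stringsAsFactors = FALSE),
    counts, totals)
}

test_that("Hudson FST: fixed difference gives 1, identical frequencies ~0", {
  pac <- make_pac(cbind(A = c(200L, 0L), B = c(0L, 100L)),
                  cbind(A = c(200L, 200L), B = c(200L, 200L)))
  f <- pairwise_fst(pac, c("A", "B"))$fst
  expect_equal(f[1], 1)
  pac0 <- simulate_panel(3000, fst = c(A = 0, B = 0), n_chrom = 200, seed = 31)
  expect_lt(abs(mean(pairwise_fst(pac0, c("A", "B"))$fst, na.rm = TRUE)), 0.005)
})

test_that("Hudson FST calibrates on a Balding-Nichols panel at F = 0.10", {
  # 5,000 SNPs, 2n = 200 per population, both pops at F = 0.10 from the
  # shared ancestral frequency. The panel-level (ratio-of-sums) Hudson
  # estimate is the calibrated quantity; the mean of per-SNP ratios is a
  # known downward-biased average and is only sanity-bounded here.
  pac <- simulate_panel(5000, fst = c(A = 0.1, B = 0.1), n_chrom = 200,
                        seed = 32)
  n1 <- pac$totals[, 1]; n2 <- pac$totals[, 2]
  p1 <- pac$counts[, 1] / n1; p2 <- pac$counts[, 2] / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_lt(abs(sum(num) / sum(den) - 0.10), 0.01)
  per_snp <- pairwise_fst(pac, c("A", "B"))$fst
  expect_gt(mean(per_snp, na.rm = TRUE), 0.07)
  expect_lt(mean(per_snp, na.rm = TRUE), 0.11)
  # Weir-Cockerham variant agrees to first order on the same panel
  wc <- pairwise_fst(pac, c("A", "B"), "wc84")$fst
  expect_lt(abs(mean(wc, na.rm = TRUE) - mean(per_snp, na.rm = TRUE)), 0.03)
})

test_that("LSBL arithmetic, symmetry and exact reconstruction identity", {
  expect_equal(lsbl(0.3, 0.2, 0.1)$lsbl_a, 0.2)
  d <- 0.24
  br <- lsbl(d, d, d)
  expect_equal(unlist(br, use.names = FALSE), rep(d / 2, 3))
  set.seed(33)
  d_ab <- runif(200); d_ac <- runif(200); d_bc <- runif(200)
  br <- lsbl(d_ab, d_ac, d_bc)
  expect_equal(br$lsbl_a + br$lsbl_b, d_ab)
  expect_equal(br$lsbl_a + br$lsbl_c, d_ac)
})

test_that("LSBL attributes drift to the drifting branch", {
  pac <- simulate_panel(2000, fst = c(A = 0.15, B = 0, C = 0), n_chrom = 200,
                        seed = 34)
  sc <- lsbl_scan(pac, c("A", "B", "C"))
  # only pop A drifts (F = 0.15), so each pairwise FST involving A is ~F/2
  # and the A branch absorbs it: expected lsbl_a ~ 0.075, others ~ 0
  expect_gt(mean(sc$lsbl_a, na.rm = TRUE), 5 * abs(mean(sc$lsbl_b, na.rm = TRUE)))
  expect_gt(mean(sc$lsbl_a, na.rm = TRUE), 0.04)
  expect_lt(abs(mean(sc$lsbl_c, na.rm = TRUE)), 0.02)
})

test_that("sliding windows anchor at step multiples and cover interiors 4x", {
  w <- sliding_windows(c(0, 200000))
  expect_equal(w$start, seq(0L, 100000L, 25000L))
  expect_true(all(w$end - w$start == 100000L))
  w1 <- sliding_windows(c(0, 1e6))
  covering <- sum(w1$start <= 130000 & w1$end > 130000)
  expect_equal(covering, 4L)
  # span shorter than one window: single truncated-coverage window at 0
  ws <- sliding_windows(c(0, 60000))
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$start, 0L)
})

test_that("window diversity: hand-checked heterozygosity and monomorphic case", {
  pac <- make_pac(cbind(A = c(50L, 0L, 100L)), cbind(A = rep(100L, 3)),
                  pos = c(10L, 20L, 30L))
  w <- data.frame(start = 0L, end = 100L)
  d <- window_diversity(pac, "A", w, min_snps = 1)
  # single segregating SNP at p = 0.5, 2n = 100: h = (100/99) * 0.5
  expect_equal(d$S, 1L)
  expect_equal(d$pi, (100 / 99) * 0.5, tolerance = 1e-12)
  pac0 <- make_pac(cbind(A = c(0L, 0L)), cbind(A = c(100L, 100L)),
                   pos = c(10L, 20L))
  d0 <- window_diversity(pac0, "A", w, min_snps = 1)
  expect_equal(d0$S, 0L)
  expect_equal(d0$pi, 0)
  # below min_snps: masked
  expect_true(is.na(window_diversity(pac0, "A", w, min_snps = 5)$pi))
})

test_that("Tajima's D matches an independent constants oracle", {
  expect_equal(tajimas_d(5, 3.0, 10), oracle_tajima_d(5, 3.0, 10),
               tolerance = 1e-10)
  set.seed(35)
  for (i in 1:20) {
    n <- sample(4:80, 1); S <- sample(1:60, 1); pi <- runif(1, 0, S)
    expect_equal(tajimas_d(S, pi, n), oracle_tajima_d(S, pi, n),
                 tolerance = 1e-10)
  }
  k <- tajima_constants(10)
  expect_equal(tajimas_d(5, 5 / k[["a1"]], 10), 0)
})

test_that("Tajima's D is centred near 0 on neutral coalescent samples", {
  set.seed(20100305)
  d <- replicate(1000, {
    s <- oracle_coalescent_sfs(20, theta = 5)
    if (s["S"] < 1) NA_real_ else tajimas_d(s[["S"]], s[["pi"]], 20)
  })
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})

test_that("lnRH: zero at equal diversity, antisymmetric, hand value", {
  expect_equal(lnrh(0.37, 0.37), 0)
  expect_equal(lnrh(0.42, 0.19), -lnrh(0.19, 0.42))
  expect_equal(round(lnrh(0.5, 0.25), 4), 1.3499)
  expect_true(is.na(lnrh(0.0005, 0.3)))
})

test_that("empirical p-values follow the literal strict-count formula", {
  dist <- 1:100
  expect_equal(empirical_p(50, dist, "upper"), 0.50)
  expect_equal(empirical_p(100, dist, "upper"), 0)
  expect_equal(empirical_p(1, dist, "lower"), 0)
  # ties excluded by strict inequality: enumeration on a small tied list
  tied <- c(1, 2, 2, 2, 3, 5)
  for (x in c(0.5, 1, 2, 3, 4, 5, 6)) {
    expect_equal(empirical_p(x, tied, "upper"), sum(tied > x) / length(tied))
    expect_equal(empirical_p(x, tied, "lower"), sum(tied < x) / length(tied))
  }
})

test_that("empirical p of a distribution against itself is near-uniform", {
  set.seed(36)
  vals <- rnorm(2000)
  p <- empirical_p(vals, vals, "upper")
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("region significance counts bin as tiers, exclusive or cumulative", {
  regions <- region_set(c("hit", "empty"), "chr1", c(0L, 1000L), c(100L, 2000L))
  p <- c(0.0005, 0.005, 0.04, 0.5)
  pos <- c(10L, 20L, 30L, 40L)
  ex <- region_significance_counts(p, rep("chr1", 4), pos, regions)
  expect_equal(unlist(ex[1, c("n_p1", "n_p2", "n_p3")], use.names = FALSE),
               c(1, 1, 1))
  expect_equal(unlist(ex[2, c("n_p1", "n_p2", "n_p3")], use.names = FALSE),
               c(0, 0, 0))
  cu <- region_significance_counts(p, rep("chr1", 4), pos, regions,
                                   mode = "cumulative")
  expect_equal(unlist(cu[1, c("n_p1", "n_p2", "n_p3")], use.names = FALSE),
               c(1, 2, 3))
})
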