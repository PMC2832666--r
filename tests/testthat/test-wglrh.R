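test_that("core haplotype enumeration counts, filters and warns", {
  hs <- hs_from_matrix(matrix(1L, 10, 4))
  ch <- core_haplotypes(hs, 1:2)
  expect_equal(nrow(ch$patterns), 1L)
  expect_equal(ch$patterns$freq, 1.0)

  m <- rbind(matrix(0L, 6, 3), matrix(1L, 4, 3))
  ch2 <- core_haplotypes(hs_from_matrix(m), 2)
  expect_equal(sort(ch2$patterns$freq), c(0.4, 0.6))

  m3 <- rbind(matrix(0L, 6, 3), matrix(1L, 2, 3))  # minor pattern: 2 carriers
  ch3 <- core_haplotypes(hs_from_matrix(m3), 1, min_carriers = 3)
  expect_equal(nrow(ch3$patterns), 1L)
  expect_warning(core_haplotypes(hs_from_matrix(m3[7:8, , drop = FALSE]), 1),
                 "below min_carriers")
})

test_that("EHH is 1 at the core and on fully identical carriers", {
  hs <- hs_from_matrix(matrix(rep(c(0L, 1L), each = 5 * 6), ncol = 6))
  ch <- core_haplotypes(hs, 3)
  curve <- ehh(hs, ch$carriers[[1]], 3, "right")
  expect_equal(curve$ehh[1], 1)           # at the core
  expect_true(all(curve$ehh == 1))        # identical carriers everywhere
})

test_that("EHH equals the brute-force pair-counting oracle exactly", {
  for (seed in 1:12) {
    hs <- random_hs(n_hap = sample(6:14, 1), n_snp = sample(6:10, 1),
                    seed = seed)
    core <- sample(2:(ncol(hs$haps) - 1), 1)
    ch <- suppressWarnings(core_haplotypes(hs, core, min_carriers = 2))
    if (nrow(ch$patterns) == 0) next
    carriers <- ch$carriers[[1]]
    if (length(carriers) < 2) next
    for (dir in c("right", "left")) {
      curve <- ehh(hs, carriers, core, dir, stop_ehh = 0)
      for (k in which(!is.na(curve$marker))) {
        cols <- if (dir == "right") (core + 1):curve$marker[k]
                else curve$marker[k]:(core - 1)
        expect_equal(curve$ehh[k], oracle_ehh(hs$haps, carriers, cols),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("EHH curves are non-increasing outward and permutation-invariant", {
  for (seed in 13:20) {
    hs <- random_hs(16, 9, seed = seed)
    ch <- suppressWarnings(core_haplotypes(hs, 5, min_carriers = 2))
    if (nrow(ch$patterns) < 2) next
    curve <- ehh(hs, ch$carriers[[1]], 5, "right", stop_ehh = 0)
    expect_true(all(diff(curve$ehh) <= 1e-12))
    r0 <- rehh(hs, ch, 1)$rehh
    set.seed(seed + 100)
    perm <- sample(nrow(hs$haps))
    hsp <- hs_from_matrix(hs$haps[perm, ])
    chp <- suppressWarnings(core_haplotypes(hsp, 5, min_carriers = 2))
    tp <- match(ch$patterns$pattern[1], chp$patterns$pattern)
    expect_equal(rehh(hsp, chp, tp)$rehh, r0)
  }
})

test_that("REHH arithmetic on constructed fixtures", {
  # target carriers identical, others split 2/2 at the flank:
  # pooled EHH = (2*1 + 2*1) / (4*3) = 1/3, target EHH = 1 -> REHH = 3
  m <- rbind(
    cbind(1L, 1L, matrix(0L, 4, 1)),           # 4 target carriers: identical
    cbind(0L, c(0L, 0L, 1L, 1L), matrix(0L, 4, 1)))
  hs <- hs_from_matrix(m[, c(3, 1, 2)])        # core at col 2, flank col 3
  ch <- core_haplotypes(hs, 2, min_carriers = 2)
  tgt <- which(ch$patterns$pattern == "1")
  r <- rehh(hs, ch, tgt)
  expect_equal(r$rehh_right, 3)
  # identically homozygous target and others -> REHH 1
  m2 <- rbind(matrix(c(1L, 0L, 0L), 4, 3, byrow = TRUE),
              matrix(0L, 4, 3))
  hs2 <- hs_from_matrix(m2)
  ch2 <- core_haplotypes(hs2, 1, min_carriers = 2)
  r2 <- rehh(hs2, ch2, 1)
  expect_equal(r2$rehh, 1)
})

test_that("gamma MLE recovers known parameters and rejects degeneracy", {
  set.seed(41)
  x <- rgamma(5000, shape = 2, scale = 3)
  fit <- gamma_fit(x)
  expect_gt(fit$shape, 1.9); expect_lt(fit$shape, 2.1)
  expect_gt(fit$scale, 2.85); expect_lt(fit$scale, 3.15)
  expect_error(gamma_fit(rep(2.5, 50)), "degenerate")
  # monotone upper tail: larger observation, smaller p
  expect_lt(gamma_p(max(x), fit), gamma_p(stats::median(x), fit))
})

test_that("derived filter applies the strict > 0.60 cutoff", {
  mk <- function(n_derived) {
    m <- cbind(c(rep(1L, n_derived), rep(0L, 100 - n_derived)),
               rbinom(100, 1, 0.5))
    hs_from_matrix(m)
  }
  set.seed(42)
  hs61 <- mk(61)
  ch <- core_haplotypes(hs61, 1)
  t1 <- which(ch$patterns$pattern == "1")
  expect_true(derived_filter(hs61, ch, t1)$pass)

  hs60 <- mk(60)
  ch60 <- core_haplotypes(hs60, 1)
  t60 <- which(ch60$patterns$pattern == "1")
  expect_false(derived_filter(hs60, ch60, t60)$pass)  # 0.60 is not > 0.60

  hs_na <- mk(61)
  hs_na$ancestral_code[1] <- NA_integer_
  chn <- core_haplotypes(hs_na, 1)
  res <- derived_filter(hs_na, chn, which(chn$patterns$pattern == "1"))
  expect_false(res$pass)
  expect_match(res$reason, "unknown")
})

test_that("Benjamini-Hochberg adjustment matches hand arithmetic", {
  out <- bh_fdr(c(0.01, 0.02, 0.03))
  expect_equal(out$q_bh, c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.041)$q_bh, 0.041)
  expect_false(any(bh_fdr(rep(1, 5))$significant))
})

test_that("neutral haplotypes are flagged at no more than the FDR level", {
  n_sig <- 0L; n_cores <- 0L
  for (sd in 1:3) {
    hn <- simulate_sweep(n_markers = 41, span = 4e5, pop_size = 200, s = 0,
                         rec = 0.001, init_freq = 0.3, generations = 40,
                         sample_size = 60, seed = 50 + sd)
    res <- wglrh_test(hn, tile_cores(hn, 1, 2))
    n_sig <- n_sig + sum(res$significant)
    n_cores <- n_cores + nrow(res)
  }
  rate <- n_sig / n_cores
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_cores))
})
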