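# Small fixtures built in code.

# Genotype matrix with a single SNP from an explicit vector of 0/1/2 calls.
gm_from_calls <- function(calls, allele_a = "A", allele_b = "G",
                          ancestral = NA_character_, snp_id = "rs_test") {
  genotype_matrix(
    sprintf("S%03d", seq_along(calls)),
    data.frame(snp_id = snp_id, chrom = "chr1", pos = 100L,
               allele_a = allele_a, allele_b = allele_b,
               ancestral = ancestral, stringsAsFactors = FALSE),
    matrix(as.integer(calls), ncol = 1))
}

# Genotype matrix from Table-2-style genotype counts (n_aa, n_ab, n_bb).
gm_from_counts <- function(gc, ...) {
  gm_from_calls(rep(c(0L, 1L, 2L), times = gc), ...)
}

# Small multi-SNP genotype matrix with missing data and ancestral states.
toy_gm <- function() {
  snps <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = "chr15", pos = c(100L, 2500L, 9000L),
    allele_a = c("A", "C", "T"), allele_b = c("G", "T", "C"),
    ancestral = c("A", NA, "C"), stringsAsFactors = FALSE)
  calls <- matrix(c(0L, 1L, 2L, 1L,
                    2L, NA, 0L, 1L,
                    1L, 1L, NA, 0L), nrow = 4)
  genotype_matrix(paste0("S", 1:4), snps, calls)
}

# Haplotype set from an explicit matrix.
hs_from_matrix <- function(m, positions = NULL, ancestral_code = NULL) {
  m <- as.matrix(m)
  if (is.null(positions)) positions <- seq_len(ncol(m)) * 1000L
  if (is.null(ancestral_code)) ancestral_code <- rep(0L, ncol(m))
  haplotype_set(m, "chr1", positions, ancestral_code = ancestral_code)
}

# Random haplotype fixture for property tests.
random_hs <- function(n_hap = 12, n_snp = 8, seed = 1) {
  set.seed(seed)
  hs_from_matrix(matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.8)),
                        nrow = n_hap))
}

write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Matched sweep / neutral-control pair used by the haplotype detectors.
# World stated once: hard sweep from a single copy (classic positive
# control), strong selection s = 0.15 in a diploid population of 200,
# 61 markers with rec 0.001 per interval, sampled at 60 haplotypes when
# the derived allele reaches frequency 0.7 (incomplete sweep, where
# long-range haplotype tests have power); the control is the same world
# with s = 0 run for the matched number of generations.
sweep_pair <- function(seed) {
  hs <- simulate_sweep(n_markers = 61, span = 5e5, pop_size = 200, s = 0.15,
                       rec = 0.001, init_freq = 1 / 400, stop_freq = 0.7,
                       sample_size = 60, seed = seed)
  hn <- simulate_sweep(n_markers = 61, span = 5e5, pop_size = 200, s = 0,
                       rec = 0.001, init_freq = 1 / 400,
                       generations = length(attr(hs, "trajectory")),
                       sample_size = 60, seed = seed + 5000L)
  list(sweep = hs, neutral = hn)
}

# Window diversity statistics straight from a haplotype sample.
hap_window_stats <- function(hs, idx) {
  p <- colMeans(hs$haps[, idx, drop = FALSE])
  n <- nrow(hs$haps)
  h <- n / (n - 1) * 2 * p * (1 - p)
  S <- sum(p > 0 & p < 1)
  c(D = if (S > 0) tajimas_d(S, sum(h), n) else NA_real_, H = mean(h))
}
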