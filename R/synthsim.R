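# Seeded synthetic-data generators for every input the pipeline consumes.
# Each generator is a pure function of its arguments plus the seed.

#' Simulate a genotype-phenotype cohort
#'
#' Genotypes at one biallelic SNP drawn under Hardy-Weinberg equilibrium at
#' the stated effect-allele frequency; melanin index built as
#' `mu + genetic value + sex effect + residual noise`, with the residual SD
#' chosen so the *total* phenotypic SD equals `sigma`. The genetic value of
#' genotype g is `beta * g` plus optional dominance offsets. Defaults mirror
#' a light-skinned East Asian cohort (melanin index mean 31, SD 3).
#'
#' @param n Cohort size.
#' @param freq Effect-allele (allele_b) frequency.
#' @param beta Per-allele effect in melanin units.
#' @param het_offset,hom_offset Dominance deviations added to the genetic
#'   value of heterozygotes (`beta + het_offset`) and effect-allele
#'   homozygotes (`2 beta + hom_offset`).
#' @param mu Phenotype mean (default 31).
#' @param sigma Total phenotype SD (default 3).
#' @param sex_effect Additive effect of sex = 1 vs sex = 0 (centered so the
#'   overall mean stays `mu`).
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return List with `genotypes` (a [genotype_matrix()] holding one SNP,
#'   `rs_sim1`, alleles A/G with G the effect allele) and `phenotypes`
#'   (a [phenotype_table()]).
#' @export
simulate_cohort <- function(n, freq, beta = 0, het_offset = 0, hom_offset = 0,
                            mu = 31, sigma = 3, sex_effect = 0,
                            missing_rate = 0, seed = 1L) {
  msc_assert(freq > 0 && freq < 1 && sigma > 0, "bad freq or sigma")
  set.seed(seed)
  gval <- c(0, beta + het_offset, 2 * beta + hom_offset)
  probs <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  mean_g <- sum(probs * gval)
  var_g <- sum(probs * gval^2) - mean_g^2
  var_sex <- sex_effect^2 / 4
  resid_var <- sigma^2 - var_g - var_sex
  msc_assert(resid_var > 0,
             "infeasible variance partition: genetic + sex variance >= sigma^2")
  g <- rbinom(n, 2L, freq)
  sex <- rbinom(n, 1L, 0.5)
  y <- mu + (gval[g + 1L] - mean_g) + sex_effect * (sex - 0.5) +
    rnorm(n, 0, sqrt(resid_var))
  calls <- matrix(as.integer(g), ncol = 1)
  if (missing_rate > 0)
    calls[runif(n) < missing_rate] <- NA_integer_
  ids <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(
    ids,
    data.frame(snp_id = "rs_sim1", chrom = "chr1", pos = 1000L,
               allele_a = "A", allele_b = "G", ancestral = "A",
               stringsAsFactors = FALSE),
    calls)
  list(genotypes = gm,
       phenotypes = phenotype_table(ids, y, sex))
}

#' Simulate a Wahlund-mixture cohort
#'
#' Each individual is drawn from one of two subpopulations, each internally
#' in HWE at its own allele frequency. The pooled sample shows the classic
#' heterozygote deficit `F ~ (p1 - p2)^2 / (4 pbar qbar)` whenever the
#' frequencies differ.
#'
#' @param n Cohort size.
#' @param p1,p2 Subpopulation allele_b frequencies.
#' @param mix Proportion of individuals from subpopulation 1 (default 0.5).
#' @param seed Integer seed.
#' @return A [genotype_matrix()] (one SNP) with a `subpop` attribute giving
#'   each sample's origin (1 or 2).
#' @export
simulate_structured_cohort <- function(n, p1, p2, mix = 0.5, seed = 1L) {
  msc_assert(all(c(p1, p2) > 0 & c(p1, p2) < 1) && mix > 0 && mix < 1,
             "frequencies and mix must be in (0, 1)")
  set.seed(seed)
  sub <- ifelse(runif(n) < mix, 1L, 2L)
  g <- rbinom(n, 2L, ifelse(sub == 1L, p1, p2))
  gm <- genotype_matrix(
    sprintf("S%04d", seq_len(n)),
    data.frame(snp_id = "rs_mix1", chrom = "chr1", pos = 1000L,
               allele_a = "A", allele_b = "G", stringsAsFactors = FALSE),
    matrix(as.integer(g), ncol = 1))
  attr(gm, "subpop") <- sub
  gm
}

#' Simulate a multi-population allele-frequency panel
#'
#' Per SNP, an ancestral frequency is drawn uniformly from `anc_range`
#' (bounded away from 0/1 to avoid monomorphic draws); each population's
#' frequency then follows the Balding-Nichols law
#' `Beta(pbar (1-F)/F, (1-pbar)(1-F)/F)` at that population's FST
#' (`F = 0` copies the ancestral frequency exactly), and observed counts are
#' binomial at the stated number of chromosomes. Positions are uniform over
#' the span.
#'
#' @param n_snps Number of SNPs.
#' @param fst Named numeric vector: per-population FST values in \[0, 1).
#'   Names become population names.
#' @param n_chrom Typed chromosomes (2n) per population; recycled.
#' @param span Length-2 0-based half-open span for positions
#'   (default 0-5 Mb).
#' @param anc_range Ancestral-frequency range (default 0.05-0.95).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A [pop_allele_counts()].
#' @export
simulate_panel <- function(n_snps, fst, n_chrom = 120L, span = c(0, 5e6),
                           anc_range = c(0.05, 0.95), chrom = "chr1",
                           seed = 1L) {
  msc_assert(n_snps > 0, "n_snps must be positive")
  msc_assert(all(fst >= 0 & fst < 1), "fst values must be in [0, 1)")
  if (is.null(names(fst))) names(fst) <- paste0("pop", seq_along(fst))
  n_chrom <- rep_len(as.integer(n_chrom), length(fst))
  set.seed(seed)
  pos <- sort(sample.int(span[2] - span[1], n_snps)) + span[1]  # 1-based
  pbar <- runif(n_snps, anc_range[1], anc_range[2])
  counts <- totals <- matrix(0L, n_snps, length(fst),
                             dimnames = list(NULL, names(fst)))
  for (k in seq_along(fst)) {
    f <- fst[k]
    p <- if (f == 0) pbar else
      rbeta(n_snps, pbar * (1 - f) / f, (1 - pbar) * (1 - f) / f)
    counts[, k] <- rbinom(n_snps, n_chrom[k], p)
    totals[, k] <- n_chrom[k]
  }
  pop_allele_counts(
    data.frame(snp_id = paste0("snp", seq_len(n_snps)), chrom = chrom,
               pos = as.integer(pos), stringsAsFactors = FALSE),
    counts, totals)
}

#' Forward Wright-Fisher simulation of a selective sweep
#'
#' Binary haplotypes for a diploid population of size `pop_size`. One focal
#' marker carries a derived allele with genotype fitness `1`, `1 + s`,
#' `1 + 2s`; recombination occurs independently between adjacent markers with
#' probability `rec` per meiosis. The run stops when the derived frequency
#' reaches `stop_freq` (restarting if the allele is lost or the generation
#' cap is hit), or after exactly `generations` generations when that is given
#' (no restart on loss; used for neutral controls). Background markers start
#' at uniform random frequencies in `bg_range`.
#'
#' @param n_markers Number of markers (focal marker at the middle index).
#' @param span Chromosome length in bp; markers are evenly spaced.
#' @param pop_size Diploid population size N (2N haplotypes).
#' @param s Selection coefficient per derived-allele copy.
#' @param rec Recombination probability per adjacent-marker interval.
#' @param init_freq Initial derived-allele frequency at the focal marker.
#' @param stop_freq Derived frequency at which to stop (ignored when
#'   `generations` is given).
#' @param generations Fixed number of generations (neutral-control mode).
#' @param sample_size Haplotypes sampled without replacement at the end.
#' @param bg_range Initial background-marker frequency range.
#' @param max_restarts Restarts allowed before giving up.
#' @param max_generations Generation cap per attempt in stop-frequency mode.
#' @param seed Integer seed.
#' @return A [haplotype_set()] with all ancestral codes 0 (derived = 1),
#'   plus attributes `focal` (marker index), `focal_freq` (final derived
#'   frequency in the sample) and `trajectory` (per-generation population
#'   derived frequency of the last attempt).
#' @export
simulate_sweep <- function(n_markers = 51L, span = 5e5, pop_size = 100L,
                           s = 0.05, rec = 0.001, init_freq = 0.05,
                           stop_freq = 0.7, generations = NULL,
                           sample_size = 40L, bg_range = c(0.2, 0.8),
                           max_restarts = 30L, max_generations = 1000L,
                           seed = 1L) {
  msc_assert(s >= 0 && rec >= 0 && rec <= 1, "bad s or rec")
  msc_assert(sample_size <= 2 * pop_size, "sample_size exceeds 2N")
  set.seed(seed)
  L <- as.integer(n_markers)
  focal <- (L + 1L) %/% 2L
  positions <- as.integer(round(seq(1, span, length.out = L)))
  n_hap <- 2L * as.integer(pop_size)
  fixed_mode <- !is.null(generations)
  for (attempt in seq_len(max_restarts + 1L)) {
    bg_freq <- runif(L, bg_range[1], bg_range[2])
    pop <- matrix(rbinom(n_hap * L, 1L, rep(bg_freq, each = n_hap)),
                  nrow = n_hap)
    pop[, focal] <- 0L
    n_init <- max(1L, round(n_hap * init_freq))
    pop[sample.int(n_hap, n_init), focal] <- 1L
    traj <- mean(pop[, focal])
    gens <- if (fixed_mode) generations else max_generations
    done <- FALSE
    for (gen in seq_len(gens)) {
      foc <- pop[, focal]
      d <- foc[seq(1, n_hap, 2)] + foc[seq(2, n_hap, 2)]
      w <- 1 + s * d
      parent <- sample.int(pop_size, n_hap, replace = TRUE, prob = w)
      first <- rbinom(n_hap, 1L, 0.5)
      if (L > 1) {
        switches <- matrix(rbinom(n_hap * (L - 1L), 1L, rec), nrow = n_hap)
        cum <- (first + cbind(0L, t(apply(switches, 1, cumsum)))) %% 2L
      } else {
        cum <- matrix(first, ncol = 1)
      }
      src_row <- 2L * (parent - 1L) + 1L + cum   # n_hap x L row indices
      pop <- matrix(pop[cbind(as.vector(src_row), rep(seq_len(L),
                                                      each = n_hap))],
                    nrow = n_hap)
      fr <- mean(pop[, focal])
      traj <- c(traj, fr)
      if (!fixed_mode) {
        if (fr >= stop_freq) { done <- TRUE; break }
        if (fr == 0) break
      }
    }
    if (fixed_mode) done <- TRUE
    if (done) {
      keep <- sample.int(n_hap, sample_size)
      hs <- haplotype_set(pop[keep, , drop = FALSE], "chr1", positions,
                          snp_id = paste0("m", seq_len(L)),
                          ancestral_code = rep(0L, L))
      attr(hs, "focal") <- focal
      attr(hs, "focal_freq") <- mean(pop[keep, focal])
      attr(hs, "trajectory") <- traj
      return(hs)
    }
  }
  stop("derived allele lost in every attempt; increase s, init_freq or restarts",
       call. = FALSE)
}
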