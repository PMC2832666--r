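# Independent oracles: deliberately naive re-implementations used only to
# check package results. They never call the code paths they test.

# Tajima's D from first principles, written directly off the constant
# definitions (harmonic sums via explicit loops).
oracle_tajima_d <- function(S, pi, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH by brute-force enumeration of all carrier pairs.
oracle_ehh <- function(haps, carriers, cols) {
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  hits <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (all(haps[carriers[i], cols] == haps[carriers[j], cols]))
      hits <- hits + 1L
  }
  hits / choose(n, 2)
}

# Neutral constant-size coalescent sample (infinite sites): returns the
# segregating-site count and the pairwise diversity of one replicate.
# Lineages are merged uniformly at random; mutations are Poisson on each
# branch with rate theta/2 per unit coalescent time.
oracle_coalescent_sfs <- function(n, theta) {
  lineages <- as.list(seq_len(n))   # descendant sets
  S <- 0L
  pi <- 0
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    for (l in seq_len(k)) {
      m <- rpois(1, theta / 2 * t_k)
      if (m > 0) {
        i <- length(lineages[[l]])
        S <- S + m
        pi <- pi + m * i * (n - i) / choose(n, 2)
      }
    }
    pick <- sample.int(k, 2)
    lineages[[pick[1]]] <- c(lineages[[pick[1]]], lineages[[pick[2]]])
    lineages[[pick[2]]] <- NULL
    k <- k - 1L
  }
  c(S = S, pi = pi)
}

# Two-proportion z statistic on allele counts (for the chi-square identity).
oracle_two_prop_z <- function(gc1, gc2) {
  x1 <- 2 * gc1[1] + gc1[2]; n1 <- 2 * sum(gc1)
  x2 <- 2 * gc2[1] + gc2[2]; n2 <- 2 * sum(gc2)
  p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}
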