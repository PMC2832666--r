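# Long-range haplotype test: core haplotypes, EHH decay, REHH against pooled
# other cores, a gamma null fitted within core-frequency bins, a
# derived-allele-frequency filter (> 0.60), and FDR control.
#
# Assumption flags (the original whole-genome implementation leaves these
# unpublished; they are configurable and stamped into CLI output headers):
#   * REHH denominator pools all non-target core carriers into one group.
#   * Test distance = farthest marker where the pooled EHH is still >= 0.05.
#   * Gamma fitted to raw REHH values, upper-tail p.
#   * Distances are physical (bp); no genetic map.

#' Enumerate core haplotypes
#'
#' Distinct allele strings over the core SNPs with carrier counts; patterns
#' with fewer than `min_carriers` carriers are dropped, so retained
#' frequencies may sum to less than 1.
#'
#' @param hs A [haplotype_set()].
#' @param core_idx Integer marker indices forming the core (contiguous).
#' @param min_carriers Minimum carriers for a pattern to be retained
#'   (default 3).
#' @return Object of class `core_haps`: list with `core_idx`, `patterns`
#'   (`data.frame`: `pattern`, `count`, `freq`) and `carriers` (list of
#'   haplotype row indices per pattern).
#' @export
core_haplotypes <- function(hs, core_idx, min_carriers = 3L) {
  core_idx <- sort(as.integer(core_idx))
  msc_assert(length(core_idx) >= 1 && all(core_idx >= 1) &&
               all(core_idx <= ncol(hs$haps)), "bad core marker indices")
  pat <- apply(hs$haps[, core_idx, drop = FALSE], 1, paste, collapse = "")
  tab <- table(pat)
  keep <- names(tab)[tab >= min_carriers]
  if (length(keep) == 0)
    warning("all core patterns fall below min_carriers", call. = FALSE)
  n <- nrow(hs$haps)
  patterns <- data.frame(pattern = keep,
                         count = as.integer(tab[keep]),
                         freq = as.integer(tab[keep]) / n,
                         stringsAsFactors = FALSE)
  o <- order(-patterns$count)
  patterns <- patterns[o, , drop = FALSE]
  rownames(patterns) <- NULL
  carriers <- lapply(patterns$pattern, function(p) which(pat == p))
  structure(list(core_idx = core_idx, patterns = patterns,
                 carriers = carriers, n_haps = n),
            class = "core_haps")
}

#' @export
print.core_haps <- function(x, ...) {
  cat(sprintf("core_haps: %d retained pattern(s) over %d core SNP(s), %d haplotypes\n",
              nrow(x$patterns), length(x$core_idx), x$n_haps))
  print(x$patterns)
  invisible(x)
}

# Homozygosity of a set of haplotype rows over marker columns `cols`
# (cols in walking order): probability two random distinct carriers are
# identical over all of them. Grouping-based; the brute-force pair count is
# kept as an independent oracle in the tests.
.ext_hom <- function(haps, rows, cols) {
  n <- length(rows)
  if (n < 2) return(NA_real_)
  if (length(cols) == 0) return(1)
  key <- apply(haps[rows, cols, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity curve
#'
#' EHH at marker x = probability that two randomly drawn distinct carriers of
#' the core are identical at every SNP between the core edge and x
#' (inclusive). Computed outward marker by marker until the curve drops below
#' `stop_ehh` or the chromosome ends. EHH is 1 at the core by definition and
#' non-increasing outward.
#'
#' @param hs A [haplotype_set()].
#' @param carriers Haplotype row indices carrying the core pattern (>= 2).
#' @param core_idx Core marker indices.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @param stop_ehh Stop extending once EHH falls below this (default 0.05).
#' @return `data.frame`: `marker` (index, `NA` for the core anchor row),
#'   `position`, `ehh`.
#' @export
ehh <- function(hs, carriers, core_idx, direction = c("right", "left"),
                stop_ehh = 0.05) {
  direction <- match.arg(direction)
  if (length(carriers) < 2) return(NULL)
  core_idx <- sort(as.integer(core_idx))
  edge <- if (direction == "right") max(core_idx) else min(core_idx)
  idx <- if (direction == "right") {
    if (edge == ncol(hs$haps)) integer() else seq(edge + 1L, ncol(hs$haps))
  } else {
    if (edge == 1L) integer() else seq(edge - 1L, 1L)
  }
  out <- data.frame(marker = NA_integer_, position = hs$positions[edge],
                    ehh = 1)
  key <- rep("", length(carriers))
  for (j in idx) {
    key <- paste0(key, hs$haps[carriers, j])
    cnt <- table(key)
    e <- sum(cnt * (cnt - 1)) / (length(carriers) * (length(carriers) - 1))
    out <- rbind(out, data.frame(marker = j, position = hs$positions[j],
                                 ehh = e))
    if (e < stop_ehh) break
  }
  out
}

#' Relative extended haplotype homozygosity
#'
#' REHH of a target core pattern: its EHH divided by the EHH of all other
#' retained core carriers pooled into one group, evaluated per direction at
#' the test distance (by default the farthest marker at which the pooled EHH
#' is still `>= ehh_floor`; alternatively a fixed physical distance in bp).
#' The reported `rehh` is the larger of the two directional values, since a
#' sweep signal can sit on either side of the core.
#'
#' @param hs A [haplotype_set()].
#' @param cores A [core_haplotypes()] result.
#' @param target Index of the target pattern in `cores$patterns`.
#' @param distance Optional fixed test distance in bp from the core edge.
#' @param ehh_floor Pooled-EHH floor defining the default test distance.
#' @return List: `rehh`, per-direction `rehh_right`/`rehh_left`, positions of
#'   the test markers, and the EHH values entering each ratio. `rehh` is `NA`
#'   when the pooled group has fewer than 2 carriers or its EHH is 0 at the
#'   test marker.
#' @export
rehh <- function(hs, cores, target, distance = NULL, ehh_floor = 0.05) {
  msc_assert(target >= 1 && target <= nrow(cores$patterns), "bad target index")
  tgt <- cores$carriers[[target]]
  oth <- sort(unlist(cores$carriers[-target]))
  if (length(oth) < 2 || length(tgt) < 2)
    return(list(rehh = NA_real_, rehh_right = NA_real_, rehh_left = NA_real_,
                reason = "fewer than 2 target or pooled-other carriers"))
  one_dir <- function(direction) {
    pooled <- ehh(hs, oth, cores$core_idx, direction, stop_ehh = 0)
    pooled <- pooled[!is.na(pooled$marker), , drop = FALSE]
    if (nrow(pooled) == 0) return(list(rehh = NA_real_, position = NA_integer_))
    edge_pos <- hs$positions[if (direction == "right") max(cores$core_idx)
                             else min(cores$core_idx)]
    ok <- if (is.null(distance)) pooled$ehh >= ehh_floor
          else abs(pooled$position - edge_pos) <= distance
    if (!any(ok)) return(list(rehh = NA_real_, position = NA_integer_))
    at <- max(which(ok))
    m <- pooled$marker[at]
    e_pool <- pooled$ehh[at]
    if (e_pool <= 0) return(list(rehh = NA_real_, position = pooled$position[at]))
    cols <- if (direction == "right") seq(max(cores$core_idx) + 1L, m)
            else seq(min(cores$core_idx) - 1L, m)
    e_tgt <- .ext_hom(hs$haps, tgt, cols)
    list(rehh = e_tgt / e_pool, position = pooled$position[at],
         ehh_target = e_tgt, ehh_pooled = e_pool)
  }
  r <- one_dir("right"); l <- one_dir("left")
  vals <- c(right = r$rehh, left = l$rehh)
  best <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  list(rehh = best, rehh_right = r$rehh, rehh_left = l$rehh,
       position_right = r$position, position_left = l$position)
}

#' Maximum-likelihood gamma fit
#'
#' Shape solved by Newton iteration on
#' `log(k) - digamma(k) = log(mean(x)) - mean(log(x))`, scale = `mean(x)/k`.
#'
#' @param x Positive observations (REHH values of one core-frequency bin).
#' @param min_obs Minimum observations required (default 20).
#' @return Object of class `gamma_fit`: list with `shape`, `scale`, `n_obs`,
#'   `loglik`.
#' @export
gamma_fit <- function(x, min_obs = 20L) {
  x <- x[!is.na(x)]
  msc_assert(length(x) >= min_obs,
             sprintf("gamma fit needs at least %d observations", min_obs))
  msc_assert(all(x > 0), "gamma fit needs strictly positive values")
  s <- log(mean(x)) - mean(log(x))
  msc_assert(s > 1e-12, "degenerate (constant) values: gamma fit undefined")
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:100) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  theta <- mean(x) / k
  ll <- sum(stats::dgamma(x, shape = k, scale = theta, log = TRUE))
  structure(list(shape = k, scale = theta, n_obs = length(x), loglik = ll),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma_fit: shape %.4f, scale %.4f (n = %d, loglik %.2f)\n",
              x$shape, x$scale, x$n_obs, x$loglik))
  invisible(x)
}

#' Upper-tail p-value under a fitted gamma null
#'
#' @param x Observed value(s).
#' @param fit A [gamma_fit()].
#' @return `P(X > x)` under the fitted gamma.
#' @export
gamma_p <- function(x, fit) {
  pgamma(x, shape = fit$shape, scale = fit$scale, lower.tail = FALSE)
}

#' Derived-allele high-frequency filter for a core haplotype
#'
#' A core pattern passes when it carries the derived allele at one or more
#' core SNPs whose sample derived-allele frequency exceeds 0.60 (strict).
#' Core SNPs with unknown ancestral state never satisfy the filter.
#'
#' @param hs A [haplotype_set()] with `ancestral_code` set.
#' @param cores A [core_haplotypes()] result.
#' @param target Pattern index.
#' @param cutoff Frequency cutoff (default 0.60, strict `>`).
#' @return List: `pass` flag, `derived_freq` (max derived frequency over core
#'   SNPs where the pattern is derived; `NA` if none known), `reason`.
#' @export
derived_filter <- function(hs, cores, target, cutoff = 0.60) {
  idx <- cores$core_idx
  anc <- hs$ancestral_code[idx]
  if (all(is.na(anc)))
    return(list(pass = FALSE, derived_freq = NA_real_,
                reason = "ancestral state unknown at all core SNPs"))
  pat <- as.integer(strsplit(cores$patterns$pattern[target], "")[[1]])
  der_allele <- 1L - anc                     # derived = complement of ancestral
  der_freq <- vapply(seq_along(idx), function(k) {
    if (is.na(anc[k])) return(NA_real_)
    mean(hs$haps[, idx[k]] == der_allele[k])
  }, numeric(1))
  carries <- !is.na(anc) & pat == der_allele
  if (!any(carries))
    return(list(pass = FALSE, derived_freq = NA_real_,
                reason = "pattern carries no known derived allele at the core"))
  dmax <- max(der_freq[carries])
  list(pass = dmax > cutoff, derived_freq = dmax,
       reason = if (dmax > cutoff) "derived frequency above cutoff"
                else "derived frequency at or below cutoff")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values with significance flags at level `q`.
#'
#' @param p P-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return `data.frame`: `p`, `q_bh`, `significant`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  msc_assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values outside [0, 1]")
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, q_bh = adj, significant = !is.na(adj) & adj <= q)
}

#' Tile non-overlapping cores along a haplotype set
#'
#' @param hs A [haplotype_set()].
#' @param core_size Number of SNPs per core (default 1).
#' @param step Offset in markers between core starts (default `core_size`).
#' @return List of integer index vectors, one per core.
#' @export
tile_cores <- function(hs, core_size = 1L, step = core_size) {
  starts <- seq(1L, ncol(hs$haps) - core_size + 1L, by = step)
  lapply(starts, function(s) seq(s, s + core_size - 1L))
}

#' Whole-genome long-range haplotype test
#'
#' Full REHH pipeline over a set of cores: enumerate core haplotypes, compute
#' each retained pattern's REHH against the pooled other carriers, fit a
#' gamma null by maximum likelihood within core-frequency bins (equal-count
#' binning), convert each REHH to an upper-tail p-value, apply the
#' derived-allele filter (> `derived_cutoff`), and control FDR by
#' Benjamini-Hochberg. A core is flagged significant when its adjusted value
#' is at most `fdr_q` *and* it passes the derived filter.
#'
#' @param hs A [haplotype_set()].
#' @param core_list List of core marker-index vectors (see [tile_cores()]).
#' @param min_carriers,ehh_floor,derived_cutoff,fdr_q Pipeline thresholds.
#' @param n_bins Number of equal-count core-frequency bins for the gamma null
#'   (reduced automatically so every bin keeps at least `min_obs` cores).
#' @param min_obs Minimum REHH observations per gamma fit (default 20).
#' @param distance Optional fixed REHH test distance in bp.
#' @return `data.frame`, one row per retained core pattern: core bounds,
#'   pattern, frequency, `rehh`, `derived_freq`, `derived_pass`, `p_gamma`,
#'   `q_bh`, `significant`.
#' @export
wglrh_test <- function(hs, core_list = tile_cores(hs), min_carriers = 3L,
                       ehh_floor = 0.05, derived_cutoff = 0.60, fdr_q = 0.05,
                       n_bins = 10L, min_obs = 20L, distance = NULL) {
  rows <- list()
  for (ci in seq_along(core_list)) {
    cores <- suppressWarnings(core_haplotypes(hs, core_list[[ci]], min_carriers))
    if (nrow(cores$patterns) < 2) next  # REHH needs a non-target pool
    for (t in seq_len(nrow(cores$patterns))) {
      rh <- rehh(hs, cores, t, distance = distance, ehh_floor = ehh_floor)
      df <- derived_filter(hs, cores, t, cutoff = derived_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        core = ci,
        core_start = hs$positions[min(cores$core_idx)],
        core_end = hs$positions[max(cores$core_idx)] + 1L,
        pattern = cores$patterns$pattern[t],
        freq = cores$patterns$freq[t],
        count = cores$patterns$count[t],
        rehh = rh$rehh,
        derived_freq = df$derived_freq,
        derived_pass = df$pass,
        stringsAsFactors = FALSE)
    }
  }
  msc_assert(length(rows) > 0, "no scorable cores")
  res <- do.call(rbind, rows)
  res$p_gamma <- NA_real_
  ok <- !is.na(res$rehh) & res$rehh > 0
  n_ok <- sum(ok)
  if (n_ok >= min_obs) {
    n_bins_eff <- max(1L, min(n_bins, n_ok %/% min_obs))
    bin <- rep(1L, n_ok)
    if (n_bins_eff > 1) {
      qs <- stats::quantile(res$freq[ok], probs = seq(0, 1, length.out =
                                                        n_bins_eff + 1))
      bin <- findInterval(res$freq[ok], unique(qs), rightmost.closed = TRUE,
                          all.inside = TRUE)
    }
    pg <- rep(NA_real_, n_ok)
    for (b in unique(bin)) {
      xs <- res$rehh[ok][bin == b]
      fit <- tryCatch(gamma_fit(xs, min_obs = min(min_obs, length(xs))),
                      error = function(e) NULL)
      if (!is.null(fit)) pg[bin == b] <- gamma_p(xs, fit)
    }
    res$p_gamma[ok] <- pg
  }
  fdr <- bh_fdr(res$p_gamma, q = fdr_q)
  res$q_bh <- fdr$q_bh
  res$significant <- fdr$significant & res$derived_pass
  res
}
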