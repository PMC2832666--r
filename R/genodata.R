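# Data model and IO for genotypes, phased haplotypes, phenotypes, regions and
# ancestral-allele annotations.
#
# Conventions (stated once, used everywhere):
#   * VCF positions are 1-based; BED intervals are 0-based half-open.
#     All internal window arithmetic is 0-based half-open and converts on IO.
#   * `calls` count copies of allele_b (the VCF ALT). Association and
#     frequency operations take an explicit effect/target allele rather than
#     assuming an orientation.
#   * Input is assumed to be on a consistent strand; no flipping is attempted.

MELANIN_BAND <- c(15, 110)

#' Construct a genotype matrix
#'
#' Container for diploid biallelic SNP genotypes: per-sample counts of
#' `allele_b` (0, 1, 2 or `NA` for missing) plus per-SNP metadata including an
#' optional ancestral-allele annotation.
#'
#' @param samples Character vector of unique sample ids.
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b` and optionally `ancestral` (one of the two allele
#'   strings, or `NA` when unknown).
#' @param calls Integer matrix, samples x SNPs, entries in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, snps, calls) {
  samples <- as.character(samples)
  msc_assert(!anyDuplicated(samples), "duplicate sample ids")
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  msc_assert(all(req %in% names(snps)),
             paste("snps must have columns:", paste(req, collapse = ", ")))
  if (is.null(snps$ancestral)) snps$ancestral <- NA_character_
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  snps$pos <- as.integer(snps$pos)
  msc_assert(all(snps$pos >= 1L), "pos must be >= 1 (1-based)")
  msc_assert(!anyDuplicated(snps$snp_id), "duplicate snp ids")
  msc_assert(all(snps$allele_a != snps$allele_b),
             "allele_a and allele_b must differ")
  bad_anc <- !is.na(snps$ancestral) &
    snps$ancestral != snps$allele_a & snps$ancestral != snps$allele_b
  msc_assert(!any(bad_anc), "ancestral allele must match allele_a or allele_b")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  msc_assert(nrow(calls) == length(samples) && ncol(calls) == nrow(snps),
             "calls dimensions do not match samples x snps")
  msc_assert(all(calls %in% c(0L, 1L, 2L) | is.na(calls)),
             "calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(samples, snps$snp_id)
  rownames(snps) <- NULL
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$calls))))
  n_anc <- sum(!is.na(x$snps$ancestral))
  cat(sprintf("  ancestral state known for %d/%d SNPs\n", n_anc, nrow(x$snps)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$snps))

#' Read diploid genotypes from VCF or tabular file
#'
#' The VCF reader uses only the GT field and keeps biallelic SNPs; in strict
#' mode a multi-allelic or non-SNP record is an error, otherwise such records
#' are dropped with a warning. Ancestral alleles are restored from the `AA`
#' INFO key when present. The tabular dialect is the one written by
#' [write_genotypes()]: one row per SNP with metadata columns followed by one
#' 0/1/2/NA column per sample.
#'
#' @param path Path to the input file.
#' @param dialect `"vcf"` or `"tab"`.
#' @param strict Logical; reject rather than drop non-biallelic records.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("vcf", "tab"), strict = TRUE) {
  dialect <- match.arg(dialect)
  msc_assert(file.exists(path), sprintf("file not found: %s", path))
  if (dialect == "vcf") .read_genotypes_vcf(path, strict) else
    .read_genotypes_tab(path)
}

.read_genotypes_vcf <- function(path, strict) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  n_alt <- S4Vectors::elementNROWS(alt)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- as.character(unlist(alt))[cumsum(n_alt)[n_alt >= 1L] -
                                                   n_alt[n_alt >= 1L] + 1L]
  ok <- n_alt == 1L & nchar(ref) == 1L & nchar(alt1) == 1L
  if (any(!ok)) {
    offenders <- paste(which(!ok), collapse = ", ")
    if (strict)
      stop(sprintf("non-biallelic or non-SNP VCF record(s) at row(s): %s",
                   offenders), call. = FALSE)
    warning(sprintf("dropping %d non-biallelic/non-SNP record(s)", sum(!ok)),
            call. = FALSE)
  }
  vcf <- vcf[ok, ]
  ref <- ref[ok]; alt1 <- alt1[ok]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  msc_assert(!is.null(gt), "VCF has no GT field")
  calls <- .gt_to_calls(gt)  # variants x samples
  anc <- NA_character_
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% names(info)) {
    anc <- as.character(info$AA)
    anc[anc %in% c(".", "")] <- NA_character_
  }
  snps <- data.frame(
    snp_id = rownames(gt) %||% paste0("snp", seq_along(ref)),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    allele_a = ref, allele_b = alt1,
    ancestral = anc, stringsAsFactors = FALSE
  )
  genotype_matrix(colnames(gt), snps, t(calls))
}

# GT strings -> integer ALT-allele dosage; NA for any missing allele.
.gt_to_calls <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == "."))
      return(NA_integer_)
    msc_assert(all(al %in% c("0", "1")),
               sprintf("malformed or non-biallelic GT '%s'", g))
    sum(al == "1")
  }, integer(1))
  m <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(m) <- dimnames(gt)
  m
}

.read_genotypes_tab <- function(path) {
  df <- msc_read_tsv(path)
  meta_cols <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "ancestral")
  msc_assert(all(meta_cols %in% names(df)),
             "tabular genotype file lacks metadata columns")
  sample_cols <- setdiff(names(df), meta_cols)
  msc_assert(length(sample_cols) > 0, "no sample columns found")
  snps <- df[meta_cols]
  snps$ancestral[snps$ancestral %in% c(".", "")] <- NA_character_
  calls <- t(as.matrix(df[sample_cols]))
  genotype_matrix(sample_cols, snps, calls)
}

#' Write genotypes to VCF or tabular format
#'
#' @inheritParams read_genotypes
#' @param gm A [genotype_matrix()].
#' @return The path, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("vcf", "tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") {
    df <- gm$snps
    df$ancestral[is.na(df$ancestral)] <- "."
    df <- cbind(df, as.data.frame(t(gm$calls)))
    msc_write_tsv(df, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=melanoscan-%s", packageVersion("melanoscan")),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$snps))) {
    s <- gm$snps[j, ]
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    info <- if (is.na(s$ancestral)) "." else paste0("AA=", s$ancestral)
    writeLines(paste(c(s$chrom, s$pos, s$snp_id, s$allele_a, s$allele_b,
                       ".", "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a TSV with header columns `sample_id`, `melanin_index`, `sex` and
#' optionally `group`. Rows with a non-numeric melanin index or an index
#' outside the instrument's plausibility band \[15, 110\] are dropped with a
#' warning; duplicate sample ids and sex codes outside `{0, 1}` are errors.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  msc_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- msc_read_tsv(path)
  req <- c("sample_id", "melanin_index", "sex")
  missing_cols <- setdiff(req, names(df))
  msc_assert(length(missing_cols) == 0,
             paste("phenotype file lacks column(s):",
                   paste(missing_cols, collapse = ", ")))
  if (is.null(df$group)) df$group <- NA_character_
  phenotype_table(df$sample_id, df$melanin_index, df$sex, df$group)
}

#' Construct a phenotype table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param melanin_index Numeric DermaSpectrometer melanin index (M units).
#' @param sex Binary covariate code, 0 or 1.
#' @param group Optional ancestry-group label.
#' @return `data.frame` of class `phenotype_table` with one row per retained
#'   sample.
#' @export
phenotype_table <- function(sample_id, melanin_index, sex,
                            group = NA_character_) {
  sample_id <- as.character(sample_id)
  msc_assert(!anyDuplicated(sample_id), "duplicate sample id in phenotypes")
  m <- suppressWarnings(as.numeric(melanin_index))
  bad <- is.na(m) | m < MELANIN_BAND[1] | m > MELANIN_BAND[2]
  if (any(bad))
    warning(sprintf("dropping %d row(s) with missing/implausible melanin index",
                    sum(bad)), call. = FALSE)
  sex <- suppressWarnings(as.integer(sex))
  msc_assert(all(sex[!bad] %in% c(0L, 1L)), "sex must be coded 0/1")
  out <- data.frame(sample_id = sample_id[!bad], melanin_index = m[!bad],
                    sex = sex[!bad],
                    group = rep_len(as.character(group), length(m))[!bad],
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read gene/region intervals from BED
#'
#' BED is 0-based half-open; intervals are kept in that convention internally.
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return `data.frame` of class `region_set` with columns `name`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
read_regions <- function(path) {
  msc_assert(file.exists(path), sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name %||% paste0("region", seq_along(gr))
  region_set(nm, as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Construct a region set
#'
#' @param name Unique region names.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @return `data.frame` of class `region_set`.
#' @export
region_set <- function(name, chrom, start, end) {
  msc_assert(!anyDuplicated(name), "region names must be unique")
  msc_assert(all(start < end), "regions require start < end")
  out <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Attach ancestral-allele annotations to a genotype matrix
#'
#' SNPs absent from the table keep (or get) an unknown ancestral state; a
#' listed ancestral allele that matches neither observed allele yields unknown
#' plus a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param table `data.frame` with columns `snp_id` and `ancestral`, or a path
#'   to a TSV with that header.
#' @return The annotated [genotype_matrix()].
#' @export
attach_ancestral <- function(gm, table) {
  if (is.character(table) && length(table) == 1L) table <- msc_read_tsv(table)
  msc_assert(all(c("snp_id", "ancestral") %in% names(table)),
             "ancestral table needs columns snp_id, ancestral")
  idx <- match(gm$snps$snp_id, table$snp_id)
  anc <- as.character(table$ancestral)[idx]
  anc[anc %in% c(".", "")] <- NA_character_
  mism <- !is.na(anc) & anc != gm$snps$allele_a & anc != gm$snps$allele_b
  if (any(mism)) {
    warning(sprintf(
      "ancestral allele matches neither observed allele for %d SNP(s): %s",
      sum(mism), paste(head(gm$snps$snp_id[mism], 5), collapse = ", ")),
      call. = FALSE)
    anc[mism] <- NA_character_
  }
  gm$snps$ancestral <- anc
  gm
}

#' Per-SNP frequency of a chosen allele
#'
#' @param gm A [genotype_matrix()].
#' @param allele `"b"` (the ALT/`allele_b` orientation of `calls`), `"a"`, or
#'   `"derived"`/`"ancestral"` to polarize by the attached ancestral state
#'   (`NA` where unknown).
#' @return Named numeric vector of allele frequencies (`NA` when all calls are
#'   missing or polarization is unknown).
#' @export
allele_freqs <- function(gm, allele = c("b", "a", "derived", "ancestral")) {
  allele <- match.arg(allele)
  n_ok <- colSums(!is.na(gm$calls))
  fb <- colSums(gm$calls, na.rm = TRUE) / (2 * n_ok)
  fb[n_ok == 0L] <- NA_real_
  out <- switch(allele,
    b = fb,
    a = 1 - fb,
    derived = ifelse(is.na(gm$snps$ancestral), NA_real_,
                     ifelse(gm$snps$ancestral == gm$snps$allele_a, fb, 1 - fb)),
    ancestral = ifelse(is.na(gm$snps$ancestral), NA_real_,
                       ifelse(gm$snps$ancestral == gm$snps$allele_a, 1 - fb, fb))
  )
  setNames(out, gm$snps$snp_id)
}

#' Per-SNP observed genotype counts
#'
#' @param gm A [genotype_matrix()].
#' @return `data.frame` with columns `snp_id`, `n_aa` (allele_a homozygotes),
#'   `n_ab`, `n_bb`, `n_missing`.
#' @export
genotype_counts <- function(gm) {
  cnt <- function(k) colSums(gm$calls == k, na.rm = TRUE)
  data.frame(snp_id = gm$snps$snp_id,
             n_aa = cnt(0L), n_ab = cnt(1L), n_bb = cnt(2L),
             n_missing = colSums(is.na(gm$calls)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- phased haplotypes -----------------------------------------------------

#' Construct a phased haplotype set
#'
#' Haplotypes are binary chromosomes: rows are haplotypes (two consecutive
#' rows per diploid individual when read from VCF), columns are markers coded
#' 0 = `allele_a`, 1 = `allele_b`. `ancestral_code` records, per marker, which
#' code is ancestral (0, 1, or `NA` when unknown).
#'
#' @param haps Integer 0/1 matrix, haplotypes x markers.
#' @param chrom Chromosome name (single string).
#' @param positions 1-based marker positions, strictly increasing.
#' @param snp_id Marker ids.
#' @param alleles Optional 2-column character matrix (`allele_a`, `allele_b`).
#' @param ancestral_code Integer vector in `{0, 1, NA}` per marker.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haps, chrom, positions,
                          snp_id = paste0("m", seq_len(ncol(haps))),
                          alleles = NULL, ancestral_code = rep(0L, ncol(haps))) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  msc_assert(all(haps %in% c(0L, 1L)), "haplotypes must be 0/1 with no missing")
  positions <- as.integer(positions)
  msc_assert(length(positions) == ncol(haps), "positions length != n markers")
  msc_assert(!is.unsorted(positions, strictly = TRUE),
             "positions must be strictly increasing")
  ancestral_code <- as.integer(ancestral_code)
  msc_assert(all(ancestral_code %in% c(0L, 1L) | is.na(ancestral_code)),
             "ancestral_code must be 0, 1 or NA")
  if (is.null(alleles))
    alleles <- cbind(allele_a = rep("A", ncol(haps)),
                     allele_b = rep("G", ncol(haps)))
  colnames(haps) <- snp_id
  structure(list(haps = haps, chrom = as.character(chrom)[1],
                 positions = positions, snp_id = as.character(snp_id),
                 alleles = alleles, ancestral_code = ancestral_code),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d markers on %s (%d-%d bp)\n",
              nrow(x$haps), ncol(x$haps), x$chrom,
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Read phased haplotypes
#'
#' The VCF dialect requires every genotype to be phased (`|`-separated); the
#' tabular dialect is the matrix layout written by [write_haplotypes()].
#'
#' @inheritParams read_genotypes
#' @return A [haplotype_set()].
#' @export
read_haplotypes <- function(path, dialect = c("vcf", "tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") {
    df <- msc_read_tsv(path)
    meta <- c("snp_id", "chrom", "pos", "ancestral_code")
    msc_assert(all(meta %in% names(df)), "haplotype TSV lacks metadata columns")
    hap_cols <- setdiff(names(df), meta)
    anc <- suppressWarnings(as.integer(df$ancestral_code))
    return(haplotype_set(t(as.matrix(df[hap_cols])), df$chrom[1], df$pos,
                         snp_id = df$snp_id, ancestral_code = anc))
  }
  gm_like <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(gm_like)$GT
  msc_assert(all(grepl("^[01]\\|[01]$", gt)),
             "haplotype VCF must be fully phased with 0|0-style GT")
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  haps <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  haps[seq(1, nrow(haps), 2), ] <- t(h1)
  haps[seq(2, nrow(haps), 2), ] <- t(h2)
  rr <- SummarizedExperiment::rowRanges(gm_like)
  ref <- as.character(VariantAnnotation::ref(gm_like))
  alt <- as.character(unlist(VariantAnnotation::alt(gm_like)))
  info <- VariantAnnotation::info(gm_like)
  anc <- rep(NA_integer_, nrow(gt))
  if ("AA" %in% names(info)) {
    aa <- as.character(info$AA)
    anc[!is.na(aa) & aa == ref] <- 0L
    anc[!is.na(aa) & aa == alt] <- 1L
  }
  haplotype_set(haps, as.character(GenomicRanges::seqnames(rr))[1],
                GenomicRanges::start(rr), snp_id = rownames(gt),
                alleles = cbind(allele_a = ref, allele_b = alt),
                ancestral_code = anc)
}

#' Write phased haplotypes as a tabular 0/1 matrix
#'
#' @param hs A [haplotype_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_haplotypes <- function(hs, path) {
  df <- data.frame(snp_id = hs$snp_id, chrom = hs$chrom, pos = hs$positions,
                   ancestral_code = hs$ancestral_code,
                   stringsAsFactors = FALSE)
  hap_mat <- t(hs$haps)
  colnames(hap_mat) <- paste0("h", seq_len(nrow(hs$haps)))
  msc_write_tsv(cbind(df, hap_mat), path)
}
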