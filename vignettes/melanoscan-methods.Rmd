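---
title: "melanoscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{melanoscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanoscan)
```

`melanoscan` packages the statistical chain of a candidate-gene study of
quantitative skin pigmentation: screen candidate regions with
population-genetic scan statistics, test SNPs for association with a
melanin index, and quantify power — with every stage exercisable end to end
on seeded synthetic data. This vignette is the package's own account of the
science: the models and their assumptions, the tunable parameters, what the
generators emulate, and the choices made where the methods literature is
silent. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## Data model and conventions

Genotypes are diploid biallelic calls stored as counts of `allele_b` (the
VCF ALT) per individual — 0, 1, 2 or missing. Orientation is never assumed:
association and frequency functions take an explicit effect/target allele.
VCF positions are 1-based, BED intervals 0-based half-open; all internal
window arithmetic is 0-based half-open and converts on IO. Input is assumed
to be on a consistent strand (no flipping), phased input is required for
haplotype work (no phasing or imputation is attempted), and all markers are
treated as autosomal. The melanin index is the DermaSpectrometer M scale;
values outside [15, 110] — beyond the range observed across human
populations — are rejected on input as instrument or transcription errors.

Ancestral states arrive as a SNP-to-allele table (in practice derived from
an outgroup such as chimpanzee). A listed ancestral allele matching neither
observed allele is demoted to unknown with a warning rather than silently
flipped, because such mismatches usually indicate strand or assembly
problems upstream.

## Hardy-Weinberg and linkage disequilibrium

The exact HWE test conditions on the observed allele counts, enumerates
every compatible heterozygote count (same parity), and sums the conditional
probabilities of all configurations no more probable than the observed one.
This probability-ordered two-sided tail is the standard exact convention;
no mid-p correction is applied (the plain convention reproduces published
candidate-gene p-values; a mid-p variant would not). Monomorphic samples
return p = 1.

Two-locus haplotype frequencies come from an EM algorithm over the
double-heterozygote phase ambiguity. Numerical choices: deterministic start
at linkage equilibrium (the product of the allele-frequency marginals), so
results are seed-free; convergence when the log-likelihood changes by less
than `tol = 1e-8`; `max_iter = 10000`. The log-likelihood is non-decreasing
by construction (an EM property asserted in the tests). Individuals missing
at either locus are excluded pairwise-complete, the simplest defensible
handling for the small marker panels this package targets. `r²` is
`D²/(p_A q_A p_B q_B)` and is undefined (returned as `NA`) at a monomorphic
marginal.

## Differentiation and diversity scans

`pairwise_fst()` defaults to the Hudson estimator because it is unbiased
under unequal sample sizes and simple to validate by simulation; a
Weir-Cockerham (haploid-sample) variant is provided. Negative per-SNP
estimates are reported as computed — they are informative about sampling
noise — and clamped to zero only inside the LSBL decomposition, where
negative branch lengths would be uninterpretable. The reconstruction
identity `lsbl_a + lsbl_b = d_ab` holds exactly. When averaging Hudson
F_ST over a panel, use the ratio-of-sums: the mean of per-SNP ratios is
biased downward (both are exercised in the test suite).

Windows are 100 kb sliding in 25-kb steps — the classic scan configuration
— anchored at multiples of the step from coordinate zero so that scans are
deterministic and reproducible regardless of where the data start. Windows
with fewer than `min_snps = 10` typed SNPs are masked rather than scored.
Per SNP the unbiased heterozygosity is `h = 2n/(2n−1) · 2p(1−p)`; per
window, `S` counts segregating SNPs, `π` sums `h`, and `H_mean` averages
it. Tajima's D uses the standard constants with the sample size taken as
the window's *minimum* typed chromosome count — a conservative choice when
missingness varies by SNP. lnRH converts `H_mean` to
`θ̂ = [1/(1−H)]² − 1`; any constant factor applied to both populations'
estimators cancels in the log ratio, so the factor-of-½ variant in the
literature is numerically equivalent (asserted as an invariance, not
assumed). Heterozygosities below `h_floor = 0.001` give `NA` rather than
an unbounded log.

Array-ascertained SNP panels bias absolute `π` and `S`. The package
computes the statistics as defined and leaves the caveat documented:
significance is always assessed against the *empirical* genome-wide
distribution of the same statistic (`P_E(x) = (#loci > x)/N`, strict
inequality, no +1 smoothing — the most extreme locus has p = 0), which
absorbs any uniform ascertainment shift. Per-region summaries report
significance-count triples at p < 0.001 / 0.01 / 0.05; the default bins are
exclusive tiers, with a cumulative mode available since published tables
are ambiguous between the two readings.

## The long-range haplotype test

For each core (one or more contiguous SNPs) the distinct allele strings are
enumerated; patterns with fewer than `min_carriers = 3` carriers are
dropped, since EHH over one or two chromosomes is vacuous. EHH at a marker
is the probability that two random distinct carriers are identical at every
SNP from the core edge to that marker; it is 1 at the core and
non-increasing outward. It is computed by grouping extended haplotypes
(`Σ n_h(n_h−1)/(n(n−1))`), with a brute-force all-pairs implementation kept
in the tests as an independent oracle.

The unpublished internals of the whole-genome long-range haplotype test
required four documented assumptions, all stamped into CLI output headers:

* the REHH denominator pools all non-target core carriers into one group
  (the grouped-EHH convention of the method's lineage);
* the test distance defaults to the farthest marker at which the pooled EHH
  is still ≥ `ehh_floor = 0.05`, avoiding 0/0; a fixed physical distance is
  available;
* each core's REHH is the larger of its two directional values, since a
  sweep signal can lie on either side of the core;
* distances are physical (bp); genetic-map support is a configuration
  extension, not a requirement.

The null is a gamma distribution fitted by maximum likelihood (Newton
iteration on the shape equation `log k − ψ(k) = log x̄ − mean(log x)`)
within equal-count core-frequency bins (default 10, reduced so every bin
keeps ≥ `min_obs = 20` observations) — REHH grows mechanically as core
frequency rises, so the null must be frequency-conditional. P-values are
the upper gamma tail of the raw REHH (not log REHH — the plainest reading
of the method). Constant values within a bin are a fit error, not a
silent degenerate fit. A core is reported significant when its
Benjamini-Hochberg adjusted value is ≤ `fdr_q = 0.05` *and* it passes the
derived-allele filter: the pattern carries the derived allele at a core SNP
whose sample derived frequency exceeds 0.60 (strict, per the method's
published cutoff); unknown ancestral states never pass, with the reason
recorded.

## Association and diagnostics

Each SNP is tested marginally (no multi-SNP model), matching small
candidate panels. The additive model regresses melanin index on effect-
allele dosage plus covariates (sex, coded 0/1, reported but never the
inference target); the unconstrained model uses heterozygote and
non-reference-homozygote indicators and requires all three genotype classes
(≥ 2 members each). The genotype's partial R² is
`(SSE_reduced − SSE_full)/SS_total`: the share of *total* phenotypic
variance explained by genotype beyond the covariates. Missing genotypes are
dropped per test, with the per-test n reported.

Multiple testing uses Bonferroni with an *effective* test count: markers
linked at `r² ≥ 0.99` are collapsed transitively into clusters and the
cluster count is the divisor. The 0.99 threshold reproduces the effective
count implied by published near-perfect LD pairs and is configurable.

Two stratification diagnostics mirror the usual reviewer questions: a
Pearson chi-square (1 df, no continuity correction — verified equal to the
squared two-proportion z statistic) on the 2×2 allele-count table compares
cohorts; and a per-SNP heterozygote excess/deficit report flags the Wahlund
signature (`F ≈ Δp²/(4 p̄q̄)` heterozygote deficit) expected under hidden
substructure. When an expected cell falls below 1 the chi-square warns and
a Fisher exact p is returned alongside.

## Power

With effect-allele frequency `p`, per-allele effect `β` and *total*
phenotypic SD `σ`, the genotype explains `v = 2p(1−p)β²` and the 1-df test
has noncentrality `λ = n·v/(σ² − v)`. Power is computed from the noncentral
`F(1, n−3)` distribution of the regression F test (intercept + genotype +
sex). The textbook noncentral-χ²(1) form is the large-n limit of this; at
n = 120 the χ² form runs ≈ 0.7 percentage points high against the exact
finite-sample t test, and the F form is the one that agrees with the
package's own 10,000-replicate simulation through the actual regression
engine within Monte-Carlo error (the acceptance suite asserts this). At
`β = 0` the power equals α exactly. Interpreting `σ` as total rather than
residual SD is a convention choice; external power tools differ, which is
why printed reference values are matched to ±2.5 percentage points rather
than exactly.

## What the synthetic data emulate — and what they do not

All generators are pure functions of their parameters plus a seed.

* `simulate_cohort()` draws HWE genotypes at a stated frequency and builds
  the phenotype as `μ + genetic value + sex effect + noise`, with the
  residual variance chosen so the *total* SD equals `σ` (defaults μ = 31,
  σ = 3 — the observed melanin distribution of a light-skinned East Asian
  cohort). Infeasible variance partitions are an error, not a silent
  rescale.
* `simulate_structured_cohort()` mixes two internally-HWE subpopulations,
  producing the closed-form Wahlund heterozygote deficit.
* `simulate_panel()` draws per-population allele frequencies from the
  Balding-Nichols law `Beta(p̄(1−F)/F, (1−p̄)(1−F)/F)` around a shared
  ancestral frequency (uniform on [0.05, 0.95], bounded away from fixation
  to avoid monomorphic draws) and binomial counts at the stated 2n. It is
  parameterized directly by F_ST, which makes estimator calibration
  testable.
* `simulate_sweep()` is a forward Wright-Fisher simulation on binary
  haplotypes: genotype fitness `1, 1+s, 1+2s` at one focal site,
  per-interval recombination, run either to a stop frequency (with restarts
  on loss) or for a fixed generation count (the matched neutral control).

The detector-validation world is stated once and not revisited: a hard
incomplete sweep — single-copy origin, `s = 0.15`, N = 200 diploids, 61
markers at `rec = 0.001` per interval, sampled at 60 haplotypes when the
derived allele reaches 0.7 — against an `s = 0` control run for the same
number of generations. The choices are method-driven: a single-copy origin
is the classic hard-sweep positive control (standing variation at 5% seeds
~20 founder haplotypes, a soft sweep whose haplotype signal is genuinely
weaker); the sweep is stopped while *incomplete* because long-range
haplotype statistics are designed for ongoing sweeps — once the ancestral
class shrinks to a few chromosomes it has itself coalesced and the REHH
denominator degenerates; and recombination is set so `r·t` over the sweep
is small near the core, while the pooled-EHH decay that defines the test
distance is driven by the linkage-equilibrium start of the background, not
by `rec`. REHH validation compares the selected core against
frequency-matched neutral cores — the method's own "given their frequency"
logic; an unmatched comparison is dominated by low-frequency cores whose
REHH is mechanically inflated.

What the generators do **not** emulate: mutation (all variation is
standing), demography (bottlenecks, growth, migration), genotyping error
beyond uniform missingness, ascertainment of array SNPs, genetic-map
heterogeneity, and linkage disequilibrium in the neutral background (which
starts at linkage equilibrium). A green detector test therefore establishes
that the statistics rank a strong injected signal above matched noise at
desk scale — not that the pipeline's power or false-positive behaviour on
real genome-wide human data matches any published scan.

## Numerical notes and degenerate inputs

Exact-HWE tail sums use a `1 + 1e-12` relative tolerance when comparing
configuration probabilities, absorbing floating-point ties between
symmetric tails. The gamma shape update halves toward zero rather than
stepping negative. `empirical_p` uses binary search on the sorted
distribution, so genome-scale lookups are `O(log N)` per query. Windows
shorter than one full window produce a single truncated-coverage window
starting at the step-floor of the span. Monomorphic SNPs yield reasoned
`NA` association rows rather than errors; absent genotype classes make the
unconstrained model refuse to fit. Ties in empirical p-values are excluded
by the strict inequality, which is the literal published formula — callers
wanting smoothing can add it explicitly.

## Known limitations

Two-locus EM only (no multi-locus haplotype estimation or block
detection); no kinship or mixed-model correction in association; physical
distance only in the haplotype test; no X-specific handling; the forward
simulator is desk-scale (hundreds of diploids, tens of markers) and is a
signal generator for validation, not a demographic inference tool.
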