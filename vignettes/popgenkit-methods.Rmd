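---
title: "Methods and numerical design of popgenkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical design of popgenkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenkit)
```

This vignette explains the statistical machinery in `popgenkit`, the
numerical decisions behind it, and what the package's test battery does and
does not demonstrate. It is written for users who want to understand what a
number coming out of the package means, and for maintainers who need to know
why a particular algorithmic choice was made.

## The packed data model

Genotypes live in the PLINK 1 binary layout: variant-major, two bits per
call (`00` hom a1, `01` missing, `10` het, `11` hom a2), four calls per
byte with the first sample in the lowest-order bits, each variant row padded
to whole bytes (pad code `00`). The convention throughout is that **a1 is
the minor allele** and unpacked integer genotypes count copies of a2, so a
dosage of 2 means homozygous major. All kernels read only the first
`n_samples` call slots, which is why the unit tests can scribble arbitrary
codes into the pad slots and demand bit-identical results.

Everything downstream - IBS, correlation, GRM, permutation counting - works
on whole 64-bit words of this representation. The population count is the
classic shift-mask-multiply reduction (no hardware intrinsic is assumed, so
results are identical on any platform), and `popcount2()` sums aligned 2-bit
fields instead of bits.

## Identity-by-state and the correlation kernel

For two samples, IBS similarity is `1 - sum |a_i - b_i| / (2|I|)` over the
jointly called markers `I`. The kernel encodes each call in two bits
(missing `01`, dosage 0/1/2 as `00`/`10`/`11`) plus a 2-bit presence mask,
processes 960-call blocks (30 words), and reduces each block with two
popcounts: `diff += popcount((A XOR B) AND C AND D)` and
`obs += popcount(C AND D)`. The code map is exactly the one that makes the
XOR's set-bit count equal `|a_i - b_i|`; the tests verify this exhaustively
over all nine genotype-pair cases rather than taking it on faith. Because
the per-block quantities are integers, block decomposition is exact and the
960-call granularity is purely an implementation rhythm.

The genotype correlation r recodes calls as `v = dosage - 1` with missing
mapped to 0. Means and second moments come from masked popcounts; the dot
product `sum v_i w_i` uses the 2-bit trick
`popcount2(((X XOR Y) AND (1010... - Z)) OR Z)` with
`Z = (X OR Y) AND 0101...`, which evaluates `1 - v_i w_i` per call. The
subtraction `1010... - Z` is safe because every minuend field is `10` and
every `Z` field is `00` or `01`, so no borrow can cross a field boundary.
Pad fields are encoded as `01` so each contributes exactly the 1 that the
final subtraction from the padded length cancels.

For all-pairs scans on missing-free data, per-variant moments are
precomputed once (`precompute_nomissing_moments()`); the package guarantees
the fast path is *bitwise* identical to the general path by routing both
through one shared arithmetic function operating on the same integer
components.

## Early-termination exact tests

The Hardy-Weinberg exact test works on the family of heterozygote counts
`k` compatible with fixed allele margins `n1`, `n2`. Adjacent-table
likelihood ratios, `L(k+2)/L(k) = (n1-k)(n2-k)/((k+1)(k+2))`, generate all
likelihoods as values relative to the most probable count (found by
hill-climbing on the ratio), so no factorial or log-gamma is ever needed.
Two tail sweeps accumulate the denominator and the numerator (terms with
likelihood at most the observed one, ties included) in constant space; a
sweep stops when its newest term no longer changes either partial sum *and*
has fallen below the observed likelihood. The second condition matters: if
the observed table sits far in a tail, the denominator saturates long before
the sweep reaches the numerator region, and stopping early would silently
zero the p-value. The tie comparison uses a relative tolerance of 1e-12 so
an exactly tied mirror table reached along a different rounding path still
counts.

The Fisher 2x2 test has the same structure over the upper-left cell of the
hypergeometric family. The 2x3 test parameterises tables by the two free
top-row cells `(a, b)`; rows of constant `a` are scanned outward from the
modal row and each row swept outward from its conditional mode with the
two ratio recurrences. The denominator visits only tables with relative
likelihood at least 2^-53 of the maximum; the numerator only the annulus
within a factor 2^53 below the observed likelihood. Terms outside these
regions are provably negligible at the 10-digit level: their total mass is
bounded by the table count times 2^-53, and the super-geometric decay makes
the realistic error orders of magnitude smaller still. Row reference
likelihoods are chained in log space so no intermediate quantity can under-
or overflow; each row's numerator contribution is rescaled to units of the
observed likelihood with one `exp()` per row.

Working relative to the mode means the method reports p-values accurately
down to roughly 1e-290; beyond that the relative scale itself underflows
and the test returns 0 (the extended-precision reference confirms the true
value is unrepresentable in doubles anyway).

All tests have mid-p modes computed as `p - obs_mass/2`: only the observed
table's probability is halved, the common definition; halving all tied mass
would differ only on exactly-tied families.

The reference implementations (`*_full`) enumerate the entire family in
80-bit extended precision from `lgammal()` absolute log-likelihoods. They
share no code path, no scaling strategy, and no precision class with the
fast tests, which is what makes the "minimum agreeing significant digits"
measurements in the acceptance script meaningful. On x86-64 the extended
format carries ~18-19 digits, comfortably more than the 10+ digits being
certified.

`relative_likelihood_support()` reports, for a 2x2 margin configuration,
the range of upper-left cells whose null *frequency* (probabilities summing
to 1 over the family) is at least 2^-53 - the tables a naive
double-precision summation can actually see. The cutoff is applied to the
sum-normalised frequency rather than the mode-normalised likelihood because
that is the quantity a p-value denominator accumulates.

## Genomic relationship matrix

The GRM increment for one marker and one sample pair is
`(x - 2q)(y - 2q) / (2q(1-q))` with `x`, `y` the a1 dosages and `q` the a1
frequency. The product form is invariant under jointly swapping the counted
allele and `q <-> 1-q`, so the allele-labelling convention does not affect
the matrix; what does matter is that the frequency must belong to the
counted allele, and the implementation enforces the consistent pairing.
Pairs with a missing call contribute 0 and decrement that pair's
denominator instead.

Twenty markers are handled per 64-bit word. Each sample's calls are
expanded once per block into 3-bit fields (`hom a1 -> 0`, `het -> 2`,
`hom a2 -> 3`, missing remapped to 0 with a parallel mask word holding 7);
the pair word is then `(g_j + g_k) OR mm_j OR mm_k`, whose fields take
seven distinct case values with no carry between fields because non-missing
sums never exceed 6. Four lookup tables with 2^15 entries each map five
3-bit codes at a time to the sum of five per-marker increments, so a
20-marker block costs four lookups and adds per pair. The tables are filled
by dynamic programming in the same left-associated order as a scalar
20-lookup loop, which is why `grm(lookup = FALSE)` is bitwise identical -
an invariant the tests assert, not just a design intention. Table entries
are 8-byte doubles (~1 MB of entries); accuracy was preferred over the
2x smaller 4-byte footprint.

Denominators are recovered from the mask words: each missing marker
contributes exactly three set bits to `mm_j OR mm_k`, so a popcount divided
by three counts them.

Diagonal entries use the same increment with `x = y`; no leave-one-out
adjustment is applied to the diagonal, and the row-chunk interface
(`row_chunk = c(k, K)` computing rows `ceiling(n(k-1)/K)+1 ..
ceiling(nk/K)`) concatenates exactly to the single-run matrix.

One statistical subtlety the calibration tests respect: when `q` is
estimated from the sample itself and no data are missing, each row of the
increment sum is identically zero, so the mean off-diagonal entry equals
`-mean(diagonal)/(n-1)` *by construction*, not because of any relatedness.
Unbiased "off-diagonal -> 0" behaviour appears when increments are centred
at the generating frequencies, which the synthetic-data generator can
provide.

## Complete-linkage clustering

`complete_linkage()` is a nearest-neighbour-chain implementation: reciprocal
nearest neighbours are merged and distances updated with the maximum rule.
Complete linkage is reducible, so the chain remains valid across merges and
the algorithm does O(n^2) distance work. Merges are recorded, then sorted
by height (stable, so equal-height merges keep chronological order) and
relabelled into the standard `hclust` encoding; the object inherits
`"hclust"`, so `cophenetic()`, `cutree()` and plotting work unchanged. Ties
are broken toward the smallest cluster index, making results deterministic.

## Linkage disequilibrium

**Pruning.** `indep_pairwise(window, step, r2max)` slides a window in
variant units within each chromosome; while any surviving pair in the
window exceeds the threshold, the member with the smaller MAF is removed
(ties: the later variant). Correlations are computed lazily and never
against removed variants. The postcondition - no surviving within-window
pair above the threshold - is what the tests verify, by exhaustive rescan.

**D' and its confidence interval.** With the double-heterozygote cell
phase-ambiguous, the likelihood stationarity condition for the frequency of
the a1/a1 haplotype is the EM fixed-point equation
`(2N p11 - c11)(f11 f22 + f12 f21) = d f11 f22`, a cubic in `p11` solved
in closed form (Cardano); roots outside `[max(0, pA+pB-1), min(pA, pB)]`
are discarded and log-likelihoods compared only when several candidates
remain (interval boundaries are always candidates, which covers |D'| = 1
configurations where the stationary point lies outside the open interval).
The 90% confidence interval follows the 101-point grid construction:
likelihoods at |D'| = 0, 0.01, ..., 1 with allele frequencies fixed at
their MLEs and the table oriented so D >= 0; `ci_low` is the largest grid
point with cumulative mass at most 5%, `ci_high` the smallest reaching 95%.
Classification (defaults: strong LD when `ci_low >= 0.70` and
`ci_high >= 0.98`; recombination when `ci_high < 0.90`) exposes all three
thresholds; only the 0.90 bound is intrinsic to the method's published
form, the others are the conventional Haploview settings.

**Fast classification.** When the cubic has a single in-range root the grid
likelihood is unimodal, and a pair can be labelled "recombination" from two
evaluations: if the peak lies left of 0.90 and
`L(0.90) < L(peak) * 0.05 / k`, where `k = 11` is the number of grid points
at or past 0.90, then the rightmost `k` likelihoods - which are monotone
decreasing - sum to less than 5% of the total, forcing `ci_high < 0.90`.
The constant is derived as `k / 0.05` rather than hard-coded, so it adapts
if the threshold is changed. The shortcut is conservative in both of its
bounds (the peak value underestimates nothing; the total is at least the
peak), so it can never disagree with the full grid; anything it cannot
prove falls back to the 101-point computation. The tests check equality of
the two paths on hundreds of random tables, small and large.

**Haplotype blocks.** Candidate spans within `max_span_kb` whose endpoint
pair is strong LD and whose informative pairs (strong + recombination;
inconclusive pairs count for neither side) satisfy strong > 19 x
recombination are collected and selected greedily by descending base-pair
span, ties leftmost, discarding overlaps. Pair classifications are computed
lazily and cached per chromosome; an optional bound aborts a candidate's
pair scan as soon as its recombination count makes 19:1 unreachable even if
every unseen pair were strong - provably output-preserving, and verified
against a brute-force reference that classifies every pair with the full
grid. Variants are MAF-filtered first (default 0.05); all within-candidate
informative pairs count toward the ratio.

## max(T) permutation testing

Genotypes of the phenotyped samples are split once into four bitplanes per
variant (hom a1 / het / hom a2 / non-missing, one bit per sample). A
permutation then costs, per variant, a handful of masked popcounts to
rebuild the 2x3 genotype or 2x2 allele table, from which the trend
chi-square, allelic chi-square, or early-termination Fisher p is computed.
Case labels are permuted by Fisher-Yates with an internal splitmix64
generator seeded from the `seed` argument - deliberately independent of R's
RNG so that reports are reproducible from the seed alone and unaffected by
the session state. Per-variant missingness is respected: each variant's
statistic uses its own called samples, so case counts vary across variants
within one permutation, exactly as in the observed data.

Empirical p-values use the `(k+1)/(R+1)` estimator (never zero, unbiased
exceedance probability under the null); the family-wise value compares each
observed statistic with the per-permutation maxima (minima of p for the
Fisher mode), so `EMP2 >= EMP1` structurally. Ties are counted as
at-least-as-extreme with a 1e-9 tolerance: chi-square statistics on
discrete tables collide exactly, and dropping ties would anti-conservatively
shrink p. Degenerate tables inside the permutation loop (a margin with no
variation) score 0, i.e. never extreme.

## The synthetic-data generator

`simulate_dataset()` draws, in a documented order from one seeded R
generator: MAFs uniform on `[maf_min, 0.5]`; LD-block haplotypes;
independent genotypes from Hardy-Weinberg proportions (heterozygote
frequency `2pq(1-F)` in inbreeding mode); a logistic case/control phenotype
whose intercept is solved so the expected case fraction matches the spec,
with planted allelic log odds ratios; and uniform missingness. LD blocks
give each sample two latent haplotype alleles at frequency p and copy them
into every block variant with a per-site flip rate epsilon solved (by
`uniroot` on the haplotype-correlation identity
`rho = p(1-p)(1-2e)^2 / (q_e(1-q_e))`) so adjacent variants hit the target
r^2. Within-block variants are laid 500 bp apart and independent variants
10 kb apart, so block structure is also spatial, which the block-estimation
fixtures rely on.

What the generator emulates: exchangeable unrelated individuals,
equilibrium (or single-F inbreeding) genotype proportions, simple
rectangular LD blocks, missingness completely at random, and a logistic
disease model. What it does not: population stratification, cryptic
relatedness, realistic recombination-rate variation or LD decay,
genotyping-error structure, informative missingness. Tests passing on
these fixtures therefore certify the *algorithms* (oracle equivalence,
calibration under the stated model), not robustness of the statistics to
real-data pathologies.

Default study conditions used by the test battery: oracle-equivalence
fixtures of 30-50 samples by 100-200 variants; calibration runs of 120-150
samples by 1200-1500 variants for the Hardy-Weinberg and GRM checks; 150
null replicates of 150 samples by 40 variants at 10000 permutations for
the family-wise error check; and the full heterozygote sweep at n = 1000,
n1 = 300 for exact-test precision. These sizes keep the whole suite around
a minute while leaving every statistical bound binding.

## Degenerate inputs and edge policies

* Zero-overlap sample pairs: IBS undefined, reported `NA`.
* Monomorphic variants: rejected by the GRM (the increment divides by
  `2q(1-q)`); callers filter on `allele_frequencies()` first.
* All-missing variants: frequencies `NA` with an `all_missing` flag.
* 2x3 tables with an empty column reduce to the 2x2 test; an empty row
  margin admits one table and returns p = 1.
* Variant tables must be position-sorted for block estimation; unsorted
  input is an error rather than a silent re-sort.
* VCF import: haploid or half-missing GT entries become missing calls; GP
  fields that are not biallelic triplets are ignored; the hard-call rule
  compares the *maximum* genotype probability against the threshold (the
  alternative - requiring the GT-named genotype's own probability to pass -
  differs only for near-uniform triplets, where both readings yield a
  missing call at the default 0.9).
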