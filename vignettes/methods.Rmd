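---
title: "Models and methods behind snppop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snppop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppop)
```

snppop characterises a genotyped population from a diploid biallelic SNP
panel: diversity, divergence, realised relatedness, stratification, linkage
disequilibrium and effective population size. This vignette explains each
model, its assumptions, the tunable parameters and the numerical choices,
and what the synthetic validation does and does not demonstrate.

## Data model and quality control

A `genotype_dataset` holds B-allele dosages (0/1/2, `NA` missing) under the
Illumina AB convention, a marker map (opaque chromosome labels, 1-based
base-pair positions, strictly increasing within chromosome) and per-sample
group labels. No strand flipping or allele matching is attempted: a panel
is taken at face value, which is appropriate for single-chip studies but
not for merging panels genotyped on different platforms.

QC applies three strict-inequality filters — marker call rate, sample call
rate, MAF — in that fixed order, with allele frequencies recomputed after
sample removal because MAF depends on the surviving sample set. MAF is
defined as min(p, 1−p) on the combined panel, not per group: group-level
analyses downstream should see a common marker set. The defaults
(call rates > 0.95, MAF > 0.01) are the conventional 50K-chip settings.
Missing dosages are then replaced by the marker mean. This preserves
per-marker allele frequencies exactly and is adequate for
frequency-and-covariance statistics; it is not haplotype-based imputation
and systematically shrinks individual genotype calls toward the mean, so it
slightly attenuates LD at markers with high missingness.

## Heterozygosity and F_ST

Per marker, expected heterozygosity is the Hardy–Weinberg value
$H_{exp} = 2p(1-p)$ computed from the frequency within the chosen group,
and observed heterozygosity is the heterozygote (dosage 1) proportion.
Both are summarised as mean ± SD across markers; for biallelic markers
$H_{exp} \le 0.5$ by construction.

Divergence uses the Weir–Cockerham variance components: per marker, $a$
(among populations), $b$ (among individuals within populations) and $c$
(within individuals), combined across markers as the ratio of sums
$\theta_W = \sum_i a_i / \sum_i (a_i + b_i + c_i)$. Three implementation
points matter:

- components are summed **before** dividing — a mean of per-marker ratios
  is a different (worse) estimator, and the test suite contains a
  two-marker case where the two disagree;
- negative per-marker components are retained, because the estimator is
  defined on raw components; the aggregate can therefore be slightly
  negative when there is no true divergence (for two duplicated groups of
  size $n$ the expectation is about $-1/(2n-2)$);
- observed heterozygote proportions enter the formulas directly — no
  Hardy–Weinberg assumption is made where the observed counts are
  available.

Pairwise matrices use only the two groups of each pair, and markers
monomorphic across a pair are skipped for that pair only (the per-pair
marker count is reported). Pairs involving a singleton group are undefined
rather than silently zero.

## The genomic relationship matrix

The VanRaden GRM is
$G = (M - 2P)(M - 2P)' \,/\, 2\sum_j p_j(1-p_j)$ with $P$ repeating the
reference B-allele frequencies. When frequencies come from the included
samples themselves the centered matrix has zero column sums, so every row
and column of $G$ sums to zero — an invariant the tests assert at
$10^{-8} \times$ dimension. Genomic inbreeding is $F_{VR} = G_{ii} - 1$,
summarised per group with the grand mean diagonal as a structure
diagnostic: recomputing $G$ on a homogeneous subset (re-centering and
re-scaling on that subset's frequencies) lowers the mean diagonal relative
to slicing the full-panel matrix, because the between-group frequency
variance no longer inflates the cross-products. The package treats the
subset GRM as a first-class operation precisely because slicing is not
equivalent.

Block relatedness averages off-diagonal entries of $G$ within and between
groups, excluding the diagonal for within-group means; each group also gets
an external mean (its mean relatedness to everything outside itself), the
conventional diagonal replacement for block-matrix plots. Size-one groups
have undefined internal relatedness and are flagged.

PCA decomposes $G$ itself (not the centered genotype matrix): the two are
identical in exact arithmetic and $G$ is the declared interface. The full
symmetric eigendecomposition is used — at the panel sizes this package
targets (thousands of samples) that is well within a desktop budget, and it
makes the POV denominator (the sum of all non-negative eigenvalues) exact.
Numerically negative eigenvalues are clamped to zero for POV and counted;
component signs are fixed by making the largest-magnitude loading positive,
so scores are bit-reproducible. Scores are eigenvectors scaled by
$\sqrt{\lambda}$.

## Linkage disequilibrium and effective population size

For each marker, LD is computed against its next `max_depth` (default 400)
successors in genome order. r² is the squared Pearson correlation of
dosage vectors — composite LD. The textbook definition
$r^2 = (p_{AB} - p_A p_B)^2 / p_A(1-p_A)p_B(1-p_B)$ is haplotypic;
unphased panels cannot evaluate it directly, but under random mating the
dosage correlation converges to it, and the test suite pins that
correspondence against the phased haplotypes the Wright–Fisher simulator
retains. Pairs whose window crosses a chromosome boundary form the
non-syntenic set; pairs involving a monomorphic marker are skipped and
counted.

The syntenic decay curve restricts to markers with a full same-chromosome
successor window (on a map of $m_c$ markers per chromosome these are the
first $m_c - \text{depth}$ of each chromosome carrying more than `depth`
markers) and averages r² per depth. Depth maps to distance via a single
panel-wide constant, the mean adjacent spacing — the curve is genuinely a
function of marker rank, and the distance axis is nominal. A per-pair true
distance would be more precise locally but would mix bin populations; the
rank convention keeps every depth bin supported by the same marker set.
No estimate is attempted below one mean spacing.

Mean non-syntenic r² estimates the sampling floor, $\approx 1/N$ for $N$
samples (more precisely $1/(N-1)$ for a squared sample correlation, which
is why the floor measured at $N = 16$ sits ~7% above $1/16$). The
sample-size experiment re-estimates it on random sub-panels of
$N = 2^n$ and tabulates it against $1/N$; on unlinked markers the
regression slope is ≈ 1. The exported correction subtracts $1/N$ and
floors at zero with a flag — near the floor the correction inevitably
produces negative values, which is why flooring is explicit rather than
silent.

Each decay-curve bin converts to a recombination fraction
$c = \text{distance} \times \text{morgan\_per\_bp}$ (default
$10^{-8}$, i.e. 1 Morgan = 100 Mb — a genome-wide average; using a linkage
map would refine it), a time $t = 1/(2c)$ generations ago, and
$Ne_t = (1 - r^2)/(4 c r^2)$. The raw depth-binned mean r² is used —
the $1/N$ subtraction is available but deliberately not applied inside
`ne_from_ld`, so the trajectory matches the conventional uncorrected
procedure; at the sample sizes the size rule enforces (below) the
inflation is small relative to mid-range r². "Current" Ne is read from the
bin whose $t$ is nearest 20 generations, ties resolved toward the smaller
$t$ (the convention is a readout point, not a model statement), and the
trajectory is reported inside $t \in [2, 500]$. Bins with $r^2 = 0$
(undefined) or $r^2 = 1$ ($Ne = 0$) are flagged.

Groups smaller than 64 samples are excluded from LD/Ne reporting by
default — below that the $1/N$ floor rivals genuine short-range LD — with
an explicit per-group override for deliberate exceptions.

## The simulators and what passing tests show

**Balding–Nichols divergence.** Ancestral frequencies are uniform on
(0.1, 0.9) (configurable; the default avoids boundary monomorphism), and
each population draws its frequency from
Beta$(p(1-\theta)/\theta,\ (1-p)(1-\theta)/\theta)$, which has mean $p$
and variance $\theta p(1-p)$ — so the expected Weir–Cockerham $\theta_W$
between two populations equals $\theta$ and recovery is a clean target.
Markers are independent: this simulator validates F_ST, GRM and PCA
behaviour, not LD.

**Wright–Fisher drift with recombination.** Constant census size $N$,
random mating with replacement, non-overlapping generations, no mutation,
no selection, no sexes — so $N_e = N$ by construction. Founders carry
independent alleles at frequency 0.5; each gamete is a recombinant mosaic
of its parent's two haplotypes with per-interval crossover probability
spacing × morgan_per_bp (a small-c approximation of Haldane's map,
adequate at chip spacings where the per-interval probability is ~5×10⁻⁴).
Phased haplotypes are retained for oracle use. This generator produces
genuine drift-recombination LD whose decay encodes $N$; recovery of $N$
from the trajectory is the package's end-to-end LD validation.

**Half-sib families.** Progeny take one Mendelian gamete from a shared
sire and one from a random base dam, without linkage. The expected
additive relationship between half sibs is 0.25 above the base level.
Recovery is checked with the GRM referenced to **base-population**
frequencies: that is the frequency set under which the pedigree
expectation holds. Estimating frequencies from the combined base+progeny
panel centers G on a family-weighted sample and shrinks the measured
increment (to ≈ 0.21 under the test conditions) — a real property of
frequency-in-sample GRMs worth knowing when interpreting block means on
family-structured data.

What the simulations do **not** show: real panels have ascertainment-biased
frequency spectra, mutation, variable local recombination, overlapping
generations, selection and migration. Passing parameter recovery
demonstrates the estimators are implemented correctly, not that their
assumptions hold in any particular real population.

## Problem sizes and numerical choices

Validation runs use reduced but honest scales chosen so each estimator is
in its operating regime: F_ST recovery at 2 × 200 samples × 5,000
independent markers over multiple seeds (Monte-Carlo SD of the mean well
under the ±0.01 acceptance band); relatedness recovery at 2,000 markers
(binomial noise on a 0.25 contrast ≈ 0.01); Ne recovery at N = 100 with
2 × 500 markers at 50 kb spacing, 200 generations, LD depth 100 — depth
100 covers the reported t-window down to 10 generations at that spacing,
and the 20-generation readout sits at depth 50. The map-bookkeeping check
runs at full scale (47,789 markers, 25 chromosomes) since it is pure
counting.

Ties and degenerate inputs are resolved explicitly throughout: strictly
increasing positions are required (no tie-break is invented for duplicate
positions); chromosome order is numeric when all labels parse as numbers,
lexicographic otherwise; QC uses strict inequalities; empty panels, fully
missing markers, singleton groups, single-chromosome non-syntenic requests
and monomorphic denominators all raise explicit errors or flagged
undefined values rather than silent zeros.

Every simulator and the pipeline are bit-reproducible given (parameters,
seed); the pipeline derives per-stage seeds deterministically from one
master seed so stages can be re-run in isolation. Pipeline tables are
byte-identical across repeated runs of the same configuration — the run
manifest (which carries wall-clock timestamps) is the only file excluded
from that guarantee.

## Known limitations

- Composite (dosage) r² ≈ haplotype r² relies on random mating; strong
  inbreeding or assortative mating breaks the correspondence.
- Mean imputation attenuates LD through imputed cells; panels with heavy
  missingness should be imputed with a haplotype-aware tool upstream.
- The distance axis of decay curves is nominal (rank × mean spacing);
  regional recombination-rate variation is invisible to it.
- The Ne formula assumes drift-recombination equilibrium at each $c$;
  recent admixture or bottlenecks distort the trajectory in ways the
  package does not correct.
- No VCF ingestion, no intensity-based QC, no phasing, and no
  model-based ancestry decomposition — the scope is descriptive panel
  statistics on called genotypes.
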