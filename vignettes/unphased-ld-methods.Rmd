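---
title: "Measuring linkage disequilibrium of deleterious alleles from unphased genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linkage disequilibrium of deleterious alleles from unphased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unphasedLD)
```

## The problem

Negative selection does not only remove deleterious alleles — it also
shapes how they are *arranged* across individuals. Under synergistic
epistasis (carrying two deleterious alleles costs more than the product of
their individual costs) and under Hill–Robertson interference among linked
selected sites, selection preferentially removes genomes that carry
several deleterious alleles together. The surviving population then shows
*negative linkage disequilibrium* among deleterious variants: derived
alleles are spread over different individuals more evenly than expected
under independence. The strength of that repulsion is a readout of how
effectively selection is acting — a quantity of direct interest in
conservation genetics, where one wants to compare the mutation burden of
small, threatened populations.

The classical pairwise LD statistics $D$, $D'$ and $r^2$ need haplotype
frequencies, and phasing is exactly what is *not* available for most
non-model species. This package implements set-level LD statistics that
work directly on unphased diploid genotypes.

## The statistics

Let $X_i \in \{0, 1, 2\}$ be the derived-allele dosage at locus $i$ in a
sample of $n$ diploids, and let $L$ be a set of $m$ loci (for example all
loss-of-function doubletons). The core statistic is the averaged pairwise
standardised covariance

$$\mathrm{LDcor}_L \;=\; \binom{m}{2}^{-1} \sum_{i<j \in L}
  \frac{\operatorname{cov}(X_i, X_j)}{\sigma(X_i)\,\sigma(X_j)},$$

i.e. the mean Pearson correlation of dosages over all pairs in the set,
with range $[-1, 1]$. Its companions are

* $\mathrm{LDcorabs}_L$: the mean *absolute* correlation, in $[0, 1]$,
  zero iff every pair is uncorrelated, always $\ge \mathrm{LDcor}_L$;
* $\mathrm{nLDcor}_L = \mathrm{LDcor}_L - \mathrm{LDcor}_S$ for a null set
  $S$ (synonymous variants in empirical work), which removes the
  species-wide baseline LD produced by demography and makes values
  comparable across populations;
* $\mathrm{NetLD}_L$: the unstandardised mean pairwise covariance, kept as
  the frequency-sensitive comparator.

For a pair of loci the dosage correlation estimates the haplotype-level
correlation $r = D / \sqrt{p_A p_a p_B p_b}$ signed by $D$ (derived–derived
coupling positive), which is why LDcor tracks the mean *signed*
$\sqrt{r^2}$ computed from true haplotypes without needing phase. The
package carries both routes — `ldcor()` on dosages, `signed_sqrt_r2_mean()`
on phased haplotypes — so the consistency can be measured rather than
assumed; `scripts/acceptance.R` recomputes exactly that correlation.

### Averaging convention

The pair average uses the number of loci $m$ in the prefactor
$2/(m(m-1))$. With this convention the stated range $[-1, 1]$ holds for
any set. Reading the prefactor's $n$ as the number of *individuals* would
not bound the statistic, so the loci-count reading is used throughout and
recorded here as a deliberate interpretation.

### $V/V_A$: two readings

For the burden $Z = \sum_j X_j$, the package reports both the literal
formula $(m(m-1)/2 \cdot \mathrm{NetLD} + V_A)/V_A$ and the empirical
ratio $\operatorname{Var}(Z)/V_A$. These disagree whenever NetLD $\ne 0$:
the variance decomposition $\operatorname{Var}(Z) = V_A + 2\sum_{i<j}
\operatorname{cov}(X_i, X_j)$ carries a factor 2 on the covariance term
that the first form omits. Rather than silently "fixing" either reading,
`v_over_va()` returns both.

### Moment conventions

All variances and covariances are sample moments with the $n-1$
denominator. Correlations — and therefore LDcor, LDcorabs and nLDcor —
are invariant to that choice; NetLD and $V_A$ are not, and the convention
is recorded in every result object.

## Computation

The sum of pairwise correlations over a complete set obeys
$\sum_{i<j} \operatorname{cor}(X_i, X_j) =
\left(\operatorname{Var}(\sum_j Z_j) - m\right)/2$ on unit-standardised
columns $Z_j$, which turns an $O(nm^2)$ computation into $O(nm)$. The
fast path is used whenever the pair filter admits all pairs and is tested
against the explicit pairwise loop to $10^{-10}$. No such identity exists
for LDcorabs (the absolute value breaks the telescoping), so it iterates
pairs, with a seeded uniform subsample of pairs above $5 \times 10^6$
pairs — the practical route for sets like a species-wide synonymous
catalogue, whose pair count is otherwise astronomical. Subsampling is
always recorded in the result.

Pairs can be restricted by physical distance (`pair_filter()`);
cross-chromosome pairs count as infinitely distant, so they satisfy any
minimum-distance bound and fail any finite maximum. Degenerate inputs
fail loudly: sets with fewer than two loci, constant dosage columns
(zero variance), and filters that exclude every pair are errors, not
silent NAs.

## Ingestion and locus sets

`read_vcf_genotypes()` applies the quality-control battery standard for
population resequencing: biallelic SNPs only, no missing genotypes,
site QUAL ≥ 20, mapping quality MQ ≥ 40, per-sample depth ≥ 3, site mean
depth at most 250% of the dataset-wide mean, and an exact Hardy–Weinberg
test at $P < 10^{-6}$ (all thresholds configurable). The HWE test is the
exact conditional-on-allele-counts test, two-sided by summing
configurations no more probable than the observed one; it agrees with an
independent matching-count enumeration to $10^{-12}$ in the test suite.

Polarisation consumes an ancestral-allele map (TSV or prior annotation):
when the ancestral allele equals REF the ALT dosage already counts derived
alleles, when it equals ALT the dosage flips to $2 - d$, and loci whose
ancestral state matches neither allele are dropped, as are loci
monomorphic after polarisation. Functional categories come from a TSV or
from VEP-style `CSQ` fields, with loss-of-function defined as the union
of stop-gained, stop-lost, splice-acceptor and splice-donor; when several
transcripts disagree, the most severe consequence wins.

Because LD statistics are frequency-sensitive, locus sets are conditioned
on the derived-allele spectrum: `select_locus_set()` bounds the derived
allele count (dac) from below (`min_dac = 2` by default — doubletons are
abundant, informative about selection, and less error-prone than
singletons) and from above via a maximum dac or maximum derived allele
frequency (MDAC / MDAF), so that sets being compared live on comparable
spectra.

## Sampling noise of D, exactly

Even with no true association, the observed $D$ of two unlinked loci in a
finite sample is almost never zero. `enumerate_unlinked_d_distribution()`
computes its exact distribution: with derived counts fixed at both loci,
every haplotype table with the right margins receives probability
proportional to its multinomial arrangement count, each table yields one
$D$, and equal-$D$ entries are merged. The enumeration is at the
haplotype level (4 classes over $2N$ gametes), which reproduces the
random-union-of-gametes model; the 9-class diploid likelihood is exposed
separately (`two_locus_diploid_loglik()`) for a user-supplied haplotype
frequency vector. The distribution always integrates to 1 with mean
exactly 0, and matches Monte-Carlo gamete pairing in the tests.

## Inference by spectrum-matched resampling

To ask whether a deleterious set's LD differs from the neutral
expectation, `daf_matched_resample()` draws replicate null sets from a
pool (synonymous loci) with *exactly* the target's dac histogram —
matching on exact counts rather than binned frequencies, with optional
binning for sparse pools — and `permutation_pvalue()` applies the add-one
convention $p = (1 + \#\{\text{null} \le \text{obs}\})/(R + 1)$, which
cannot return zero and is exact under exchangeability. Sidedness is never
guessed: lower, upper and two-sided p-values are all reported. The default
of 100 resamples matches standard practice for these permutation designs.

## The forward simulator

Validation needs populations whose true selective and epistatic regime is
known, so the package ships a native forward-in-time Wright–Fisher
simulator rather than wrapping an external one: diploid random mating
with fitness-proportional parent sampling, per-gamete Poisson
recombination, infinite-sites mutation at rate $\mu$ per bp per
generation with a configurable neutral fraction, multi-epoch demography
with migration, and instantaneous bottlenecks via random subsetting.
Fitness is

$$w = \prod_j w_j \cdot (1-\varepsilon)^{k(k-1)/2},$$

with $w_j = 1+s$ (homozygous derived), $1+hs$ (heterozygous), $1$
otherwise, and $k$ the individual's count of deleterious allele copies.
The pairwise $(1-\varepsilon)$ penalty makes log fitness quadratic in the
burden — the standard synergistic-epistasis model, chosen here as the
functional form because it is the canonical way to induce the
epistasis-driven repulsion the statistics are meant to detect; a variant
counting affected *loci* instead of allele copies is available via
`epistasis_count = "loci"`. Direction-of-effect claims, not numerical
equality to any particular epistasis implementation, are what the
validation suite asserts.

The single-deme generation kernel is implemented in C++ (sites are byte
columns; crossover mosaics are resolved per site from the crossover
positions, so column order is free and new mutations append in O(1));
the multi-deme path with migration runs in R. All randomness flows
through R's RNG, so every run is reproducible from its seed.

**Rescaling.** `scaling_factor` $Q$ divides $N$, epoch durations and the
burn-in by $Q$ and multiplies $\mu$, $r$, $s$ and $\varepsilon$ by $Q$,
preserving $4N\mu$, $4Nr$, $2Ns$ and the per-generation epistatic load.
This is the standard device for desk-scale forward simulation; it is also
why the strongest nominal selection coefficients saturate (a nominal
$s = -0.1$ at $Q = 10$ becomes $s = -1$), which thins the conditioned
deleterious sets in those cells.

**Burn-in.** 10 N generations from an empty state before any epoch,
configurable. Low-frequency variants — the ones the conditioned sets are
built from — equilibrate much faster than that, so this is conservative.

**Calibration.** The simulator is validated against closed-form
population genetics rather than against another simulator: mean
segregating sites in neutral runs match Watterson's
$\theta \sum_{i=1}^{2n-1} 1/i$; the fixation probability of a new neutral
mutant matches $1/(2N)$; allele frequencies without selection are
martingales. These checks exercise the same compiled kernel used by every
simulation.

**Demography presets.** "Model 1" is the constant-size population. The
expansion and expansion-plus-gene-flow presets (`gravel_human_epochs()`)
are piecewise-constant approximations of the published three-population
human demographic model of Gravel et al. (2011), shipped as editable
externally-sourced configurations; the validation experiments use model 1
and generic epochs only.

## What the validation shows — and what it does not

The simulation experiments reproduce *directions*, at desk scale:
LDcor of spectrum-conditioned deleterious sets falls as synergistic
epistasis strengthens and (across the usable selection range) as
selection strengthens; bottlenecks raise LDcor the deeper and longer they
are; neutral sets centre on zero; and per-replicate LDcor tracks the
phased mean signed $\sqrt{r^2}$ with a Pearson correlation well above
0.85. Problem sizes are chosen once as the package's study conditions:
populations of 500–1000 (after rescaling from nominal sizes with
$Q = 5$–$10$), 50–100 kb of sequence, 30–60 replicates per grid cell, and
spectrum conditioning mirroring the design that motivates the statistics
(MDAF ≤ 5% for the selection and epistasis grids; MDAF ≤ 25% for the
20-diploid bottleneck samples, whose spectra are coarser; doubletons for
the doubleton-specific comparison).

What passing these tests does *not* show: desk-scale simulations have
far less mutational input than a 1 Mb, $N = 10^4$, $10^5$-generation
regime, so per-replicate locus sets are small and cells under the
strongest selection ($2Ns \sim 10^3$) may contribute few usable
replicates; empirical species values depend on real genome data,
alignment-based ancestral-allele calls and VEP annotations that are out
of scope here — the package ships the full pipeline for them but no
claims about their values. The synthetic-genotype generator
(`synth_genotype_matrix()`) produces exchangeable individuals with a
single global correlation parameter and an exact dac spectrum; it
emulates none of the positional structure (distance decay,
recombination-rate variation) of real genomes and is meant for unit
calibration, not realism.

## Numerical choices

* Exact enumeration is guarded at $2N \le 60$; beyond that the
  state space is astronomical and Monte-Carlo is the right tool.
* HWE two-sidedness includes ties (configurations with probability equal
  to the observed one, up to $10^{-12}$ relative slack).
* Fitness is floored at $10^{-12}$ per locus in log space so that lethal
  rescaled coefficients cannot produce $-\infty \times 0$ artefacts.
* Pair subsampling deduplicates draws, so it is without replacement in
  effect; the subsample size and seed are part of the result.
* `ldcorabs` defaults to subsampling only beyond $5 \times 10^6$ pairs,
  which keeps every desk-scale computation exact.
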