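# unphasedLD

Linkage disequilibrium of deleterious alleles, measured directly from
unphased genotypes.

## The problem

In small or threatened populations, the health of the gene pool depends
not only on how many deleterious mutations segregate but on how they are
arranged across individuals. Negative selection — especially with
synergistic epistasis, and through Hill–Robertson interference among
linked sites — preferentially removes genomes carrying several
deleterious alleles at once, leaving the survivors with deleterious
alleles in *repulsion*: negative linkage disequilibrium. Measuring that
repulsion genome-wide is a way to compare selection intensity across
species. The classical statistics ($D$, $D'$, $r^2$) need phased
haplotypes, which conservation datasets rarely have.

`unphasedLD` is for population geneticists who have diploid VCFs,
ancestral-allele calls and functional annotations, and want set-level LD
statistics that skip phasing entirely.

## The statistics

For derived-allele dosages $X_i \in \{0,1,2\}$ and a locus set $L$ of
size $m$:

- **LDcor** $= \binom{m}{2}^{-1} \sum_{i<j \in L}
  \operatorname{cov}(X_i,X_j) / (\sigma(X_i)\sigma(X_j))$ — mean pairwise
  dosage correlation, in $[-1, 1]$; negative = net repulsion.
- **LDcorabs** — mean absolute correlation, in $[0, 1]$; zero iff all
  pairs are uncorrelated; always $\ge$ LDcor.
- **nLDcor** $=$ LDcor(target) $-$ LDcor(null) — baseline-corrected
  against a nearly neutral (synonymous) set; cross-species comparable.
- **NetLD** — mean pairwise raw covariance (unstandardised comparator).

Around them sit: VCF ingestion with QUAL/MQ/depth/HWE filters and
ancestral-allele polarisation; derived-allele-count conditioned locus
sets; the exact finite-sample distribution of $D$ for two unlinked loci;
derived-allele-frequency-matched resampling with permutation p-values;
and a forward Wright–Fisher simulator (selection, dominance, synergistic
epistasis, recombination, demography, bottlenecks) used to validate the
statistics against known regimes.

## Worked example

```r
library(unphasedLD)

# simulate a cohort under moderate selection instead of reading a VCF:
cfg <- sim_config(N = 2000, seq_length = 2e5, mu = 1.5e-8,
                  rec_rate = 1e-8, s = -1e-2, neutral_fraction = 0.5,
                  sample_n = 200, scaling_factor = 4, seed = 7)
gm  <- simulate_population(cfg)
gm
#> genotype_matrix: 200 individuals x 89 loci
#>   chrom(s): sim1
#>   dac range: 1 - 355
#>   categories: deleterious=28, neutral=61

del  <- select_locus_set(gm, category = "deleterious", mdaf = 0.05,
                         drop_constant = TRUE)
neut <- select_locus_set(gm, category = "neutral", mdaf = 0.05,
                         drop_constant = TRUE)
ldcor(del)
#> ldcor = 0.0100301  (set 'deleterious', 16 loci, 120 pairs, fast path)
ldcor(neut)
#> ldcor = 0.021145  (set 'neutral', 29 loci, 406 pairs, fast path)
nldcor(ldcor(del), ldcor(neut))
#> [1] -0.0111149
```

Both low-frequency sets carry the positive baseline LD that tight linkage
and drift produce, but the deleterious-class set sits *below* the neutral
baseline: `nLDcor < 0`, the signature of negative selection thinning out
co-occurring deleterious alleles. A permutation test against
frequency-matched neutral nulls attaches p-values to that comparison:

```r
ld_permutation_test(del, neut, n_reps = 100, seed = 1, bin_width = 4)
#>   statistic   observed null_mean    null_sd   p_lower   p_upper     p_two
#> 1     ldcor 0.01003008 0.0118296 0.01480275 0.5445545 0.4653465 0.9306931
```

(here one 200 kb replicate is far from significant — single desk-scale
regions are noisy, which is exactly why the statistics are averaged over
genome-wide sets in real data).

For empirical data the same pipeline starts from files:
`read_vcf_genotypes()` → `polarize_to_derived()` →
`apply_annotations()` → `select_locus_set()` → `ldcor()` /
`ld_permutation_test()`.

## Command line

A thin executable (`exec/unphasedld`) exposes the same pipeline:

```
unphasedld compute  --vcf cohort.vcf --ancestral aa.tsv \
                    --annotations ann.tsv --permutations 100 --out out/
unphasedld simulate --config sim.yaml --seed 1 --out sim/
unphasedld sweep    --config sim.yaml --s-grid 0,-1e-3,-1e-2 --reps 30 --out sweep/
unphasedld resample --matrix sim/genotypes.tsv --target-category LoF --out rs/
unphasedld exact-d  --n 2 --dac1 1 --dac2 1
unphasedld fixtures make --out fixtures/
```

`compute` writes `ld_results.tsv` (columns: set, statistic, n_loci,
n_pairs, value, computation path), optional `permutation_tests.tsv`
(observed value, null mean/s.d., lower/upper/two-sided p-values), and a
`manifest.json` recording resolved parameters, seed, package version and
input checksums. Exit codes: 0 success, 1 data error, 2 usage error.

## Scope

Read mapping, variant calling, genome alignment, ancestral-state
reconstruction and running VEP are out of scope: the package consumes
their outputs (VCF, ancestral TSV, annotation TSV or CSQ field).
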