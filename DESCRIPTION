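Package: unphasedLD
Title: Linkage Disequilibrium of Deleterious Alleles from Unphased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes set-level linkage disequilibrium statistics for derived
    (and in particular deleterious) alleles directly from unphased diploid
    genotypes: LDcor (mean pairwise dosage correlation), LDcorabs (mean
    absolute correlation), their null-normalised forms nLDcor and nLDcorabs,
    NetLD (mean pairwise raw dosage covariance), and the classical two-locus
    statistics D, D' and r-squared. Includes VCF ingestion with site-quality,
    depth, biallelic and Hardy-Weinberg filtering, ancestral-allele
    polarisation and functional-category locus sets; the exact distribution
    of observed D for two unlinked loci in a finite sample; derived-allele
    frequency matched resampling with permutation tests; a forward-in-time
    diploid Wright-Fisher simulator with selection, dominance, synergistic
    epistasis, recombination, multi-epoch demography, migration and
    bottlenecks; and deterministic synthetic-genotype generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
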