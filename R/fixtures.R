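#' Synthetic genotype matrix with controllable pairwise LD
#'
#' Deterministic generator for tests and demos. 2n latent haplotypes are
#' built by copying a template haplotype with per-locus resampling: at
#' locus j each haplotype copies the template allele with probability
#' sqrt(rho) and otherwise draws a fresh Bernoulli(dac_j / 2n) allele,
#' which gives an expected pairwise haplotype (and, after random pairing
#' into diploids, dosage) correlation of rho between loci of equal allele
#' frequency. The exact derived-allele-count spectrum is enforced by
#' per-locus rejection. Negative rho is only attainable for a single pair
#' of loci (the second locus copies the complemented template); requesting
#' it for more loci is an error, as is a spectrum for which rejection does
#' not terminate.
#'
#' @param n_individuals diploid sample size n
#' @param dac_spectrum integer vector of derived allele counts, one per
#'   locus (each in 1..2n-1)
#' @param rho target expected pairwise dosage correlation, in (-1, 1)
#' @param seed integer seed; same seed, same matrix
#' @param max_tries rejection cap per locus
#' @return a [genotype_matrix()] with phased haplotypes attached as
#'   `attr(, "haplotypes")`; loci are placed 100 bp apart on "synth1"
#' @export
synth_genotype_matrix <- function(n_individuals, dac_spectrum, rho = 0,
                                  seed = 1L, max_tries = 10000L) {
  n2 <- 2L * n_individuals
  m <- length(dac_spectrum)
  stopifnot(m >= 1, all(dac_spectrum >= 1), all(dac_spectrum <= n2 - 1),
            rho > -1, rho < 1)
  if (rho < 0 && m > 2) {
    stop("infeasible rho: a common negative pairwise correlation is only ",
         "attainable for 2 loci")
  }
  phi <- sqrt(abs(rho))
  with_seed(seed, {
    p_t <- mean(dac_spectrum) / n2
    template <- as.integer(stats::runif(n2) < p_t)
    H <- matrix(0L, n2, m)
    for (j in seq_len(m)) {
      d <- dac_spectrum[j]
      p <- d / n2
      tem <- if (rho < 0 && j == 2L) 1L - template else template
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        copy <- stats::runif(n2) < phi
        hap <- ifelse(copy, tem, as.integer(stats::runif(n2) < p))
        if (sum(hap) == d) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("infeasible spectrum: could not realise dac = ", d,
             " at locus ", j, " within ", max_tries, " tries")
      }
      H[, j] <- hap
    }
    H <- H[sample.int(n2), , drop = FALSE]   # random pairing into diploids
    dos <- H[seq(1L, n2, 2L), , drop = FALSE] +
      H[seq(2L, n2, 2L), , drop = FALSE]
    gm <- genotype_matrix(
      dos, data.frame(chrom = rep("synth1", m), pos = 100L * seq_len(m),
                      ref = rep("A", m), alt = rep("G", m),
                      stringsAsFactors = FALSE))
    attr(gm, "haplotypes") <- H
    gm
  })
}

#' Write a genotype matrix as a VCF
#'
#' Serialises dosages as unphased GT calls (0/0, 0/1, 1/1) with constant
#' QUAL, INFO MQ and per-sample DP, so the file round-trips through
#' [read_vcf_genotypes()] with default filters. The ALT allele carries the
#' dosage; for simulated (already polarised) matrices REF is therefore the
#' ancestral allele.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param qual,mq,dp constant site QUAL, INFO MQ and per-sample depth
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path, qual = 99, mq = 60, dp = 30) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ref <- gm$loci$ref %||% rep("A", n_loci(gm))
  alt <- gm$loci$alt %||% rep("G", n_loci(gm))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"))
  for (j in seq_len(n_loci(gm))) {
    cells <- paste0(gt_str[gm$dosages[, j] + 1L], ":", dp)
    lines <- c(lines, paste(c(
      gm$loci$chrom[j], format(round(gm$loci$pos[j]), scientific = FALSE),
      ".", ref[j], alt[j], qual, "PASS", paste0("MQ=", mq), "GT:DP",
      cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the hand-crafted fixture files
#'
#' Creates, in `dir`, a small set of plain-text inputs that exercise every
#' ingestion branch: `filters.vcf` (a good site plus sites failing each
#' filter: missing genotype, triallelic, low QUAL, low MQ, low and
#' excessive depth), `hwe.vcf` (20 samples, one site with a gross
#' heterozygote deficit), `ancestral.tsv` (ancestral equal to REF, to ALT,
#' and unresolvable "N") and `annotations.tsv` (synonymous / missense /
#' LoF labels). The same files ship under `inst/extdata/`.
#'
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture_set <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  row <- function(chrom, pos, ref, alt, qual, mq, ...) {
    paste(c(chrom, pos, ".", ref, alt, qual, "PASS", paste0("MQ=", mq),
            "GT:DP", ...), collapse = "\t")
  }
  writeLines(c(
    hdr,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    row("chr1", 100, "A", "G", 99, 60, "0/1:30", "1/1:30"),   # kept
    row("chr1", 200, "C", "T", 99, 60, "./.:30", "0/1:30"),   # missing GT
    row("chr1", 300, "G", "A,T", 99, 60, "0/1:30", "0/2:30"), # triallelic
    row("chr1", 400, "T", "C", 10, 60, "0/1:30", "0/0:30"),   # low QUAL
    row("chr1", 500, "A", "C", 99, 10, "0/1:30", "0/0:30"),   # low MQ
    row("chr1", 600, "G", "T", 99, 60, "0/1:1", "0/1:30"),    # low DP
    row("chr1", 700, "C", "G", 99, 60, "0/1:300", "0/1:300"), # high DP
    row("chr1", 800, "T", "A", 99, 60, "1/1:30", "0/1:30")    # kept
  ), file.path(dir, "filters.vcf"))

  n <- 24
  hom_split <- c(rep("0/0:30", 12), rep("1/1:30", 12))  # no heterozygotes
  het_ok <- rep(c("0/1:30", "0/0:30"), 12)
  writeLines(c(
    hdr,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:n)), collapse = "\t"),
    row("chr1", 100, "A", "G", 99, 60, het_ok),
    row("chr1", 200, "C", "T", 99, 60, hom_split),
    row("chr1", 300, "G", "A", 99, 60, rev(het_ok))
  ), file.path(dir, "hwe.vcf"))

  writeLines(c(
    "# chrom\tpos\tancestral",
    "chr1\t100\tA",      # == REF: dosage unchanged
    "chr1\t800\tA",      # == ALT: dosage flipped
    "chr1\t900\tN"),     # unresolvable: locus dropped
    file.path(dir, "ancestral.tsv"))

  writeLines(c(
    "# chrom\tpos\tcategory",
    "chr1\t100\tsynonymous",
    "chr1\t800\tLoF"),
    file.path(dir, "annotations.tsv"))
  invisible(dir)
}
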