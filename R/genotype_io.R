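#' Read diploid genotypes from a VCF into a dosage matrix
#'
#' Parses a VCF (v4.x, plain or bgzipped) and returns the ALT-allele dosage
#' matrix for the sites that pass the quality-control filters used for
#' population-level LD work:
#' \itemize{
#'   \item biallelic SNPs only (single-nucleotide REF and ALT, one ALT);
#'   \item no missing genotypes at the site;
#'   \item site `QUAL >= min_qual` and INFO `MQ >= min_mq` (a missing QUAL
#'     or MQ annotation passes, as in datasets that do not report them);
#'   \item per-sample depth `DP >= min_dp` for every sample, and site mean
#'     depth at most `max_dp_frac` times the dataset-wide mean depth
#'     (skipped when the VCF carries no FORMAT/DP);
#'   \item exact Hardy-Weinberg test p-value `>= hwe_p`.
#' }
#' Dosages count the ALT allele; polarisation to the derived allele is a
#' separate step ([polarize_to_derived()]). Filter counts are reported via
#' `message()`.
#'
#' @param path VCF file path
#' @param min_qual minimum site QUAL (phred)
#' @param min_mq minimum INFO mapping quality
#' @param min_dp minimum per-sample depth
#' @param max_dp_frac maximum site mean depth as a multiple of the
#'   dataset-wide mean depth
#' @param hwe_p Hardy-Weinberg exact-test exclusion threshold; sites with
#'   p < `hwe_p` are removed. `NULL` disables the test.
#' @return a [genotype_matrix()] (loci carry `chrom`, `pos`, `ref`, `alt`)
#' @export
read_vcf_genotypes <- function(path, min_qual = 20, min_mq = 40,
                               min_dp = 3, max_dp_frac = 2.5,
                               hwe_p = 1e-6) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  stopifnot(min_qual >= 0, min_mq >= 0, min_dp >= 0, max_dp_frac >= 0)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop("failed to parse VCF '", path, "': ",
                       conditionMessage(e))
                })
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  if (n_in == 0L) stop("no sites surviving filters: VCF has no records")

  nuc <- c("A", "C", "G", "T")
  biallelic <- fix[, "REF"] %in% nuc & fix[, "ALT"] %in% nuc
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual_ok <- is.na(qual) | qual >= min_qual
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  if (length(mq) == 0L) mq <- rep(NA_real_, n_in)
  mq_ok <- is.na(mq) | mq >= min_mq

  gt <- vcfR::extract.gt(v, "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_in)
  alleles <- gsub("[|]", "/", gt)
  miss <- is.na(alleles) | grepl("\\.", alleles)
  complete <- rowSums(miss) == 0L
  dos <- matrix(0L, nrow = n_in, ncol = ncol(gt))
  ok_rows <- which(complete)
  if (length(ok_rows)) {
    a1 <- substr(alleles[ok_rows, , drop = FALSE], 1, 1)
    a2 <- substr(alleles[ok_rows, , drop = FALSE], 3, 3)
    dos[ok_rows, ] <- (a1 == "1") + (a2 == "1")
  }

  dp_ok <- rep(TRUE, n_in)
  fmt_dp <- "DP" %in% unlist(strsplit(unique(v@gt[, 1]), ":"))
  if (fmt_dp) {
    dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = n_in)
    mean_dp <- mean(dp, na.rm = TRUE)
    site_min <- apply(dp, 1, function(z) min(z, na.rm = TRUE))
    site_mean <- rowMeans(dp, na.rm = TRUE)
    dp_ok <- !is.na(site_min) & site_min >= min_dp &
      site_mean <= max_dp_frac * mean_dp
  }

  keep <- biallelic & qual_ok & mq_ok & complete & dp_ok
  # HWE on sites still in play
  hwe_fail <- rep(FALSE, n_in)
  if (!is.null(hwe_p)) {
    for (i in which(keep)) {
      d <- dos[i, ]
      p <- hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
      if (p < hwe_p) hwe_fail[i] <- TRUE
    }
  }
  keep <- keep & !hwe_fail
  message(sprintf(paste0(
    "read_vcf_genotypes: %d records; removed %d non-biallelic-SNP, ",
    "%d low-QUAL, %d low-MQ, %d with missing genotypes, %d depth-filtered, ",
    "%d HWE-failing; %d kept"),
    n_in, sum(!biallelic), sum(biallelic & !qual_ok),
    sum(biallelic & qual_ok & !mq_ok),
    sum(biallelic & qual_ok & mq_ok & !complete),
    sum(biallelic & qual_ok & mq_ok & complete & !dp_ok),
    sum(hwe_fail), sum(keep)))
  if (!any(keep)) stop("no sites surviving filters in ", path)

  genotype_matrix(
    t(dos[keep, , drop = FALSE]),
    data.frame(chrom = fix[keep, "CHROM"],
               pos = as.integer(fix[keep, "POS"]),
               ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
               stringsAsFactors = FALSE),
    sample_ids = colnames(gt))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditional on the observed allele counts: under random union
#' of gametes, the probability of h heterozygotes given n diploids and n1
#' copies of the rarer allele is
#' \deqn{P(h) = \frac{n!\, 2^h\, n_1!\, n_2!}{h!\,
#'   \frac{n_1-h}{2}!\, \frac{n_2-h}{2}!\, (2n)!}.}
#' The two-sided p-value sums the probabilities of all heterozygote
#' configurations no more likely than the observed one (ties included).
#'
#' @param n_hom_ref,n_het,n_hom_alt observed genotype counts
#' @return two-sided exact p-value in (0, 1]; 1 for monomorphic sites
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("no genotypes: all counts zero")
  n_alt <- 2 * n_hom_alt + n_het
  n1 <- min(n_alt, 2 * n - n_alt)   # rarer allele copies
  n2 <- 2 * n - n1
  if (n1 == 0) return(1.0)          # monomorphic: single configuration
  hs <- seq(n1 %% 2, n1, by = 2)    # feasible heterozygote counts
  logp <- lfactorial(n) + hs * log(2) + lfactorial(n1) + lfactorial(n2) -
    lfactorial(hs) - lfactorial((n1 - hs) / 2) - lfactorial((n2 - hs) / 2) -
    lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Ancestral-allele map
#'
#' A lookup from (chrom, pos) to the single-nucleotide ancestral allele,
#' used to polarise ALT dosages into derived-allele dosages.
#'
#' @param chrom,pos,allele parallel vectors
#' @return an object of class `ancestral_map`
#' @export
ancestral_map <- function(chrom, pos, allele) {
  allele <- toupper(as.character(allele))
  if (!all(nchar(allele) == 1L)) {
    stop("ancestral alleles must be single nucleotides")
  }
  structure(list(key = paste(chrom, pos, sep = ":"), allele = allele),
            class = "ancestral_map")
}

#' Read an ancestral-allele TSV (chrom, pos, allele; '#' comments)
#'
#' @param path tab-separated file with columns chrom, pos, ancestral allele
#' @return an [ancestral_map()]
#' @export
read_ancestral_tsv <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "allele"))
  ancestral_map(df$chrom, df$pos, df$allele)
}

#' Polarise ALT dosages to derived-allele dosages
#'
#' For each locus, looks up the ancestral allele: if it equals REF the ALT
#' dosage already counts derived alleles; if it equals ALT the dosage is
#' flipped to 2 - dosage; if it matches neither allele, or the site has no
#' ancestral annotation, the locus is dropped. Loci monomorphic after
#' polarisation are dropped as well. Drop counts are reported via
#' `message()`.
#'
#' @param gm a [genotype_matrix()] with ALT-counted dosages and `ref`/`alt`
#'   locus metadata
#' @param aa an [ancestral_map()]
#' @return a [genotype_matrix()] of derived-allele dosages
#' @export
polarize_to_derived <- function(gm, aa) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(aa, "ancestral_map"))
  if (!all(c("ref", "alt") %in% names(gm$loci))) {
    stop("genotype matrix lacks ref/alt metadata")
  }
  key <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")
  anc <- aa$allele[match(key, aa$key)]
  is_ref <- !is.na(anc) & anc == gm$loci$ref
  is_alt <- !is.na(anc) & anc == gm$loci$alt
  dos <- gm$dosages
  dos[, is_alt] <- 2L - dos[, is_alt, drop = FALSE]
  keep <- is_ref | is_alt
  dac <- colSums(dos)
  poly <- dac >= 1L & dac <= 2L * nrow(dos) - 1L
  message(sprintf(paste0(
    "polarize_to_derived: %d loci; %d without usable ancestral allele, ",
    "%d monomorphic after polarisation; %d kept"),
    ncol(dos), sum(!keep), sum(keep & !poly), sum(keep & poly)))
  keep <- keep & poly
  genotype_matrix(dos[, keep, drop = FALSE],
                  gm$loci[keep, setdiff(names(gm$loci), "dac"),
                          drop = FALSE],
                  gm$sample_ids)
}

#' Select a locus set by category and derived-allele-count bounds
#'
#' Builds the locus set an LD statistic is averaged over: loci of a given
#' functional category whose derived allele count (dac) satisfies
#' `min_dac <= dac`, `dac <= mdac` and `dac/(2n) <= mdaf`. The default
#' `min_dac = 2` starts at doubletons, the most frequent variant class
#' after singletons and the one least affected by genotyping error.
#' `mdac = NULL` with `mdaf = NULL` is the maximum-MDAC level: every
#' polymorphic locus with dac >= `min_dac`.
#'
#' @param gm a polarised [genotype_matrix()]
#' @param category category label to select, or `NULL` for all loci
#' @param mdac maximum derived allele count, or `NULL` for no bound
#' @param mdaf maximum derived allele frequency (of 2n), or `NULL`
#' @param min_dac minimum derived allele count (default 2: doubletons up)
#' @param drop_constant drop loci whose dosage column is constant (e.g. all
#'   heterozygous), which carry no correlation information
#' @return a [locus_set()]
#' @export
select_locus_set <- function(gm, category = NULL, mdac = NULL, mdaf = NULL,
                             min_dac = 2, drop_constant = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), min_dac >= 1)
  keep <- rep(TRUE, n_loci(gm))
  if (!is.null(category)) {
    if (!"category" %in% names(gm$loci)) {
      stop("genotype matrix carries no category annotations")
    }
    keep <- keep & !is.na(gm$loci$category) & gm$loci$category == category
  }
  dac <- gm$loci$dac
  keep <- keep & dac >= min_dac
  if (!is.null(mdac)) keep <- keep & dac <= mdac
  if (!is.null(mdaf)) keep <- keep & dac / (2 * n_ind(gm)) <= mdaf
  if (drop_constant && any(keep)) {
    v <- colVars(gm$dosages[, keep, drop = FALSE])
    keep[keep] <- v > 0
  }
  if (sum(keep) < 2L) {
    stop("insufficient loci: ", sum(keep), " loci match ",
         if (is.null(category)) "all categories" else category,
         " with dac in [", min_dac, ", ", mdac %||% "Inf", "]")
  }
  locus_set(gm, which(keep), label = category %||% "all",
            mdac = mdac, mdaf = mdaf)
}

# severity order used when one variant has several annotations
.category_rank <- c(LoF = 3L, missense = 2L, synonymous = 1L)

.lof_terms <- c("stop_gained", "stop_lost",
                "splice_acceptor_variant", "splice_donor_variant")

csq_term_category <- function(terms) {
  if (any(terms %in% .lof_terms)) return("LoF")
  if ("missense_variant" %in% terms) return("missense")
  if ("synonymous_variant" %in% terms) return("synonymous")
  NA_character_
}

#' Read functional-category annotations
#'
#' Two ingestion routes: a TSV with columns chrom, pos, category
#' ('#' comments allowed), or the `CSQ` INFO field of a VEP-annotated VCF.
#' For CSQ, each transcript's '&'-joined consequence terms are mapped to a
#' category — loss-of-function (the union of stop_gained, stop_lost,
#' splice_acceptor_variant and splice_donor_variant), missense, or
#' synonymous — and the most severe category across transcripts wins
#' (LoF > missense > synonymous).
#'
#' @param path TSV path (for `read_annotation_tsv`) or VCF path (for
#'   `read_csq_annotations`)
#' @return data.frame with columns `chrom`, `pos`, `category`
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "category"))
  df$pos <- as.integer(df$pos)
  df
}

#' @rdname read_annotation_tsv
#' @export
read_csq_annotations <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  csq <- vcfR::extract.info(v, "CSQ")
  # locate the Consequence slot from the header description, default slot 2
  meta <- v@meta
  cons_idx <- 2L
  desc <- grep("ID=CSQ", meta, value = TRUE)
  if (length(desc)) {
    fmt <- sub('.*Format: *([^">]+).*', "\\1", desc[1])
    slots <- strsplit(fmt, "|", fixed = TRUE)[[1]]
    hit <- match("Consequence", slots)
    if (!is.na(hit)) cons_idx <- hit
  }
  cat_of <- vapply(csq, function(s) {
    if (is.na(s)) return(NA_character_)
    tx <- strsplit(s, ",", fixed = TRUE)[[1]]
    cats <- vapply(tx, function(t) {
      fields <- strsplit(t, "|", fixed = TRUE)[[1]]
      if (length(fields) < cons_idx) return(NA_character_)
      csq_term_category(strsplit(fields[cons_idx], "&", fixed = TRUE)[[1]])
    }, character(1))
    cats <- cats[!is.na(cats)]
    if (!length(cats)) return(NA_character_)
    cats[which.max(.category_rank[cats])]
  }, character(1), USE.NAMES = FALSE)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             category = cat_of, stringsAsFactors = FALSE)
}

#' Attach functional categories to a genotype matrix
#'
#' @param gm a [genotype_matrix()]
#' @param ann data.frame with chrom, pos, category (from
#'   [read_annotation_tsv()] or [read_csq_annotations()]); when a position
#'   appears several times the most severe category wins
#' @return `gm` with a filled `category` locus column
#' @export
apply_annotations <- function(gm, ann) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ann <- ann[!is.na(ann$category), , drop = FALSE]
  ann <- ann[order(.category_rank[ann$category], decreasing = TRUE), ]
  ann <- ann[!duplicated(paste(ann$chrom, ann$pos)), ]
  key <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")
  gm$loci$category <- ann$category[match(key,
                                         paste(ann$chrom, ann$pos,
                                               sep = ":"))]
  gm
}
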