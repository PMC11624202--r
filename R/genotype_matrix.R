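#' Construct a derived-allele dosage matrix
#'
#' The central container of the package: an `n_individuals x n_loci` integer
#' matrix of derived-allele dosages (0, 1 or 2 copies per diploid individual)
#' together with per-locus metadata. All LD statistics are computed on this
#' object. Loci are kept sorted by (chrom, pos).
#'
#' @param dosages integer matrix, individuals in rows, loci in columns,
#'   entries in \{0, 1, 2\}. No missing values are allowed: sites with
#'   missing genotypes must be excluded upstream.
#' @param loci data.frame with one row per column of `dosages`. Must contain
#'   `chrom` and `pos` (1-based bp). Optional columns: `category`
#'   (e.g. "synonymous", "missense", "LoF"), `s` (selection coefficient for
#'   simulated loci), `ref`, `alt`. A `dac` column (derived allele count) is
#'   recomputed from the column sums.
#' @param sample_ids character vector of individual identifiers (defaults to
#'   "ind1", "ind2", ...).
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `loci`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, loci, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (anyNA(dosages)) stop("dosage matrix contains missing values")
  if (length(dosages) && (min(dosages) < 0L || max(dosages) > 2L)) {
    stop("dosages must be in {0, 1, 2}")
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (nrow(loci) != ncol(dosages)) {
    stop("loci metadata rows (", nrow(loci), ") != dosage columns (",
         ncol(dosages), ")")
  }
  if (!all(c("chrom", "pos") %in% names(loci))) {
    stop("loci metadata needs 'chrom' and 'pos' columns")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length != number of individuals")
  }
  ord <- order(loci$chrom, loci$pos)
  dosages <- dosages[, ord, drop = FALSE]
  loci <- loci[ord, , drop = FALSE]
  loci$dac <- as.integer(colSums(dosages))
  rownames(loci) <- NULL
  structure(list(dosages = dosages, loci = loci,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "loci\n")
  if (ncol(x$dosages)) {
    cat("  chrom(s):", paste(unique(x$loci$chrom), collapse = ", "), "\n")
    cat("  dac range:", min(x$loci$dac), "-", max(x$loci$dac), "\n")
    if ("category" %in% names(x$loci)) {
      tb <- table(x$loci$category)
      cat("  categories:",
          paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of individuals / loci in a genotype matrix
#'
#' @param gm a [genotype_matrix()]
#' @return integer count
#' @export
n_ind <- function(gm) nrow(gm$dosages)

#' @rdname n_ind
#' @export
n_loci <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix by locus index
#'
#' @param gm a [genotype_matrix()]
#' @param j integer vector of locus (column) indices to keep
#' @return a `genotype_matrix` restricted to those loci
#' @export
subset_loci <- function(gm, j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$dosages[, j, drop = FALSE],
                  gm$loci[j, , drop = FALSE], gm$sample_ids)
}

#' Define an ordered locus set within a genotype matrix
#'
#' A `locus_set` names the collection of loci an LD statistic is averaged
#' over (for example all LoF doubletons). Construction via
#' [select_locus_set()] applies category and derived-allele-count bounds;
#' this low-level constructor takes explicit indices.
#'
#' @param gm a [genotype_matrix()]
#' @param indices integer locus indices into `gm` (deduplicated and sorted by
#'   chrom, pos)
#' @param label set label, e.g. "synonymous", "missense", "LoF" or "custom"
#' @param mdac,mdaf optional maximum derived allele count / frequency the set
#'   was conditioned on (recorded for provenance)
#' @return an object of class `locus_set`
#' @export
locus_set <- function(gm, indices, label = "custom",
                      mdac = NULL, mdaf = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  indices <- unique(as.integer(indices))
  if (any(indices < 1L | indices > n_loci(gm))) {
    stop("locus indices out of range")
  }
  ord <- order(gm$loci$chrom[indices], gm$loci$pos[indices])
  indices <- indices[ord]
  structure(list(gm = gm, indices = indices, label = label,
                 mdac = mdac, mdaf = mdaf),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set '", x$label, "': ", length(x$indices), " loci",
      if (!is.null(x$mdac)) paste0(", mdac=", x$mdac),
      if (!is.null(x$mdaf)) paste0(", mdaf=", x$mdaf), "\n", sep = "")
  invisible(x)
}

#' @export
length.locus_set <- function(x) length(x$indices)

set_dosages <- function(set) set$gm$dosages[, set$indices, drop = FALSE]
set_loci <- function(set) set$gm$loci[set$indices, , drop = FALSE]

#' Serialise a genotype matrix to TSV
#'
#' Writes one row per locus: metadata columns followed by one dosage column
#' per individual. The inverse of [read_genotype_tsv()].
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta_cols <- intersect(c("chrom", "pos", "ref", "alt", "dac",
                           "category", "s"), names(gm$loci))
  out <- cbind(gm$loci[, meta_cols, drop = FALSE],
               as.data.frame(t(gm$dosages)))
  names(out) <- c(meta_cols, gm$sample_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from its TSV serialisation
#'
#' @param path file written by [write_genotype_tsv()]
#' @return a [genotype_matrix()]
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "ref", "alt", "dac",
                           "category", "s"), names(df))
  samp_cols <- setdiff(names(df), meta_cols)
  dos <- t(as.matrix(df[, samp_cols, drop = FALSE]))
  genotype_matrix(dos, df[, meta_cols, drop = FALSE], sample_ids = samp_cols)
}
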