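#' Pair filter for set-level LD statistics
#'
#' Restricts which locus pairs enter an averaged LD statistic by physical
#' distance. Pairs on different chromosomes are treated as infinitely
#' distant: they satisfy any minimum-distance bound and fail any finite
#' maximum-distance bound.
#'
#' @param min_distance_bp minimum pair distance in bp (0 = no limit)
#' @param max_distance_bp maximum pair distance in bp, or `NULL` for none
#' @param same_chrom_only if `TRUE`, only intra-chromosomal pairs are used
#' @return an object of class `pair_filter`
#' @export
pair_filter <- function(min_distance_bp = 0, max_distance_bp = NULL,
                        same_chrom_only = FALSE) {
  if (!is.null(max_distance_bp) && min_distance_bp > max_distance_bp) {
    stop("min_distance_bp must be <= max_distance_bp")
  }
  structure(list(min_distance_bp = min_distance_bp,
                 max_distance_bp = max_distance_bp,
                 same_chrom_only = isTRUE(same_chrom_only)),
            class = "pair_filter")
}

pf_is_trivial <- function(pf) {
  pf$min_distance_bp <= 0 && is.null(pf$max_distance_bp) &&
    !pf$same_chrom_only
}

pf_equal <- function(a, b) {
  identical(a$min_distance_bp, b$min_distance_bp) &&
    identical(a$max_distance_bp, b$max_distance_bp) &&
    identical(a$same_chrom_only, b$same_chrom_only)
}

# logical m x m matrix of admissible i<j pairs under pf (upper triangle only)
pair_mask <- function(loci, pf) {
  m <- nrow(loci)
  same <- outer(loci$chrom, loci$chrom, "==")
  dist <- abs(outer(loci$pos, loci$pos, "-"))
  dist[!same] <- Inf
  ok <- dist >= pf$min_distance_bp
  if (!is.null(pf$max_distance_bp)) ok <- ok & dist <= pf$max_distance_bp
  if (pf$same_chrom_only) ok <- ok & same
  ok & upper.tri(ok)
}

ld_result <- function(statistic, value, n_loci, n_pairs, set_label, pf,
                      path) {
  structure(list(statistic = statistic, value = value,
                 n_loci = n_loci, n_pairs = n_pairs,
                 set_label = set_label, pair_filter = pf,
                 computation_path = path,
                 convention = "sample moments (n-1 denominator)"),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("%s = %.6g  (set '%s', %d loci, %d pairs, %s path)\n",
              x$statistic, x$value, x$set_label, x$n_loci, x$n_pairs,
              x$computation_path))
  invisible(x)
}

check_ld_set <- function(set) {
  if (!inherits(set, "locus_set")) stop("expected a locus_set")
  if (length(set$indices) < 2L) {
    stop("insufficient loci: LD statistics need at least 2 loci")
  }
  X <- set_dosages(set)
  v <- colVars(X)
  if (any(v == 0)) {
    stop("zero variance: locus set contains constant dosage column(s) at ",
         "index ", paste(utils::head(which(v == 0), 3), collapse = ", "))
  }
  X
}

colVars <- function(X) {
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 individuals")
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Pearson correlation of two dosage vectors
#'
#' The elementary pairwise quantity behind LDcor: the linear correlation
#' coefficient of the derived-allele dosages at two loci, in [-1, 1].
#' Sample moments (n-1 denominator) are used throughout the package;
#' correlations are invariant to that choice.
#'
#' @param x,y numeric dosage vectors of equal length >= 2, neither constant
#' @return the correlation coefficient
#' @export
dosage_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  if (length(x) < 2L) stop("need >= 2 individuals")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: constant dosage vector")
  }
  stats::cor(x, y)
}

# shared driver for ldcor / netld: statistic is the mean over admissible
# pairs of cor (standardise = TRUE) or cov (standardise = FALSE).
# When the filter admits every pair the O(n*m) variance identity
#   sum_{i<j} cov(Xi, Xj) = (Var(sum_j Xj) - sum_j Var(Xj)) / 2
# is used on (optionally unit-scaled) columns; otherwise the exact pairwise
# matrix is formed.
mean_pairwise <- function(set, pf, standardise, statistic) {
  X <- check_ld_set(set)
  m <- ncol(X)
  loci <- set_loci(set)
  if (pf_is_trivial(pf)) {
    n_pairs <- m * (m - 1) / 2
    if (standardise) {
      Z <- scale(X)  # unit sample sd; Var(sum Z) - m identity
      tot <- stats::var(rowSums(Z))
      s <- (tot - m) / 2
    } else {
      tot <- stats::var(rowSums(X))
      s <- (tot - sum(colVars(X))) / 2
    }
    return(ld_result(statistic, s / n_pairs, m, n_pairs, set$label, pf,
                     "fast"))
  }
  mask <- pair_mask(loci, pf)
  n_pairs <- sum(mask)
  if (n_pairs == 0L) stop("pair filter excludes all pairs")
  C <- if (standardise) stats::cor(X) else stats::cov(X)
  ld_result(statistic, mean(C[mask]), m, n_pairs, set$label, pf, "exact")
}

#' LDcor: mean pairwise dosage correlation of a locus set
#'
#' The set-level, sign-preserving LD statistic for unphased genotypes:
#' the average over all admissible locus pairs (i < j) of the Pearson
#' correlation of derived-allele dosages,
#' \deqn{LDcor_L = \frac{2}{m(m-1)} \sum_{i<j \in L}
#'   \frac{cov(X_i, X_j)}{\sigma(X_i)\sigma(X_j)},}
#' where m is the number of loci in the set L. LDcor lies in [-1, 1];
#' negative values indicate net repulsion (derived alleles spread across
#' individuals more than expected, the signature of negative selection with
#' synergistic epistasis), positive values net coupling.
#'
#' When the pair filter admits every pair, the sum of correlations is
#' computed in O(n m) time via the variance identity on unit-standardised
#' columns; the result is identical to explicit pair iteration.
#'
#' @param set a [locus_set()] with >= 2 loci, none constant
#' @param pf a [pair_filter()]
#' @return an `ld_result` with the value and provenance
#' @export
ldcor <- function(set, pf = pair_filter()) {
  mean_pairwise(set, pf, standardise = TRUE, statistic = "ldcor")
}

#' NetLD: mean pairwise raw dosage covariance of a locus set
#'
#' The unstandardised counterpart of [ldcor()]: the average pairwise
#' covariance of derived-allele dosages. Unlike LDcor it is not bounded and
#' depends on allele frequencies directly. Sample covariances (n-1
#' denominator) are used.
#'
#' @inheritParams ldcor
#' @return an `ld_result`
#' @export
netld <- function(set, pf = pair_filter()) {
  mean_pairwise(set, pf, standardise = FALSE, statistic = "netld")
}

#' LDcorabs: mean absolute pairwise dosage correlation
#'
#' The magnitude version of [ldcor()]: the average of |cor| over admissible
#' pairs, in [0, 1]. It equals 0 iff every admissible pair is uncorrelated,
#' and always satisfies LDcorabs >= LDcor. The absolute value breaks the
#' variance-identity shortcut, so pairs are iterated explicitly; for very
#' large sets a seeded uniform subsample of pairs can be used via
#' `max_pairs`.
#'
#' @inheritParams ldcor
#' @param max_pairs if non-`NULL` and fewer than the number of admissible
#'   pairs, a uniform random subsample of that many pairs is averaged
#'   (path "subsampled"); the default subsamples beyond 5e6 pairs
#' @param seed integer seed for the pair subsample
#' @return an `ld_result`
#' @export
ldcorabs <- function(set, pf = pair_filter(), max_pairs = 5e6, seed = 1L) {
  X <- check_ld_set(set)
  m <- ncol(X)
  loci <- set_loci(set)
  trivial <- pf_is_trivial(pf)
  n_adm <- if (trivial) m * (m - 1) / 2 else sum(pair_mask(loci, pf))
  if (n_adm == 0L) stop("pair filter excludes all pairs")

  if (!is.null(max_pairs) && n_adm > max_pairs) {
    # uniform pair subsample: draw (i, j) pairs, deduplicate, filter,
    # repeat until max_pairs collected
    Z <- scale(X)
    n1 <- nrow(X) - 1L
    pick_i <- integer(0); pick_j <- integer(0)
    with_seed(seed, while (length(pick_i) < max_pairs) {
      k <- ceiling((max_pairs - length(pick_i)) * 1.3)
      a <- sample.int(m, k, replace = TRUE)
      b <- sample.int(m, k, replace = TRUE)
      i <- pmin(a, b); j <- pmax(a, b)
      keep <- i < j
      i <- i[keep]; j <- j[keep]
      if (!trivial) {
        d <- ifelse(loci$chrom[i] == loci$chrom[j],
                    abs(loci$pos[i] - loci$pos[j]), Inf)
        ok <- d >= pf$min_distance_bp
        if (!is.null(pf$max_distance_bp)) ok <- ok & d <= pf$max_distance_bp
        if (pf$same_chrom_only) ok <- ok & is.finite(d)
        i <- i[ok]; j <- j[ok]
      }
      pick_i <- c(pick_i, i); pick_j <- c(pick_j, j)
      dup <- duplicated(pick_i * (m + 1) + pick_j)
      pick_i <- pick_i[!dup]; pick_j <- pick_j[!dup]
    })
    pick_i <- pick_i[seq_len(max_pairs)]
    pick_j <- pick_j[seq_len(max_pairs)]
    vals <- abs(colSums(Z[, pick_i, drop = FALSE] *
                          Z[, pick_j, drop = FALSE]) / n1)
    return(ld_result("ldcorabs", mean(vals), m, max_pairs, set$label, pf,
                     "subsampled"))
  }

  C <- abs(stats::cor(X))
  mask <- if (trivial) upper.tri(C) else pair_mask(loci, pf)
  ld_result("ldcorabs", mean(C[mask]), m, n_adm, set$label, pf, "exact")
}

#' Null-normalised LD: nLDcor and nLDcorabs
#'
#' Subtracts the LD of a null (nearly neutral, typically synonymous) locus
#' set from that of a target (e.g. LoF) set computed with the same statistic
#' and pair filter:
#' \deqn{nLDcor_L = LDcor_L - LDcor_S.}
#' The difference removes species- and demography-wide baseline LD, making
#' the deleterious-set signal comparable across populations. Range [-2, 2].
#'
#' @param target,null `ld_result` objects from [ldcor()] or [ldcorabs()]
#'   computed with identical statistic and pair filter
#' @return the difference of values (numeric scalar)
#' @export
nldcor <- function(target, null) {
  stopifnot(inherits(target, "ld_result"), inherits(null, "ld_result"))
  if (target$statistic != null$statistic) {
    stop("target and null were computed with different statistics (",
         target$statistic, " vs ", null$statistic, ")")
  }
  if (!pf_equal(target$pair_filter, null$pair_filter)) {
    stop("target and null were computed with different pair filters")
  }
  target$value - null$value
}

#' @rdname nldcor
#' @export
nldcorabs <- function(target, null) {
  if (target$statistic != "ldcorabs" || null$statistic != "ldcorabs") {
    stop("nldcorabs expects ldcorabs results")
  }
  nldcor(target, null)
}

#' Ratio of total to additive variance of the mutation burden
#'
#' For the burden Z = sum_j X_j over a locus set, compares the variance of
#' the sum with the additive variance V_A = sum_j Var(X_j). Two values are
#' returned: `paper_formula`, the printed form
#' (m(m-1)/2 * NetLD + V_A) / V_A with m the number of loci, and
#' `direct_ratio`, the empirical Var(Z) / V_A, which carries the factor 2
#' on the covariance term implied by Var(sum X) = V_A + 2 sum_{i<j} cov.
#' The two agree only when NetLD = 0; both are reported so the discrepancy
#' is visible rather than silently resolved.
#'
#' @param set a [locus_set()]
#' @return list with `paper_formula` and `direct_ratio`
#' @export
v_over_va <- function(set) {
  X <- check_ld_set(set)
  m <- ncol(X)
  va <- sum(colVars(X))
  if (va == 0) stop("additive variance is zero")
  nl <- netld(set)$value
  list(paper_formula = (m * (m - 1) / 2 * nl + va) / va,
       direct_ratio = stats::var(rowSums(X)) / va)
}

#' Two-locus haplotype counts
#'
#' Counts of the four haplotype classes over 2N gametes at a pair of
#' biallelic loci, with A/B the derived alleles. The basis for the
#' classical LD statistics.
#'
#' @param n_AB,n_Ab,n_aB,n_ab nonnegative haplotype counts
#' @return an object of class `haplotype_counts`
#' @export
haplotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  cnt <- c(n_AB = n_AB, n_Ab = n_Ab, n_aB = n_aB, n_ab = n_ab)
  if (any(cnt < 0) || sum(cnt) < 1) stop("invalid haplotype counts")
  structure(as.list(cnt), total = sum(cnt), class = "haplotype_counts")
}

#' Classical two-locus LD statistics from haplotype counts
#'
#' Computes, from a 2x2 haplotype table, the haplotype-frequency deviation
#' D = p_AB - p_A p_B, the normalised D' (divided by max(-p_A p_B,
#' -p_a p_b) when D < 0 and by min(p_A p_b, p_a p_B) when D > 0; D' = 0 when
#' D = 0), r^2 = D^2 / (p_A p_a p_B p_b), and the signed square root of r^2
#' (sign of D, with A and B the derived alleles).
#'
#' @param h a [haplotype_counts()] object with all four allele frequencies
#'   strictly inside (0, 1)
#' @return list with `D`, `D_prime`, `r2`, `signed_sqrt_r2`
#' @export
classical_two_locus <- function(h) {
  stopifnot(inherits(h, "haplotype_counts"))
  tot <- attr(h, "total")
  pAB <- h$n_AB / tot
  pA <- (h$n_AB + h$n_Ab) / tot
  pB <- (h$n_AB + h$n_aB) / tot
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("monomorphic locus: all allele frequencies must be in (0,1)")
  }
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * pa * pB * pb)
  Dp <- if (D < 0) {
    D / max(-pA * pB, -pa * pb)
  } else if (D > 0) {
    D / min(pA * pb, pa * pB)
  } else 0
  list(D = D, D_prime = Dp, r2 = r2, signed_sqrt_r2 = sign(D) * sqrt(r2))
}

#' Mean signed sqrt(r^2) over a locus set from phased haplotypes
#'
#' The phased-data comparator for [ldcor()]: for every admissible pair the
#' classical r is computed from true haplotype frequencies and signed by D
#' (derived-derived coupling positive), then averaged. Note sign(D) *
#' sqrt(r^2) is exactly the haplotype-level Pearson correlation
#' D / sqrt(p_A p_a p_B p_b).
#'
#' @param haplotypes 2n x m binary matrix (rows gametes, columns loci,
#'   1 = derived), column order matching the locus set's genotype matrix
#' @param set a [locus_set()] naming the columns to use
#' @param pf a [pair_filter()]
#' @return mean signed sqrt(r^2) over admissible pairs
#' @export
signed_sqrt_r2_mean <- function(haplotypes, set, pf = pair_filter()) {
  H <- as.matrix(haplotypes)
  if (!all(H %in% c(0, 1))) {
    stop("haplotype matrix must be binary (phased, derived = 1)")
  }
  stopifnot(inherits(set, "locus_set"))
  H <- H[, set$indices, drop = FALSE]
  m <- ncol(H)
  if (m < 2L) stop("insufficient loci")
  p <- colMeans(H)
  if (any(p <= 0 | p >= 1)) stop("monomorphic haplotype column(s)")
  P <- crossprod(H) / nrow(H)          # p_AB for derived-derived
  D <- P - outer(p, p)
  S <- D / sqrt(outer(p * (1 - p), p * (1 - p)))
  mask <- if (pf_is_trivial(pf)) {
    upper.tri(S)
  } else {
    pair_mask(set_loci(set), pf)
  }
  if (!sum(mask)) stop("pair filter excludes all pairs")
  mean(S[mask])
}
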