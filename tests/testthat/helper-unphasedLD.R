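# shared helpers: small builders and independent oracles

# genotype matrix from dosage columns given as a list of vectors
mk_gm <- function(..., chrom = NULL) {
  cols <- list(...)
  X <- do.call(cbind, cols)
  m <- ncol(X)
  genotype_matrix(X, data.frame(
    chrom = chrom %||% rep("c1", m), pos = 100L * seq_len(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random polymorphic, non-constant dosage matrix
rand_gm <- function(n, m, seed, p = 0.3) {
  set.seed(seed)
  repeat {
    X <- matrix(rbinom(n * m, 2, p), n, m)
    v <- apply(X, 2, var)
    X <- X[, v > 0, drop = FALSE]
    if (ncol(X) >= 2) break
  }
  genotype_matrix(X, data.frame(chrom = rep("c1", ncol(X)),
                                pos = 10L * seq_len(ncol(X))))
}

full_set <- function(gm) locus_set(gm, seq_len(ncol(gm$dosages)))

# explicit O(m^2) pairwise oracle: double loop over stats::cor
pair_loop_mean <- function(X, f = identity, standardise = TRUE) {
  m <- ncol(X)
  tot <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      v <- if (standardise) stats::cor(X[, i], X[, j])
           else stats::cov(X[, i], X[, j])
      tot <- tot + f(v)
    }
  }
  tot / (m * (m - 1) / 2)
}

# independent HWE oracle: count perfect matchings of the 2n alleles into n
# unordered pairs; h mixed pairs out of nA copies of one allele
hwe_matching_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_alt + n_het
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1.0)
  log_m <- function(k) {               # matchings of k items into k/2 pairs
    if (k == 0) return(0)
    lfactorial(k) - (k / 2) * log(2) - lfactorial(k / 2)
  }
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logw <- vapply(hs, function(h) {
    lchoose(nA, h) + lchoose(na, h) + lfactorial(h) +
      log_m(nA - h) + log_m(na - h)
  }, numeric(1))
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Watterson's closed-form expectation of segregating sites in a sample
watterson_expected_s <- function(N, mu, L, sample_n) {
  4 * N * mu * L * sum(1 / seq_len(2 * sample_n - 1))
}
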