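#' Exact distribution of observed D for two unlinked loci
#'
#' In a finite random-mating sample of N diploids (2N gametes), two
#' unlinked loci with fixed derived allele counts dac1 and dac2 can realise
#' only finitely many haplotype tables (n_AB, n_Ab, n_aB, n_ab) with margins
#' n_AB + n_Ab = dac1, n_AB + n_aB = dac2 and total 2N. Under random union
#' of gametes with independent loci, a table's probability is its
#' multinomial arrangement count (2N)! / (n_AB! n_Ab! n_aB! n_ab!) divided
#' by C(2N, dac1) * C(2N, dac2). Each table yields an observed
#' D = p_AB - p_A p_B; tables with equal D are merged. The distribution
#' integrates to 1 and has mean exactly 0 — even with no true association,
#' any single sample shows a nonzero D, which is why set-averaged
#' statistics are compared against this sampling noise.
#'
#' @param N diploid sample size
#' @param dac1,dac2 derived allele counts at the two loci, each in
#'   1..(2N-1)
#' @param max_2n enumeration guard on 2N (default 60)
#' @return data.frame with columns `D` and `prob`, sorted by `D`
#' @export
enumerate_unlinked_d_distribution <- function(N, dac1, dac2, max_2n = 60) {
  stopifnot(N >= 1)
  two_n <- 2L * N
  if (two_n > max_2n) {
    stop("enumeration guard exceeded: 2N = ", two_n, " > ", max_2n)
  }
  if (dac1 < 1 || dac1 > two_n - 1 || dac2 < 1 || dac2 > two_n - 1) {
    stop("dac must be in 1..(2N-1)")
  }
  n_ab_rng <- max(0L, dac1 + dac2 - two_n):min(dac1, dac2)   # n_AB values
  n_AB <- n_ab_rng
  n_Ab <- dac1 - n_AB
  n_aB <- dac2 - n_AB
  n_ab <- two_n - n_AB - n_Ab - n_aB
  logw <- lfactorial(two_n) - lfactorial(n_AB) - lfactorial(n_Ab) -
    lfactorial(n_aB) - lfactorial(n_ab)
  logw <- logw - (lchoose(two_n, dac1) + lchoose(two_n, dac2))
  prob <- exp(logw)
  D <- n_AB / two_n - (dac1 / two_n) * (dac2 / two_n)
  agg <- tapply(prob, D, sum)
  out <- data.frame(D = as.numeric(names(agg)), prob = as.numeric(agg))
  out[order(out$D), , drop = FALSE]
}

#' Diploid-class probabilities and likelihood under random union of gametes
#'
#' For a haplotype-frequency vector y = (p_AB, p_Ab, p_aB, p_ab), random
#' union of gametes gives the nine two-locus diploid genotype classes the
#' probabilities of a multinomial square (the double heterozygote pooling
#' coupling and repulsion: 2 p_AB p_ab + 2 p_Ab p_aB).
#' `two_locus_diploid_loglik` evaluates the multinomial log-likelihood of
#' an observed 3x3 diploid class table under those probabilities.
#'
#' @param hap_freqs numeric length-4 vector (p_AB, p_Ab, p_aB, p_ab)
#'   summing to 1
#' @return `diploid_class_probs`: 3x3 matrix of genotype-class
#'   probabilities, rows = dosage at locus 1 (0,1,2 derived), columns =
#'   dosage at locus 2
#' @export
diploid_class_probs <- function(hap_freqs) {
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= 0),
            abs(sum(hap_freqs) - 1) < 1e-8)
  pAB <- hap_freqs[1]; pAb <- hap_freqs[2]
  paB <- hap_freqs[3]; pab <- hap_freqs[4]
  # haplotype dosage contributions: locus1 derived in AB, Ab; locus2 in AB, aB
  y <- matrix(0, 3, 3, dimnames = list(d1 = 0:2, d2 = 0:2))
  y["2", "2"] <- pAB^2
  y["2", "1"] <- 2 * pAB * pAb
  y["2", "0"] <- pAb^2
  y["1", "2"] <- 2 * pAB * paB
  y["1", "1"] <- 2 * pAB * pab + 2 * pAb * paB
  y["1", "0"] <- 2 * pAb * pab
  y["0", "2"] <- paB^2
  y["0", "1"] <- 2 * paB * pab
  y["0", "0"] <- pab^2
  y
}

#' @rdname diploid_class_probs
#' @param counts 3x3 matrix of observed diploid class counts (same layout
#'   as `diploid_class_probs`)
#' @return `two_locus_diploid_loglik`: the multinomial log-likelihood
#'   (including the combinatorial coefficient N! / prod N_ij!)
#' @export
two_locus_diploid_loglik <- function(hap_freqs, counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  y <- diploid_class_probs(hap_freqs)
  if (any(counts > 0 & y == 0)) return(-Inf)
  pos <- counts > 0
  lfactorial(sum(counts)) - sum(lfactorial(counts)) +
    sum(counts[pos] * log(y[pos]))
}
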