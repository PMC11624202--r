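#' Frequency-spectrum-matched resampling of null locus sets
#'
#' Draws replicate null sets from a pool (typically synonymous loci) whose
#' derived-allele-count histogram matches the target set's exactly: for
#' every dac value present in the target, the same number of pool loci with
#' that dac is drawn without replacement, independently per replicate.
#' This removes allele-frequency-spectrum differences as a confounder when
#' the target set's LD is compared with the null distribution.
#'
#' With `bin_width > 1` matching is on dac bins instead of exact counts,
#' for small pools whose spectrum is too sparse for exact matching.
#'
#' @param pool a [locus_set()] to resample from
#' @param target a [locus_set()] whose dac histogram is to be reproduced
#' @param n_reps number of replicate sets (default 100)
#' @param seed integer seed; the draw is reproducible
#' @param bin_width dac bin width for matching (1 = exact dac matching)
#' @return list of `n_reps` [locus_set()] objects labelled
#'   "resampled<k>"
#' @export
daf_matched_resample <- function(pool, target, n_reps = 100, seed = 1L,
                                 bin_width = 1L) {
  stopifnot(inherits(pool, "locus_set"), inherits(target, "locus_set"),
            n_reps >= 1, bin_width >= 1)
  if (!identical(pool$gm, target$gm)) {
    # pools from a different matrix are fine as long as sample size matches
    if (n_ind(pool$gm) != n_ind(target$gm)) {
      stop("pool and target come from different sample sizes")
    }
  }
  strat <- function(dac) as.integer((dac - 1L) %/% bin_width)
  pool_dac <- pool$gm$loci$dac[pool$indices]
  tgt_dac <- target$gm$loci$dac[target$indices]
  pool_strata <- split(pool$indices, strat(pool_dac))
  need <- table(strat(tgt_dac))
  for (s in names(need)) {
    have <- length(pool_strata[[s]])
    if (have < need[[s]]) {
      lo <- as.integer(s) * bin_width + 1L
      stop("insufficient pool loci for dac stratum ", lo,
           if (bin_width > 1L) paste0("-", lo + bin_width - 1L),
           ": need ", need[[s]], ", have ", have)
    }
  }
  with_seed(seed, lapply(seq_len(n_reps), function(k) {
    idx <- unlist(lapply(names(need), function(s) {
      pool_strata[[s]][sample.int(length(pool_strata[[s]]), need[[s]])]
    }), use.names = FALSE)
    locus_set(pool$gm, idx, label = paste0("resampled", k),
              mdac = target$mdac, mdaf = target$mdaf)
  }))
}

#' Permutation p-value with the add-one convention
#'
#' Compares an observed statistic with a null distribution of R resampled
#' values. The add-one rule p = (1 + #\{null <= observed\}) / (R + 1)
#' (lower tail; upper symmetric) never returns 0 and is valid for
#' permutation nulls. The two-sided p-value is 2 min(lower, upper) capped
#' at 1.
#'
#' @param observed observed statistic
#' @param null_values numeric vector of null statistics (length >= 1)
#' @param side "lower", "upper" or "two"
#' @return p-value in (0, 1]
#' @export
permutation_pvalue <- function(observed, null_values,
                               side = c("two", "lower", "upper")) {
  side <- match.arg(side)
  if (!length(null_values)) stop("empty null distribution")
  r <- length(null_values)
  lower <- (1 + sum(null_values <= observed)) / (r + 1)
  upper <- (1 + sum(null_values >= observed)) / (r + 1)
  switch(side,
         lower = lower,
         upper = upper,
         two = min(1, 2 * min(lower, upper)))
}

#' Resampling-based LD significance test
#'
#' Convenience driver: computes a statistic on the target set, recomputes
#' it on `n_reps` dac-matched resamples of the pool, and reports the
#' observed value, null mean and s.d., and lower / upper / two-sided
#' permutation p-values.
#'
#' @param target,pool [locus_set()] objects (see [daf_matched_resample()])
#' @param statistic "ldcor", "ldcorabs" or "netld"
#' @param pf a [pair_filter()]
#' @param n_reps,seed resampling plan
#' @param bin_width dac bin width for spectrum matching (see
#'   [daf_matched_resample()])
#' @return one-row data.frame report
#' @export
ld_permutation_test <- function(target, pool,
                                statistic = c("ldcor", "ldcorabs", "netld"),
                                pf = pair_filter(), n_reps = 100,
                                seed = 1L, bin_width = 1L) {
  statistic <- match.arg(statistic)
  fn <- switch(statistic, ldcor = ldcor, ldcorabs = ldcorabs,
               netld = netld)
  obs <- fn(target, pf)$value
  reps <- daf_matched_resample(pool, target, n_reps = n_reps, seed = seed,
                               bin_width = bin_width)
  nulls <- vapply(reps, function(s) fn(s, pf)$value, numeric(1))
  data.frame(statistic = statistic, observed = obs,
             null_mean = mean(nulls), null_sd = stats::sd(nulls),
             p_lower = permutation_pvalue(obs, nulls, "lower"),
             p_upper = permutation_pvalue(obs, nulls, "upper"),
             p_two = permutation_pvalue(obs, nulls, "two"),
             n_reps = n_reps, seed = seed)
}
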