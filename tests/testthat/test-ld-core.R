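test_that("dosage correlation handles the elementary cases and errors", {
  expect_equal(dosage_correlation(c(2, 0, 0, 0), c(2, 0, 0, 0)), 1.0)
  expect_equal(dosage_correlation(c(2, 0), c(0, 2)), -1.0)
  expect_equal(dosage_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.0)
  expect_error(dosage_correlation(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(dosage_correlation(c(1, 2), c(0, 1, 2)), "length")
})

test_that("ldcor matches hand-derived values and the pairwise loop", {
  expect_equal(ldcor(full_set(mk_gm(c(2, 0, 0, 0), c(2, 0, 0, 0))))$value,
               1.0)
  # three mutually exclusive carriers: each pairwise correlation is -1/3
  gm <- mk_gm(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0))
  expect_equal(ldcor(full_set(gm))$value, -1 / 3)

  gm2 <- rand_gm(20, 50, seed = 7)
  res <- ldcor(full_set(gm2))
  expect_equal(res$computation_path, "fast")
  expect_equal(res$value, pair_loop_mean(gm2$dosages), tolerance = 1e-12)
})

test_that("ldcorabs: identical, independent and subsampled paths", {
  expect_equal(ldcorabs(full_set(mk_gm(c(2, 0, 0, 0), c(2, 0, 0, 0))))$value,
               1.0)
  # pairwise-orthogonal columns: every |cor| is exactly zero
  gm0 <- mk_gm(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_equal(ldcorabs(full_set(gm0))$value, 0.0)

  gm <- rand_gm(30, 40, seed = 11)
  exact <- ldcorabs(full_set(gm))
  expect_equal(exact$value, pair_loop_mean(gm$dosages, f = abs),
               tolerance = 1e-12)
  sub <- ldcorabs(full_set(gm), max_pairs = 300, seed = 5)
  expect_equal(sub$computation_path, "subsampled")
  expect_equal(sub$n_pairs, 300)
  expect_lt(abs(sub$value - exact$value), 0.05)
  # same seed, same subsample
  expect_equal(ldcorabs(full_set(gm), max_pairs = 300, seed = 5)$value,
               sub$value)
})

test_that("ldcor/ldcorabs bounds hold on random inputs", {
  for (k in 1:40) {
    gm <- rand_gm(15, 12, seed = 100 + k, p = runif(1, 0.1, 0.5))
    a <- ldcor(full_set(gm))$value
    b <- ldcorabs(full_set(gm))$value
    expect_gte(a, -1); expect_lte(a, b); expect_lte(b, 1); expect_gte(b, 0)
  }
})

test_that("ldcor is invariant to permuting individuals", {
  gm <- rand_gm(25, 20, seed = 3)
  set.seed(1)
  perm <- sample(nrow(gm$dosages))
  gm2 <- genotype_matrix(gm$dosages[perm, ], gm$loci)
  expect_equal(ldcor(full_set(gm))$value, ldcor(full_set(gm2))$value)
})

test_that("netld matches covariances and the pairwise loop", {
  gm0 <- mk_gm(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(netld(full_set(gm0))$value, 0.0)
  # two identical columns: mean pair covariance = sample variance = 1
  expect_equal(netld(full_set(mk_gm(c(2, 0, 0, 0), c(2, 0, 0, 0))))$value,
               1.0)
  gm <- rand_gm(20, 30, seed = 13)
  expect_equal(netld(full_set(gm))$value,
               pair_loop_mean(gm$dosages, standardise = FALSE),
               tolerance = 1e-12)
})

test_that("v_over_va reports the printed formula and the direct ratio", {
  gm <- mk_gm(c(1, 1, 0, 0), c(1, 0, 1, 0))       # NetLD = 0
  expect_equal(v_over_va(full_set(gm))$paper_formula, 1.0)
  gm2 <- mk_gm(c(2, 0, 0, 0), c(2, 0, 0, 0))
  vv <- v_over_va(full_set(gm2))
  expect_equal(vv$paper_formula, 1.5)   # (1 * 1.0 + 2.0) / 2.0
  expect_equal(vv$direct_ratio, 2.0)    # Var(sum) = 4, V_A = 2
})

test_that("null normalisation subtracts and validates provenance", {
  gm <- mk_gm(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0))
  tgt <- ldcor(full_set(gm))
  expect_equal(nldcor(tgt, tgt), 0.0)
  null <- ldcor(full_set(mk_gm(c(2, 0, 0, 0), c(2, 0, 0, 0))))
  expect_equal(nldcor(tgt, null), -1 / 3 - 1.0)
  other_pf <- ldcor(full_set(gm), pair_filter(min_distance_bp = 50))
  expect_error(nldcor(tgt, other_pf), "pair filters")
  expect_error(nldcor(tgt, ldcorabs(full_set(gm))), "different statistics")
})

test_that("classical two-locus statistics evaluate the printed formulas", {
  cp <- classical_two_locus(haplotype_counts(50, 0, 0, 50))
  expect_equal(cp$D, 0.25); expect_equal(cp$D_prime, 1)
  expect_equal(cp$r2, 1)
  ind <- classical_two_locus(haplotype_counts(25, 25, 25, 25))
  expect_equal(ind$D, 0); expect_equal(ind$r2, 0); expect_equal(ind$D_prime, 0)
  ex <- classical_two_locus(haplotype_counts(10, 10, 10, 70))
  expect_equal(ex$D, 0.06)
  expect_equal(ex$r2, 0.140625)
  expect_equal(ex$D_prime, 0.375)
  expect_equal(ex$signed_sqrt_r2, sqrt(0.140625))
  expect_error(classical_two_locus(haplotype_counts(50, 50, 0, 0)),
               "monomorphic")
})

test_that("signed sqrt r2 from haplotypes: coupling, repulsion, phasing", {
  Hc <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  gm <- genotype_matrix(Hc[c(1, 3), ] + Hc[c(2, 4), ],
                        data.frame(chrom = "c1", pos = c(10, 20, 30)))
  expect_equal(signed_sqrt_r2_mean(Hc, full_set(gm)), 1.0)
  Hr <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  gmr <- genotype_matrix(Hr[c(1, 3), ] + Hr[c(2, 4), ],
                         data.frame(chrom = "c1", pos = c(10, 20)))
  expect_equal(signed_sqrt_r2_mean(Hr, full_set(gmr)), -1.0)
  expect_error(signed_sqrt_r2_mean(Hr * 2L, full_set(gmr)), "binary")
})

test_that("pair filters restrict by distance with cross-chromosome = Inf", {
  gm <- genotype_matrix(
    rand_gm(30, 4, seed = 21)$dosages,
    data.frame(chrom = c("c1", "c1", "c1", "c2"),
               pos = c(100, 150, 5000, 100)))
  s <- full_set(gm)
  C <- cor(gm$dosages)
  # min distance 1000: excludes (1,2) [50 bp] and (1,3)/(2,3)? no: 4900/4850
  res <- ldcor(s, pair_filter(min_distance_bp = 1000))
  keep <- c(C[1, 3], C[2, 3], C[1, 4], C[2, 4], C[3, 4])
  expect_equal(res$value, mean(keep))
  expect_equal(res$n_pairs, 5)
  # finite max distance drops cross-chromosome pairs
  res2 <- ldcor(s, pair_filter(max_distance_bp = 100))
  expect_equal(res2$value, C[1, 2])
  expect_equal(res2$n_pairs, 1)
  res3 <- ldcor(s, pair_filter(same_chrom_only = TRUE))
  expect_equal(res3$n_pairs, 3)
  # min-distance alone keeps cross-chromosome (infinitely distant) pairs
  expect_equal(ldcor(s, pair_filter(min_distance_bp = 1e6))$n_pairs, 3)
  expect_error(ldcor(s, pair_filter(min_distance_bp = 1e6,
                                    same_chrom_only = TRUE)),
               "excludes all pairs")
  expect_error(pair_filter(10, 5), "min_distance")
})

test_that("degenerate locus sets are rejected", {
  gm <- mk_gm(c(2, 0, 0, 0), c(0, 2, 0, 0))
  expect_error(ldcor(locus_set(gm, 1L)), "insufficient loci")
  gmc <- mk_gm(c(1, 1, 1, 1), c(0, 2, 0, 0))
  expect_error(ldcor(full_set(gmc)), "zero variance")
})
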