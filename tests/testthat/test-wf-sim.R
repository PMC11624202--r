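test_that("genotype fitness multiplies locus effects and pair penalties", {
  expect_equal(genotype_fitness(integer(0), -0.01, 0.5, 0), 1.0)
  expect_equal(genotype_fitness(c(1, 1), -0.01, 0.5, 0), 0.990025)
  expect_equal(genotype_fitness(c(1, 1), -0.01, 0.5, 0.01),
               0.990025 * 0.99)         # k = 2 copies, one pair penalty
  expect_equal(genotype_fitness(c(2, 0), -0.01, 0.5, 0.01),
               0.99 * 0.99)             # one hom locus, k = 2 copies
  # "loci" counting: a single homozygous locus carries no pair penalty
  expect_equal(genotype_fitness(c(2, 0), -0.01, 0.5, 0.01,
                                epistasis_count = "loci"), 0.99)
  expect_equal(genotype_fitness(c(1, 0, 1, 1), -0.1, 0, 0), 1.0)  # h = 0
})

test_that("simulations are reproducible and respect degenerate configs", {
  cfg <- sim_config(N = 60, seq_length = 2e4, mu = 5e-7, rec_rate = 1e-7,
                    s = -0.05, neutral_fraction = 0.5, sample_n = 30,
                    seed = 17)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$loci$pos, b$loci$pos)

  # no mutation, monomorphic start: nothing segregates
  expect_equal(n_loci(simulate_population(sim_config(N = 30, mu = 0,
                                                     seq_length = 1e4))),
               0L)
})

test_that("sampled haplotypes, dosages and metadata are consistent", {
  cfg <- sim_config(N = 80, seq_length = 3e4, mu = 5e-7, rec_rate = 1e-7,
                    s = -0.02, neutral_fraction = 0.6, sample_n = 40,
                    seed = 23)
  gm <- simulate_population(cfg)
  H <- attr(gm, "haplotypes")
  expect_equal(nrow(H), 80L)
  expect_equal(H[seq(1, 80, 2), ] + H[seq(2, 80, 2), ],
               unname(gm$dosages), ignore_attr = TRUE)
  expect_equal(gm$loci$dac, unname(colSums(gm$dosages)))
  expect_true(all(gm$loci$dac >= 1 & gm$loci$dac <= 79))
  expect_true(all(gm$loci$category %in% c("neutral", "deleterious")))
  expect_true(all(gm$loci$s[gm$loci$category == "neutral"] == 0))
  expect_true(all(diff(gm$loci$pos) > 0))
})

test_that("allele frequencies drift as a martingale without selection", {
  f <- simulate_frequency_change(N = 100, p0 = 0.3, n_gens = 25,
                                 n_reps = 500, seed = 31)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.3), 3 * se)
  # negative selection pushes the mean below the martingale expectation
  fs <- simulate_frequency_change(N = 100, p0 = 0.3, n_gens = 25,
                                  n_reps = 500, s = -0.2, seed = 32)
  expect_lt(mean(fs), mean(f))
})

test_that("rescaling preserves the compound population parameters", {
  cfg <- sim_config(N = 1000, mu = 1e-8, rec_rate = 1e-8, s = -0.01,
                    epsilon = 1e-3, burn_in = 5000, scaling_factor = 10,
                    epochs = list(demography_epoch(100, 400)))
  sc <- unphasedLD:::rescale_config(cfg)
  expect_equal(sc$.N_run, 100L)
  expect_equal(sc$mu, 1e-7)
  expect_equal(sc$rec_rate, 1e-7)
  expect_equal(sc$s, -0.1)
  expect_equal(sc$epsilon, 1e-2)
  expect_equal(sc$burn_in, 500L)
  expect_equal(sc$.epochs_run[[1]]$duration, 10L)
  expect_equal(sc$.epochs_run[[1]]$sizes, 40L)
  # compound parameters are invariant
  expect_equal(sc$.N_run * sc$mu, cfg$N * 1e-8 * 1)
  expect_equal(sc$.N_run * sc$s, cfg$N * -0.01)
})

test_that("epochs change the population size (bottleneck mechanics)", {
  cfg <- sim_config(N = 60, seq_length = 2e4, mu = 5e-7, rec_rate = 0,
                    neutral_fraction = 1, seed = 3, burn_in = 300,
                    epochs = list(demography_epoch(5, 20)))
  gm <- simulate_population(cfg)
  expect_equal(n_ind(gm), 20L)
  # duration-0 epoch: pure subsetting, no reproduction
  cfg0 <- cfg; cfg0$epochs <- list(demography_epoch(0, 15))
  expect_equal(n_ind(simulate_population(cfg0)), 15L)
})

test_that("branching from a saved state continues the simulation", {
  cfg <- sim_config(N = 50, seq_length = 2e4, mu = 5e-7, rec_rate = 1e-7,
                    neutral_fraction = 1, seed = 11, burn_in = 250)
  base <- simulate_population(cfg, return_state = TRUE)
  expect_true(is.matrix(base$state$H))
  branch_cfg <- cfg
  branch_cfg$seed <- 12L
  branch_cfg$epochs <- list(demography_epoch(4, 25))
  gm <- simulate_population(branch_cfg, init_state = base$state)
  expect_equal(n_ind(gm), 25L)
})

test_that("migration mixes demes and multi-deme epochs run", {
  mig <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  cfg <- sim_config(N = 40, seq_length = 2e4, mu = 5e-7, rec_rate = 0,
                    neutral_fraction = 1, seed = 5, burn_in = 150,
                    sample_pop = 2,
                    epochs = list(demography_epoch(30, c(40, 30), mig)))
  gm <- simulate_population(cfg)
  expect_equal(n_ind(gm), 30L)
  expect_gt(n_loci(gm), 0L)
})

test_that("simulation grids summarise per-cell means and errors", {
  mk <- function(s) sim_config(N = 60, seq_length = 2e4, mu = 5e-7,
                               rec_rate = 1e-7, s = s,
                               neutral_fraction = 0.5, sample_n = 60)
  det <- run_replicates(list(neutral = mk(0), sel = mk(-0.2)),
                        n_reps = 3, min_dac = 2, base_seed = 2)
  expect_equal(nrow(det), 6L)
  expect_true(all(c("ldcor_del", "ldcor_neut", "nldcor", "ssr2_del")
                  %in% names(det)))
  summ <- summarize_sweep(det)
  expect_true(all(summ$n <= 3))
  expect_true(any(is.finite(summ$mean)))
})

test_that("YAML configs round-trip", {
  cfg <- sim_config(N = 120, seq_length = 5e4, mu = 2e-7, rec_rate = 1e-8,
                    s = -0.01, epsilon = 1e-3, sample_n = 50, seed = 77,
                    epochs = list(demography_epoch(10, 60)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$N, cfg$N)
  expect_equal(back$mu, cfg$mu)
  expect_equal(back$s, cfg$s)
  expect_equal(back$epochs[[1]]$duration, 10L)
  expect_equal(back$epochs[[1]]$sizes, 60L)
})

test_that("preset demographies are structurally valid", {
  eps <- gravel_human_epochs(migration = TRUE)
  expect_true(all(vapply(eps, inherits, logical(1), "demography_epoch")))
  expect_equal(length(eps[[length(eps)]]$sizes), 3L)
  m <- eps[[length(eps)]]$migration
  off <- m; diag(off) <- 0
  expect_true(all(rowSums(off) < 1))
  expect_s3_class(model1_config(N = 100, generations = 10), "sim_config")
})

test_that("the memory guard aborts runaway states", {
  cfg <- sim_config(N = 500, seq_length = 1e6, mu = 1e-5, seed = 1,
                    burn_in = 200)
  expect_error(simulate_population(cfg, max_entries = 2e5),
               "scaling_factor")
})
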