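#' Demography epoch
#'
#' One constant-size (per subpopulation) interval of a demographic model.
#' Entering an epoch whose sizes differ from the current population is a
#' fitness-proportional resampling to the new sizes — the mechanism by
#' which instantaneous bottlenecks and expansions are realised.
#'
#' @param duration generations (nonnegative integer, before rescaling)
#' @param sizes diploid size of each subpopulation (each >= 2)
#' @param migration optional K x K matrix; `migration[k, j]` is the
#'   probability a parent of an offspring born in subpopulation k is drawn
#'   from subpopulation j (off-diagonal rows must sum to < 1)
#' @return an object of class `demography_epoch`
#' @export
demography_epoch <- function(duration, sizes, migration = NULL) {
  stopifnot(duration >= 0, all(sizes >= 2))
  K <- length(sizes)
  if (!is.null(migration)) {
    migration <- as.matrix(migration)
    stopifnot(all(dim(migration) == K), all(migration >= 0))
    off <- migration; diag(off) <- 0
    if (any(rowSums(off) >= 1)) stop("off-diagonal migration rows must sum < 1")
  }
  structure(list(duration = as.integer(duration),
                 sizes = as.integer(sizes), migration = migration),
            class = "demography_epoch")
}

#' Forward Wright-Fisher simulation configuration
#'
#' Parameters of a discrete-generation diploid Wright-Fisher simulation
#' with infinite-sites mutation, uniform recombination, selection with
#' dominance, pairwise synergistic epistasis on the deleterious class,
#' multi-epoch demography and migration.
#'
#' Rescaling: `scaling_factor` Q divides population sizes, burn-in and
#' epoch durations by Q and multiplies mu, rec_rate, s and epsilon by Q
#' (the standard population-genetic rescaling that preserves 4N mu, 4N r,
#' 2N s and the epistatic load per generation while cutting run time by
#' ~Q^2).
#'
#' @param N initial diploid population size (used when `epochs` is `NULL`
#'   or for the burn-in before the first epoch)
#' @param epochs list of [demography_epoch()] applied in order after
#'   burn-in; `NULL` for a constant-size model
#' @param seq_length simulated sequence length in bp
#' @param mu mutation rate per bp per generation
#' @param rec_rate crossover rate per bp per generation
#' @param s selection coefficient of the deleterious class (<= 0)
#' @param h dominance coefficient (0.5 additive, 0 fully recessive)
#' @param epsilon synergistic-epistasis strength (>= 0): fitness is
#'   multiplied by (1 - epsilon)^(k(k-1)/2), see [genotype_fitness()]
#' @param neutral_fraction fraction of new mutations that are neutral
#' @param sample_n diploid individuals sampled at the end (`NULL`: whole
#'   final population of the sampled subpopulation)
#' @param sample_pop subpopulation sampled from (default 1)
#' @param seed integer seed; runs are fully reproducible
#' @param scaling_factor population/time rescaling Q (see above)
#' @param burn_in generations before the first epoch (`NULL`: 10 N after
#'   rescaling)
#' @param epistasis_count "copies": k counts deleterious allele copies
#'   (default); "loci": k counts loci carrying at least one deleterious
#'   allele
#' @return an object of class `sim_config`
#' @export
sim_config <- function(N = 1000, epochs = NULL, seq_length = 1e6,
                       mu = 1.5e-8, rec_rate = 1e-8, s = 0, h = 0.5,
                       epsilon = 0, neutral_fraction = 0.5,
                       sample_n = NULL, sample_pop = 1L, seed = 1L,
                       scaling_factor = 1, burn_in = NULL,
                       epistasis_count = c("copies", "loci")) {
  stopifnot(N >= 2, seq_length > 0, mu >= 0, rec_rate >= 0, s <= 0,
            epsilon >= 0, neutral_fraction >= 0, neutral_fraction <= 1,
            scaling_factor >= 1)
  epistasis_count <- match.arg(epistasis_count)
  if (!is.null(epochs)) {
    stopifnot(all(vapply(epochs, inherits, logical(1), "demography_epoch")))
  }
  structure(list(N = as.integer(N), epochs = epochs,
                 seq_length = seq_length, mu = mu, rec_rate = rec_rate,
                 s = s, h = h, epsilon = epsilon,
                 neutral_fraction = neutral_fraction,
                 sample_n = sample_n, sample_pop = as.integer(sample_pop),
                 seed = as.integer(seed), scaling_factor = scaling_factor,
                 burn_in = burn_in, epistasis_count = epistasis_count),
            class = "sim_config")
}

# apply scaling_factor Q: N/Q, durations/Q, rates * Q
rescale_config <- function(cfg) {
  q <- cfg$scaling_factor
  if (q == 1) {
    cfg$.N_run <- cfg$N
    cfg$.epochs_run <- cfg$epochs
    return(cfg)
  }
  cfg$.N_run <- max(2L, as.integer(round(cfg$N / q)))
  cfg$.epochs_run <- lapply(cfg$epochs, function(e) {
    demography_epoch(max(0L, as.integer(round(e$duration / q))),
                     pmax(2L, as.integer(round(e$sizes / q))),
                     e$migration)
  })
  cfg$mu <- cfg$mu * q
  cfg$rec_rate <- cfg$rec_rate * q
  cfg$s <- max(-1, cfg$s * q)
  cfg$epsilon <- min(1, cfg$epsilon * q)
  if (!is.null(cfg$burn_in)) cfg$burn_in <- as.integer(round(cfg$burn_in / q))
  cfg
}

#' Diploid fitness with dominance and pairwise synergistic epistasis
#'
#' Per-individual fitness from the dosages at its deleterious loci:
#' \deqn{w = \prod_j w_j \cdot (1-\epsilon)^{k(k-1)/2},}
#' where w_j = 1 + s for a homozygous derived locus, 1 + h s for a
#' heterozygous locus and 1 otherwise, and k is the total number of
#' deleterious derived allele copies carried (with
#' `epistasis_count = "loci"`, the number of loci carrying at least one
#' copy). The pairwise penalty makes log-fitness concave (quadratic) in the
#' mutation burden — the standard synergistic-epistasis model, under which
#' selection removes individuals carrying many deleterious alleles
#' together and thereby generates negative LD among them. Fitness is
#' floored at 0.
#'
#' @param k_dosages integer vector of derived-allele dosages (0/1/2) at the
#'   deleterious loci of one individual
#' @param s selection coefficient (<= 0)
#' @param h dominance coefficient
#' @param epsilon synergistic-epistasis strength (>= 0)
#' @param epistasis_count "copies" or "loci" (see above)
#' @return fitness in [0, 1] (for s <= 0)
#' @export
genotype_fitness <- function(k_dosages, s, h, epsilon,
                             epistasis_count = c("copies", "loci")) {
  epistasis_count <- match.arg(epistasis_count)
  stopifnot(all(k_dosages %in% 0:2), s <= 0, epsilon >= 0)
  wj <- ifelse(k_dosages == 2L, 1 + s,
               ifelse(k_dosages == 1L, 1 + h * s, 1))
  k <- if (epistasis_count == "copies") sum(k_dosages)
       else sum(k_dosages > 0L)
  max(0, prod(pmax(wj, 0)) * max(0, 1 - epsilon)^(k * (k - 1) / 2))
}

# vectorised fitness over all individuals; H is 2N x S, s_site per column
fitness_vector <- function(H, s_site, s, h, eps, eps_count) {
  N <- nrow(H) %/% 2L
  del <- which(s_site < 0)
  if (!length(del)) return(rep(1, N))
  Hd <- H[, del, drop = FALSE]
  Dm <- Hd[seq(1L, 2L * N, 2L), , drop = FALSE] +
    Hd[seq(2L, 2L * N, 2L), , drop = FALSE]
  loghet <- log(pmax(1 + h * s_site[del], 1e-12))
  loghom <- log(pmax(1 + s_site[del], 1e-12))
  logw <- as.numeric((Dm == 1L) %*% loghet + (Dm == 2L) %*% loghom)
  if (eps > 0) {
    k <- if (eps_count == "copies") rowSums(Dm) else rowSums(Dm > 0L)
    logw <- logw + log(pmax(1 - eps, 1e-12)) * k * (k - 1) / 2
  }
  exp(logw - max(logw))
}

# one meiotic gamete per entry of `parents`; Poisson crossovers at uniform
# positions, mosaic read off by crossover-interval parity
make_gametes <- function(H, pos, parents, rec_bp, L) {
  m2 <- length(parents)
  S <- length(pos)
  start <- sample.int(2L, m2, replace = TRUE)
  if (S == 0L) return(matrix(0L, m2, 0L))
  nco <- stats::rpois(m2, rec_bp * L)
  G <- H[2L * (parents - 1L) + start, , drop = FALSE]
  for (g in which(nco > 0L)) {
    cuts <- sort(stats::runif(nco[g], 0, L))
    swap <- findInterval(pos, cuts) %% 2L == 1L
    if (any(swap)) {
      other <- H[2L * (parents[g] - 1L) + (3L - start[g]), ]
      G[g, swap] <- other[swap]
    }
  }
  G
}

# advance one Wright-Fisher generation; st: list(H, pos, s_site, subpop)
wf_step <- function(st, sizes_next, migration, cfg) {
  K <- length(sizes_next)
  M <- sum(sizes_next)
  w <- fitness_vector(st$H, st$s_site, cfg$s, cfg$h, cfg$epsilon,
                      cfg$epistasis_count)
  if (K == 1L) {
    parents <- sample.int(length(st$subpop), 2L * M, replace = TRUE,
                          prob = w)
  } else {
    new_subpop <- rep(seq_len(K), sizes_next)
    parents <- integer(2L * M)
    by_pop <- split(seq_along(st$subpop), st$subpop)
    for (k in seq_len(K)) {
      off <- which(new_subpop == k)
      probs <- if (is.null(migration)) {
        as.numeric(seq_len(K) == k)
      } else migration[k, ]
      for (slot in 1:2) {
        src <- sample.int(K, length(off), replace = TRUE, prob = probs)
        for (j in unique(src)) {
          pool <- by_pop[[as.character(j)]]
          if (is.null(pool) || !length(pool)) {
            # founding event: the source deme does not exist yet, so the
            # new deme is seeded from the first populated deme
            pool <- by_pop[[which(lengths(by_pop) > 0)[1]]]
          }
          tgt <- off[src == j]
          parents[2L * tgt - (2L - slot)] <-
            pool[sample.int(length(pool), length(tgt), replace = TRUE,
                            prob = w[pool])]
        }
      }
    }
  }
  G <- make_gametes(st$H, st$pos, parents, cfg$rec_rate, cfg$seq_length)
  # infinite-sites mutation on the offspring gametes
  n_new <- stats::rpois(1L, 2 * M * cfg$mu * cfg$seq_length)
  if (n_new > 0L) {
    new_pos <- stats::runif(n_new, 0, cfg$seq_length)
    # the selected class keeps its label even when s = 0, so neutral grid
    # cells still expose a selected-class locus set
    new_sel <- stats::runif(n_new) >= cfg$neutral_fraction
    new_s <- ifelse(new_sel, cfg$s, 0)
    cols <- matrix(0L, nrow(G), n_new)
    cols[cbind(sample.int(nrow(G), n_new, replace = TRUE),
               seq_len(n_new))] <- 1L
    pos <- c(st$pos, new_pos)
    ord <- order(pos)
    G <- cbind(G, cols)[, ord, drop = FALSE]
    pos <- pos[ord]
    s_site <- c(st$s_site, new_s)[ord]
    sel_site <- c(st$sel_site, new_sel)[ord]
  } else {
    pos <- st$pos
    s_site <- st$s_site
    sel_site <- st$sel_site
  }
  cs <- colSums(G)
  keep <- cs > 0L & cs < nrow(G)
  list(H = G[, keep, drop = FALSE], pos = pos[keep],
       s_site = s_site[keep], sel_site = sel_site[keep],
       subpop = if (K == 1L) rep(1L, M) else rep(seq_len(K), sizes_next))
}

# run `gens` generations of the compiled single-deme kernel
run_kernel <- function(st, gens, n_next, sc, prune = TRUE,
                       max_entries = 5e8) {
  if (gens < 1L) return(st)
  storage.mode(st$H) <- "integer"
  out <- .wf_run_cpp(st$H, st$pos, st$s_site, st$sel_site,
                     as.integer(gens), as.integer(n_next),
                     sc$mu, sc$rec_rate, sc$seq_length, sc$s, sc$h,
                     sc$epsilon, sc$neutral_fraction,
                     identical(sc$epistasis_count, "loci"), prune,
                     max_entries)
  out$subpop <- rep(1L, n_next)
  out
}

empty_state <- function(sizes) {
  list(H = matrix(0L, 2L * sum(sizes), 0L), pos = numeric(0),
       s_site = numeric(0), sel_site = logical(0),
       subpop = rep(seq_along(sizes), sizes))
}

# random subset of individuals (the bottleneck "resampling" operation)
subset_state <- function(st, n_keep, pop = 1L) {
  ids <- which(st$subpop == pop)
  if (n_keep > length(ids)) stop("cannot subset to more individuals than present")
  keep <- sort(sample(ids, n_keep))
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  H <- st$H[rows, , drop = FALSE]
  cs <- colSums(H)
  ok <- cs > 0L & cs < nrow(H)
  list(H = H[, ok, drop = FALSE], pos = st$pos[ok], s_site = st$s_site[ok],
       sel_site = st$sel_site[ok], subpop = rep(1L, n_keep))
}

#' Run a forward Wright-Fisher simulation
#'
#' Simulates discrete generations of a diploid random-mating population:
#' each offspring draws two parents with probability proportional to
#' fitness ([genotype_fitness()]), each parent transmits one recombinant
#' gamete (Poisson(rec_rate * L) crossovers at uniform positions), and
#' Poisson(2 N mu L) new infinite-sites mutations arise per generation,
#' each deleterious (coefficient s) with probability
#' 1 - neutral_fraction. After a burn-in of 10 N generations (configurable)
#' the epochs are applied in order; size changes are fitness-proportional
#' resamplings to the new sizes. Finally `sample_n` individuals are drawn
#' without replacement from the sampled subpopulation.
#'
#' The returned genotype matrix is already polarised (alleles are derived
#' by construction), carries per-locus selection coefficients and a
#' category label ("neutral" / "deleterious"), and has the sampled phased
#' haplotypes attached as `attr(, "haplotypes")` (2 sample_n x m binary,
#' columns aligned with the matrix) so that phased and unphased statistics
#' can be compared on identical data.
#'
#' @param cfg a [sim_config()]
#' @param init_state internal population state from a previous
#'   `return_state = TRUE` run; skips burn-in and applies `cfg$epochs` from
#'   that state (used to branch bottleneck scenarios off one equilibrium)
#' @param return_state also return the final internal state
#' @param max_entries guard on the haplotype-matrix size (2N x segregating
#'   sites); exceeding it aborts with advice to raise `scaling_factor`
#' @return a [genotype_matrix()] of the sample (loci monomorphic in the
#'   sample are dropped); with `return_state = TRUE`, a list
#'   `list(gm, state)`
#' @export
simulate_population <- function(cfg, init_state = NULL,
                                return_state = FALSE, max_entries = 5e8) {
  stopifnot(inherits(cfg, "sim_config"))
  sc <- rescale_config(cfg)
  with_seed(cfg$seed, {
    if (is.null(init_state)) {
      st <- empty_state(if (length(sc$.N_run) == 1L) sc$.N_run
                        else sc$.N_run)
      burn <- sc$burn_in %||% (10L * sum(sc$.N_run))
      if (length(unique(st$subpop)) == 1L) {
        st <- run_kernel(st, burn, sum(sc$.N_run), sc,
                         max_entries = max_entries)
      } else {
        for (g in seq_len(burn)) st <- wf_step(st, sc$.N_run, NULL, sc)
      }
    } else {
      st <- init_state
    }
    for (e in sc$.epochs_run) {
      if (e$duration == 0L) {
        if (is.null(e$migration) && length(e$sizes) == 1L &&
            length(unique(st$subpop)) == 1L &&
            e$sizes < length(st$subpop)) {
          # instantaneous downsizing, no reproduction: random subset
          st <- subset_state(st, e$sizes)
        }
        next
      }
      if (length(e$sizes) == 1L && is.null(e$migration) &&
          length(unique(st$subpop)) == 1L) {
        st <- run_kernel(st, e$duration, e$sizes, sc,
                         max_entries = max_entries)
      } else {
        for (g in seq_len(e$duration)) {
          st <- wf_step(st, e$sizes, e$migration, sc)
          if (length(st$pos) * nrow(st$H) > max_entries) {
            stop("population state exceeds memory budget; ",
                 "increase scaling_factor")
          }
        }
      }
    }
    gm <- state_to_sample(st, sc)
    if (return_state) list(gm = gm, state = st) else gm
  })
}

# draw the final sample and package it as a genotype_matrix + haplotypes
state_to_sample <- function(st, sc) {
  ids <- which(st$subpop == sc$sample_pop)
  n_s <- sc$sample_n %||% length(ids)
  n_s <- min(n_s, length(ids))
  keep <- sort(sample(ids, n_s))
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  H <- st$H[rows, , drop = FALSE]
  cs <- colSums(H)
  poly <- cs > 0L & cs < nrow(H)
  H <- H[, poly, drop = FALSE]
  pos <- st$pos[poly]
  s_site <- st$s_site[poly]
  sel_site <- st$sel_site[poly]
  ord <- order(pos)                 # kernel appends sites unsorted
  H <- H[, ord, drop = FALSE]
  pos <- pos[ord]
  s_site <- s_site[ord]
  sel_site <- sel_site[ord]
  dos <- H[seq(1L, nrow(H), 2L), , drop = FALSE] +
    H[seq(2L, nrow(H), 2L), , drop = FALSE]
  loci <- data.frame(chrom = rep("sim1", ncol(H)), pos = pos,
                     category = ifelse(sel_site, "deleterious", "neutral"),
                     s = s_site, stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, loci)
  attr(gm, "haplotypes") <- H   # columns sorted to match the matrix
  gm
}

#' Replicate a simulation grid and summarise LD statistics per cell
#'
#' Runs `n_reps` independently seeded simulations for every configuration
#' in `cfg_grid`, builds the deleterious and neutral locus sets of each
#' replicate under the given derived-allele-count conditioning (pairs are
#' thereby restricted to loci of the same selection coefficient), and
#' computes the requested statistics: ldcor / ldcorabs / netld per class,
#' nldcor (deleterious minus neutral), and the phased mean signed sqrt(r^2)
#' per class. Replicates with fewer than 2 usable loci in a class yield NA
#' for that class and are counted.
#'
#' @param cfg_grid named list of [sim_config()] objects (one per grid cell)
#' @param n_reps replicates per cell (>= 2)
#' @param mdac,mdaf,min_dac locus-set conditioning (see
#'   [select_locus_set()])
#' @param base_seed integer; replicate seeds are derived from it
#' @return data.frame with one row per (cell, replicate) and per-statistic
#'   columns; see [summarize_sweep()] for per-cell means and s.e.m.
#' @export
run_replicates <- function(cfg_grid, n_reps, mdac = NULL, mdaf = NULL,
                           min_dac = 2, base_seed = 1L) {
  stopifnot(n_reps >= 2)
  if (is.null(names(cfg_grid))) {
    names(cfg_grid) <- paste0("cell", seq_along(cfg_grid))
  }
  rows <- list()
  for (ci in seq_along(cfg_grid)) {
    cfg <- cfg_grid[[ci]]
    for (r in seq_len(n_reps)) {
      cfg$seed <- as.integer((base_seed * 100003 + ci * 1009 + r) %%
                               2147483647)
      gm <- simulate_population(cfg)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(cell = names(cfg_grid)[ci], rep = r,
                         stringsAsFactors = FALSE),
              replicate_stats(gm, mdac = mdac, mdaf = mdaf,
                              min_dac = min_dac))
    }
  }
  do.call(rbind, rows)
}

# per-replicate statistics on the deleterious and neutral classes
replicate_stats <- function(gm, mdac = NULL, mdaf = NULL, min_dac = 2) {
  H <- attr(gm, "haplotypes")
  one_class <- function(cat) {
    set <- tryCatch(
      select_locus_set(gm, category = cat, mdac = mdac, mdaf = mdaf,
                       min_dac = min_dac, drop_constant = TRUE),
      error = function(e) NULL)
    if (is.null(set)) {
      return(data.frame(n = 0L, ldcor = NA_real_, ldcorabs = NA_real_,
                        netld = NA_real_, ssr2 = NA_real_))
    }
    data.frame(n = length(set), ldcor = ldcor(set)$value,
               ldcorabs = ldcorabs(set)$value, netld = netld(set)$value,
               ssr2 = if (is.null(H)) NA_real_ else
                 signed_sqrt_r2_mean(H, set))
  }
  del <- one_class("deleterious")
  neu <- one_class("neutral")
  names(del) <- paste0(names(del), "_del")
  names(neu) <- paste0(names(neu), "_neut")
  out <- cbind(del, neu)
  out$nldcor <- out$ldcor_del - out$ldcor_neut
  out
}

#' Per-cell means and standard errors of a replicate table
#'
#' @param reps output of [run_replicates()]
#' @param stats columns to summarise
#' @return data.frame: one row per (cell, statistic) with mean, s.e.m.,
#'   and the number of non-missing replicates
#' @export
summarize_sweep <- function(reps,
                            stats = c("ldcor_del", "ldcorabs_del",
                                      "netld_del", "ldcor_neut",
                                      "nldcor")) {
  stats <- intersect(stats, names(reps))
  out <- list()
  for (cell in unique(reps$cell)) {
    sub <- reps[reps$cell == cell, , drop = FALSE]
    for (st in stats) {
      v <- sub[[st]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        cell = cell, statistic = st, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
              else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bottleneck sweep branched from shared equilibria
#'
#' For each replicate, one base population is evolved to equilibrium under
#' `base_cfg`; every (size, duration) bottleneck scenario is then branched
#' from that same equilibrium state: the population is randomly subset to
#' the bottleneck size, evolved for the given number of generations, and
#' sampled. `size = N` with `duration = 0` is the no-bottleneck baseline.
#'
#' @param base_cfg a [sim_config()] (constant-size model)
#' @param sizes bottleneck diploid sizes (pre-rescaling)
#' @param durations bottleneck durations in generations (pre-rescaling)
#' @param n_reps replicates
#' @param min_dac,mdac locus-set conditioning for the LDcor computed on all
#'   polymorphic loci of each branch sample
#' @param base_seed integer seed
#' @return data.frame with cell (size x duration), rep and ldcor columns
#' @export
bottleneck_sweep <- function(base_cfg, sizes, durations, n_reps,
                             min_dac = 2, mdac = NULL, base_seed = 1L) {
  q <- base_cfg$scaling_factor
  rows <- list()
  for (r in seq_len(n_reps)) {
    base_cfg$seed <- as.integer((base_seed * 7919 + r) %% 2147483647)
    base <- simulate_population(base_cfg, return_state = TRUE)
    for (nb in sizes) {
      for (d in durations) {
        branch_cfg <- base_cfg
        branch_cfg$seed <-
          as.integer(((base_seed * 7919 + r) * 31 + nb * 17 + d) %%
                       2147483647)
        branch_cfg$epochs <- list(demography_epoch(d, nb))
        branch_cfg$sample_n <- min(base_cfg$sample_n %||% nb,
                                   max(2L, as.integer(round(nb / q))))
        gm <- simulate_population(branch_cfg, init_state = base$state)
        val <- tryCatch({
          set <- select_locus_set(gm, mdac = mdac, min_dac = min_dac,
                                  drop_constant = TRUE)
          ldcor(set)$value
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          size = nb, duration = d, rep = r, ldcor = val)
      }
    }
  }
  do.call(rbind, rows)
}

#' Single-mutant fixation probability of the simulator
#'
#' Calibration utility: injects one mutant gamete into an equilibrium-free
#' population of N diploids, disables mutation, and iterates the
#' simulator's own reproduction engine until the allele fixes or is lost.
#' Under neutrality the fixation probability is 1/(2N).
#'
#' @param N diploid size
#' @param s,h selection and dominance of the tracked allele
#' @param n_reps replicates
#' @param seed integer seed
#' @return proportion of replicates that fixed
#' @export
simulate_fixation <- function(N, s = 0, h = 0.5, n_reps = 2000,
                              seed = 1L) {
  cfg <- sim_config(N = N, mu = 0, s = min(s, 0), h = h,
                    neutral_fraction = 0)
  sc <- rescale_config(cfg)
  with_seed(seed, {
    fixed <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      H <- matrix(0L, 2L * N, 1L)
      H[sample.int(2L * N, 1L), 1L] <- 1L
      st <- list(H = H, pos = 0.5, s_site = s, sel_site = s < 0,
                 subpop = rep(1L, N))
      repeat {
        st <- run_kernel(st, 10L, N, sc, prune = FALSE)
        cs <- sum(st$H)
        if (cs == 0L) { fixed[r] <- FALSE; break }
        if (cs == 2L * N) { fixed[r] <- TRUE; break }
      }
    }
    mean(fixed)
  })
}

#' Neutral drift of a standing allele (martingale check)
#'
#' Calibration utility: places a standing allele at initial frequency `p0`
#' on random gametes, runs `n_gens` generations of the simulator's
#' reproduction engine without mutation, and returns the final frequency
#' of each replicate. With s = 0 the frequency is a martingale: the mean
#' final frequency equals `p0` up to Monte-Carlo error.
#'
#' @param N diploid size
#' @param p0 initial allele frequency
#' @param n_gens generations to evolve
#' @param n_reps replicates
#' @param s,h selection and dominance
#' @param seed integer seed
#' @return numeric vector of final frequencies (length `n_reps`)
#' @export
simulate_frequency_change <- function(N, p0, n_gens, n_reps, s = 0,
                                      h = 0.5, seed = 1L) {
  stopifnot(p0 > 0, p0 < 1)
  with_seed(seed, {
    dac0 <- max(1L, round(p0 * 2 * N))
    out <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      H <- matrix(0L, 2L * N, 1L)
      H[sample.int(2L * N, dac0), 1L] <- 1L
      st <- list(H = H, pos = 0.5, s_site = s, sel_site = s < 0,
                 subpop = rep(1L, N))
      cfg2 <- sim_config(N = N, mu = 0, s = min(s, 0), h = h,
                         neutral_fraction = 0)
      st <- run_kernel(st, n_gens, N, rescale_config(cfg2),
                       prune = FALSE)
      out[r] <- sum(st$H) / (2 * N)
    }
    out
  })
}

#' Preset demographies
#'
#' `model1_config()` is the constant-size model. `gravel_human_epochs()`
#' returns a three-population human demography after the published model of
#' Gravel et al. (2011, PNAS): an ancestral African expansion, an
#' out-of-Africa bottleneck, and a European/Asian split with stepwise
#' exponential growth (approximated by piecewise-constant epochs), with or
#' without the published continent-pair migration rates. These numbers are
#' externally sourced presets for the expansion ("model 2", no migration)
#' and expansion-plus-gene-flow ("model 3") scenarios; they are editable
#' inputs, not package results.
#'
#' @param N diploid size (model 1)
#' @param generations post-burn-in generations (model 1)
#' @param migration include the Gravel et al. migration rates ("model 3")
#'   or not ("model 2")
#' @param growth_steps epochs used to approximate exponential growth
#' @param ... passed to [sim_config()]
#' @return a [sim_config()] (model1) or a list of [demography_epoch()]
#' @export
model1_config <- function(N = 10000, generations = 100000, ...) {
  sim_config(N = N, epochs = list(demography_epoch(generations, N)), ...)
}

#' @rdname model1_config
#' @export
gravel_human_epochs <- function(migration = TRUE, growth_steps = 5L) {
  # Gravel et al. (2011): N_A=7310, N_AF=14474 (5920 gen ago), OOA
  # bottleneck N_B=1861 (2040 gen), EUR/ASN split 920 gen ago with
  # N_EU 1032 -> 9300 (r=0.38%/gen), N_AS 554 -> 10740 (r=0.48%/gen);
  # migration per gen: AF<->B 15e-5, AF<->EU 2.5e-5, AF<->AS 0.78e-5,
  # EU<->AS 3.11e-5
  mig3 <- function(af_eu, af_as, eu_as) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- af_eu
    m[1, 3] <- m[3, 1] <- af_as
    m[2, 3] <- m[3, 2] <- eu_as
    diag(m) <- 1 - rowSums(m)
    m
  }
  eps <- list(
    demography_epoch(5920 - 2040, c(14474L)),
    demography_epoch(2040 - 920, c(14474L, 1861L),
                     if (migration) {
                       m <- matrix(c(1 - 15e-5, 15e-5, 15e-5, 1 - 15e-5),
                                   2, 2, byrow = TRUE)
                       m
                     })
  )
  # stepwise growth of EUR (1032 -> 9300) and ASN (554 -> 10740)
  step_len <- as.integer(floor(920 / growth_steps))
  for (k in seq_len(growth_steps)) {
    f <- k / growth_steps
    eps[[length(eps) + 1L]] <- demography_epoch(
      if (k < growth_steps) step_len else 920 - step_len * (growth_steps - 1),
      c(14474L, as.integer(round(1032 * (9300 / 1032)^f)),
        as.integer(round(554 * (10740 / 554)^f))),
      if (migration) mig3(2.5e-5, 0.78e-5, 3.11e-5))
  }
  eps
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML mirrors the [sim_config()] fields; epochs are a list of
#' mappings with `duration`, `sizes` and optional `migration` (row-major).
#'
#' @param path YAML file path
#' @return `read_sim_config`: a [sim_config()]
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  epochs <- NULL
  if (!is.null(y$epochs)) {
    epochs <- lapply(y$epochs, function(e) {
      mig <- if (!is.null(e$migration)) {
        matrix(unlist(e$migration), length(e$sizes), byrow = TRUE)
      }
      demography_epoch(e$duration, unlist(e$sizes), mig)
    })
    y$epochs <- NULL
  }
  args <- y[intersect(names(y), names(formals(sim_config)))]
  args$epochs <- epochs
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()]
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  y <- unclass(cfg)
  y <- y[!vapply(y, is.null, logical(1))]
  if (!is.null(cfg$epochs)) {
    y$epochs <- lapply(cfg$epochs, function(e) {
      out <- list(duration = e$duration, sizes = as.list(e$sizes))
      if (!is.null(e$migration)) {
        out$migration <- lapply(seq_len(nrow(e$migration)),
                                function(i) as.list(e$migration[i, ]))
      }
      out
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
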