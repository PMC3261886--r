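#' The delta discordance statistic
#'
#' The percent difference between the measured sp1--sp2 divergence (the
#' tMRCA of the sampled genes, read from an estimated clock gene tree)
#' and the true speciation time: `100 * (tmrca - tau) / tau`.  Because
#' gene divergence predates species divergence under the coalescent,
#' delta is positive in expectation and quantifies the maximum
#' overestimation a phylogenetic (gene-tree) dating approach commits.
#'
#' @param tmrca_myr Measured divergence, Myr.
#' @param tau_true_myr True split time, Myr (> 0).
#' @return Percent discordance (vectorized).
#' @export
delta_statistic <- function(tmrca_myr, tau_true_myr) {
  if (any(tau_true_myr <= 0)) stop("true split time must be positive")
  100 * (tmrca_myr - tau_true_myr) / tau_true_myr
}

#' Box-plot style whisker summary of percent errors
#'
#' Quartiles use the linear-interpolation convention (R's default type
#' 7); the whiskers are the lowest and highest values still inside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.  The mean is reported alongside, so
#' a condition is summarized as mean plus a robust range, as in the
#' performance figures of multilocus simulation studies.
#'
#' @param estimates Numeric vector (>= 4 values) of percent errors.
#' @return List: `mean`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n`.
#' @export
whisker_summary <- function(estimates) {
  if (length(estimates) < 4) stop("need at least 4 values")
  q <- stats::quantile(estimates, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  inside <- estimates[estimates >= lo & estimates <= hi]
  list(mean = mean(estimates), q1 = q[1], q3 = q[2],
       whisker_low = min(inside), whisker_high = max(inside),
       n = length(estimates))
}

# deterministic per-(replicate, locus) seed substreams from a root seed
substream_seed <- function(root_seed, replicate, locus = 0L) {
  (as.double(root_seed) * 1000003 + replicate * 10007 + locus * 101) %%
    2147483647
}

#' Simulate one multilocus replicate (gene trees + alignments)
#'
#' @param st A [species_tree()].
#' @param strategy List of [marker_profile()]s.
#' @param n_per_species Sequences per ingroup species (sp1, sp2; all
#'   non-outgroup species for radiation trees).
#' @param seed Replicate seed (per-locus substreams are derived).
#' @param ingroup Species sampled at `n_per_species`; others get 1.
#' @return List with `gene_trees` and `alignments`.
#' @export
simulate_replicate <- function(st, strategy, n_per_species, seed,
                               ingroup = c("sp1", "sp2")) {
  samples <- stats::setNames(
    ifelse(st$labels %in% ingroup, n_per_species, 1L), st$labels)
  gts <- list(); alns <- list()
  for (l in seq_along(strategy)) {
    gts[[l]] <- simulate_gene_genealogy(st, strategy[[l]], samples,
                                        rng_seed = substream_seed(seed, 0, l))
    alns[[l]] <- evolve_alignment(gts[[l]],
                                  rng_seed = substream_seed(seed, 1, l))
  }
  list(gene_trees = gts, alignments = alns)
}

#' Gene-tree (concatenation) discordance experiment
#'
#' For each study condition: simulates replicate multilocus data sets,
#' estimates one concatenated clock gene tree per replicate (per-locus
#' HKY+Gamma ML distances, NJ, Langley-Fitch clock, K-score rescale),
#' measures the sp1--sp2 tMRCA in Myr, and summarizes delta across
#' replicates.  This is the "classical phylogenetics" arm of the study:
#' it quantifies how badly gene-tree dating overestimates shallow
#' splits.
#'
#' @param grid List of [study_condition()]s.
#' @param seed Root seed; every replicate derives its own substream.
#' @return Data frame with one row per condition: mean tmrca, mean
#'   delta, whiskers, and the per-replicate values as an attribute.
#' @export
run_discordance_grid <- function(grid, seed = 1L) {
  if (!length(grid)) stop("empty condition grid")
  rows <- list(); percond <- list()
  for (ci in seq_along(grid)) {
    cond <- grid[[ci]]
    st <- build_focal_tree(cond$theta_mit, cond$u_mit, cond$tau1_myr)
    tm <- numeric(cond$n_replicates)
    for (r in seq_len(cond$n_replicates)) {
      rep_seed <- substream_seed(seed, 1000 * ci + r)
      dat <- simulate_replicate(st, cond$strategy, cond$n_per_species,
                                rep_seed)
      est <- estimate_gene_tree(dat$alignments)
      clk <- kscore_rescale(langley_fitch_clock(est), est)
      tm[r] <- tmrca_sp1_sp2(clk)
    }
    deltas <- delta_statistic(tm, cond$tau1_myr)
    w <- whisker_summary(deltas)
    rows[[ci]] <- data.frame(
      condition = cond$id, tau1_myr = cond$tau1_myr,
      theta_mit = cond$theta_mit, u_mit = cond$u_mit,
      n_loci = length(cond$strategy),
      mean_tmrca_myr = mean(tm), mean_delta = w$mean,
      whisker_low = w$whisker_low, whisker_high = w$whisker_high,
      se_tmrca = stats::sd(tm) / sqrt(length(tm)),
      n_replicates = cond$n_replicates)
    percond[[cond$id]] <- data.frame(replicate = seq_along(tm),
                                     tmrca_myr = tm, delta = deltas)
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- percond
  out
}

#' Bayesian multilocus (MB) divergence-time experiment
#'
#' For each condition: simulates replicates, sets the divergence-time
#' prior empirically (exponential with mean equal to the average
#' minimum sp1--sp2 divergence in per-locus clock trees, mitochondrial
#' trees rescaled to the nuclear rate), runs [sample_msc_posterior()]
#' on the fixed 4-taxon topology, and summarizes the percent error of
#' the posterior-mean tau1 with [whisker_summary()].
#'
#' @inheritParams run_discordance_grid
#' @param mcmc [mcmc_settings()] shared by all runs.
#' @param rate_mode,heredity_mode Passed to [sample_msc_posterior()];
#'   `rate_mode = "fixed_external"` computes the multipliers per
#'   replicate from the per-locus ML trees.
#' @param rate_jitter When `TRUE`, nuclear locus rates are drawn
#'   uniformly from 0.7--1.4 times the mean (the among-loci
#'   rate-variation experiment).
#' @return Data frame of per-condition summaries; per-replicate percent
#'   errors in `attr(, "replicates")`.
#' @export
run_mb_grid <- function(grid, seed = 1L, mcmc = mcmc_settings(),
                        rate_mode = "fixed_true",
                        heredity_mode = "fixed_true",
                        rate_jitter = FALSE) {
  if (!length(grid)) stop("empty condition grid")
  rows <- list(); percond <- list()
  for (ci in seq_along(grid)) {
    cond <- grid[[ci]]
    st <- build_focal_tree(cond$theta_mit, cond$u_mit, cond$tau1_myr)
    true_tau1 <- cond$tau1_myr * cond$u_mit / 10
    errs <- numeric(cond$n_replicates)
    for (r in seq_len(cond$n_replicates)) {
      rep_seed <- substream_seed(seed, 1000 * ci + r)
      errs[r] <- mb_replicate(st, cond, rep_seed, true_tau1, mcmc,
                              rate_mode, heredity_mode, rate_jitter)
    }
    w <- whisker_summary(errs)
    rows[[ci]] <- data.frame(
      condition = cond$id, tau1_myr = cond$tau1_myr,
      n_loci = length(cond$strategy),
      mean_percent_error = w$mean,
      whisker_low = w$whisker_low, whisker_high = w$whisker_high,
      n_replicates = cond$n_replicates)
    percond[[cond$id]] <- errs
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- percond
  out
}

# one replicate of the MB experiment; returns the percent error of tau1
mb_replicate <- function(st, cond, rep_seed, true_tau1, mcmc,
                         rate_mode, heredity_mode, rate_jitter) {
  strategy <- cond$strategy
  if (rate_jitter) {
    set.seed(substream_seed(rep_seed, 7))
    strategy <- lapply(strategy, function(p) {
      if (p$marker_class == "nuclear") {
        mult <- stats::runif(1, 0.7, 1.4)
        p$rate_multiplier <- p$rate_multiplier * mult
        p$per_lineage_rate <- p$per_lineage_rate * mult
      }
      p
    })
  }
  dat <- simulate_replicate(st, strategy, cond$n_per_species, rep_seed)
  # empirical tau prior: average minimum sp1-sp2 divergence in per-locus
  # clock trees; mitochondrial trees are put on the nuclear scale
  trees <- lapply(seq_along(strategy), function(l) {
    est <- estimate_gene_tree(dat$alignments[[l]])
    kscore_rescale(langley_fitch_clock(est), est)
  })
  is_mit <- vapply(strategy, function(p)
    p$marker_class == "mitochondrial", logical(1))
  m <- if (any(is_mit)) {
    tau_prior_mean(trees[is_mit], rate_ratio = 10)
  } else {
    tau_prior_mean(trees, rate_ratio = 1)
  }
  pr <- msc_priors(tau_mean = max(m, 1e-6))
  ext <- NULL
  if (rate_mode == "fixed_external")
    ext <- estimate_rate_ratios_external(trees)
  tr <- sample_msc_posterior(dat$alignments, st$phylo, pr,
                             cond$strategy, mcmc = mcmc,
                             rng_seed = substream_seed(rep_seed, 13),
                             rate_mode = rate_mode,
                             heredity_mode = heredity_mode,
                             external_rates = ext)
  summarize_percent_error(tr, true_tau1)
}

#' Radiation topology-recovery experiment
#'
#' Simulates replicate multilocus data sets under a 5-taxon radiation
#' species tree and estimates the species-tree topology per replicate
#' with [sample_topology_posterior()]; reports the proportion of
#' replicates whose MAP topology equals the truth and the mean rooted
#' Robinson-Foulds distance.
#'
#' @param scenario `"moderate"` or `"fast"` (see
#'   [build_radiation_tree()]).
#' @param strategy List of marker profiles (e.g. 10 nuclear, or 4
#'   nuclear + 1 mitochondrial).
#' @param n_replicates Number of replicate data sets.
#' @param seed Root seed.
#' @param theta_nuc Nuclear theta of the radiation tree.
#' @param mcmc [mcmc_settings()] per replicate.
#' @param n_per_species Sequences per species (1 for sp5).
#' @return List: `percent_correct`, `mean_rf`, `results` data frame.
#' @export
run_radiation_experiment <- function(scenario, strategy, n_replicates = 30L,
                                     seed = 1L, theta_nuc = 0.01,
                                     mcmc = mcmc_settings(),
                                     n_per_species = 5L) {
  rt <- build_radiation_tree(scenario, theta_nuc)
  truth <- canonical_topology(rt)
  maps <- character(n_replicates)
  rfs <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- substream_seed(seed, r)
    dat <- simulate_replicate(rt, strategy, n_per_species, rep_seed,
                              ingroup = c("sp1", "sp2", "sp3", "sp4"))
    # empirical tau prior from the shallowest split, as in the 4-taxon runs
    pr <- msc_priors(tau_mean = 2 * theta_nuc, root_mean = 6 * theta_nuc)
    tp <- sample_topology_posterior(dat$alignments, pr, strategy,
                                    mcmc = mcmc,
                                    rng_seed = substream_seed(rep_seed, 13))
    maps[r] <- tp$map_topology
    rfs[r] <- rf_distance(tp$map_topology, rt$phylo)
  }
  correct <- vapply(maps, function(m)
    canonical_topology(m) == truth, logical(1))
  list(percent_correct = 100 * mean(correct), mean_rf = mean(rfs),
       results = data.frame(replicate = seq_len(n_replicates),
                            map = maps, rf = rfs,
                            correct = unname(correct)))
}
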