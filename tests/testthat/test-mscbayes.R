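test_that("theta prior derivation matches the documented Gamma", {
  pr <- derive_theta_prior(0.025, c(0.003, 0.07))
  expect_equal(pr$shape, 2, tolerance = 0.1)
  expect_equal(pr$shape * pr$scale, 0.025, tolerance = 1e-8)
  expect_lt(abs(pr$ci95[1] - 0.003) / 0.003, 0.1)
  expect_lt(abs(pr$ci95[2] - 0.07) / 0.07, 0.1)
  # self-consistency: CI of a known Gamma recovers its shape
  k <- 3.7; m <- 0.02
  ci <- stats::qgamma(c(0.025, 0.975), shape = k, scale = m / k)
  rec <- derive_theta_prior(m, ci)
  expect_equal(rec$shape, k, tolerance = 0.01 * k)
  # an impossibly tight interval has no Gamma solution
  expect_error(derive_theta_prior(0.025, c(0.024, 0.026)), "no Gamma")
})

test_that("external rate ratios are tree-length ratios with mean one", {
  mk <- function(lens) {
    phy <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
    phy$edge.length <- rep(lens / 4, 4)
    structure(list(phylo = phy), class = "estimated_gene_tree")
  }
  r <- estimate_rate_ratios_external(list(mk(1), mk(1)))
  expect_equal(r, c(1, 1))
  r2 <- estimate_rate_ratios_external(list(mk(10), mk(1), mk(1)))
  expect_equal(r2[1] / r2[2], 10)
  expect_equal(mean(r2), 1)
  expect_equal(rev(estimate_rate_ratios_external(list(mk(1), mk(10)))),
               estimate_rate_ratios_external(list(mk(10), mk(1))),
               ignore_attr = TRUE)
  expect_error(estimate_rate_ratios_external(list(mk(1))))
  expect_error(estimate_rate_ratios_external(list(mk(0), mk(1))))
})

test_that("percent error summary is the signed relative posterior-mean error", {
  fake <- function(tau1, scale = 1) structure(
    list(tau1 = tau1, tau_scale = scale), class = "msc_trace")
  expect_equal(summarize_percent_error(fake(rep(0.01, 5)), 0.01), 0)
  expect_equal(summarize_percent_error(fake(rep(0.012, 5)), 0.01), 20)
  expect_equal(summarize_percent_error(fake(rep(0.008, 5)), 0.01), -20)
  # the sampler-scale conversion divides by tau_scale
  expect_equal(summarize_percent_error(fake(rep(0.028, 5), 2.8), 0.01), 0)
  expect_error(summarize_percent_error(fake(numeric(0)), 0.01))
})

test_that("with likelihood off the sampler reproduces its priors", {
  pr <- msc_priors(tau_mean = 0.002)
  prof <- nuc_strategy(2)
  tr <- sample_msc_posterior(NULL, "(((sp1,sp2),sp3),sp4);", pr, prof,
                             mcmc = mcmc_settings(24000, 3000, 10),
                             rng_seed = 11, likelihood_on = FALSE)
  sub <- seq(1, length(tr$tau1), 5)
  expect_gt(stats::ks.test(tr$tau1[sub], "pexp", 1 / 0.002)$p.value, 0.01)
  th <- tr$theta[seq(1, nrow(tr$theta), 5), 2]
  expect_gt(stats::ks.test(th, "pgamma", pr$theta_shape,
                           scale = pr$theta_scale)$p.value, 0.01)
  # root age = sum of three Exp(0.002) increments
  iroot <- grep("sp4", colnames(tr$tau))
  expect_equal(mean(tr$tau[, iroot]), 0.006, tolerance = 0.12)
})

test_that("zero-information alignments return the prior", {
  labels <- c("sp1_1", "sp2_1", "sp3_1", "sp4_1")
  prof <- marker_profile("nuclear", kappa = 1, gamma_shape = 1,
                         n_categories = 1L, length = 1L)
  aln <- structure(list(mat = matrix(1L, 4, 1, dimnames = list(labels, NULL)),
                        labels = labels, profile = prof),
                   class = "locus_alignment")
  pr <- msc_priors(tau_mean = 0.003)
  tr <- sample_msc_posterior(list(aln), "(((sp1,sp2),sp3),sp4);", pr,
                             list(prof), mcmc = mcmc_settings(20000, 3000, 10),
                             rng_seed = 21)
  expect_equal(mean(tr$tau1), 0.003, tolerance = 0.12)
  expect_equal(mean(tr$theta), 0.025, tolerance = 0.08)
})

test_that("single-population posterior matches a brute-force grid", {
  set.seed(4)
  prof <- marker_profile("nuclear", kappa = 1, gamma_shape = 1,
                         n_categories = 1L, length = 1000L)
  gt <- sim_single_pop_tree(2L, "sp1", 0.01, prof)
  aln <- evolve_alignment(gt, rng_seed = 77)
  x <- sum(aln$mat[1, ] != aln$mat[2, ]); L <- 1000
  pr <- msc_priors(theta_mean = 0.025)
  tr <- sample_msc_posterior(list(aln), "sp1", pr, list(prof),
                             mcmc = mcmc_settings(120000, 5000, 20),
                             rng_seed = 2)
  th_samp <- tr$theta[seq(1, nrow(tr$theta), 2), 1]
  thg <- seq(1e-4, 0.15, length.out = 500)
  tg <- seq(1e-6, 0.1, length.out = 800)
  p1 <- function(d) 0.25 - 0.25 * exp(-4 * d / 3)
  p0 <- function(d) 0.25 + 0.75 * exp(-4 * d / 3)
  loglik <- x * log(p1(2 * tg)) + (L - x) * log(p0(2 * tg))
  post <- vapply(thg, function(th)
    sum(exp(loglik - max(loglik)) * (2 / th) * exp(-2 * tg / th)) *
      stats::dgamma(th, pr$theta_shape, scale = pr$theta_scale), numeric(1))
  post <- post / sum(post)
  Fth <- stats::approxfun(thg, cumsum(post), yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(th_samp, Fth))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("one joint sweep preserves the prior-predictive distribution", {
  # successive-conditional (Geweke-style) check on a tiny configuration:
  # draw from the joint, alternate [MCMC sweep | data] with
  # [data | gene tree]; the parameter marginals must stay at the prior
  topo <- "(((sp1,sp2),sp3),sp4);"
  labels <- c("sp1_1", "sp1_2", "sp2_1", "sp2_2", "sp3_1", "sp4_1")
  prof <- marker_profile("nuclear", kappa = 1, gamma_shape = 1,
                         n_categories = 1L, length = 50L)
  pr <- msc_priors(tau_mean = 0.003)
  phy <- ape::read.tree(text = topo)
  i_tau1 <- ape::getMRCA(phy, 1:2)
  dummy <- structure(list(mat = matrix(1L, 6, 50,
                                       dimnames = list(labels, NULL)),
                          labels = labels, profile = prof),
                     class = "locus_alignment")
  mc <- mcmc_settings(n_gen = 5, burnin = 0, sample_every = 5, adapt = FALSE)
  boot <- sample_msc_posterior(list(dummy), topo, pr, list(prof),
                               mcmc = mcmc_settings(300, 0, 300,
                                                    adapt = FALSE),
                               rng_seed = 1, likelihood_on = FALSE)
  state <- boot$state
  n_rounds <- 2000
  tau1 <- thr <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    stl <- state$loci[[1]]
    gt <- structure(list(parent = ifelse(stl$parent < 0, 0L, stl$parent + 1L),
                         ages = stl$age, tip_species = sub("_.*$", "", labels),
                         tip_labels = labels, ntip = 6L, profile = prof),
                    class = "gene_tree")
    aln <- evolve_alignment(gt, rng_seed = 11 + 7 * r)
    out <- sample_msc_posterior(list(aln), topo, pr, list(prof), mcmc = mc,
                                rng_seed = 13 + 17 * r, init_state = state)
    state <- out$state
    tau1[r] <- state$tau[i_tau1]
    thr[r] <- state$theta[5]
  }
  # batch-mean z-scores against the known prior means
  nb <- 10; bs <- n_rounds / nb
  z <- function(x, mu) {
    m <- tapply(x, rep(1:nb, each = bs), mean)
    (mean(x) - mu) / (stats::sd(m) / sqrt(nb))
  }
  expect_lt(abs(z(tau1, 0.003)), 4)
  expect_lt(abs(z(thr, 0.025)), 4)
})

test_that("the pruning likelihood matches an independent implementation", {
  skip_if_not_installed("phangorn")
  st <- focal_tree_default()
  for (cfg in list(list(prof = marker_profile("nuclear", kappa = 1,
                                              gamma_shape = 1,
                                              n_categories = 1L,
                                              length = 300L),
                        kappa = 1, Q = rep(1, 6)),
                   list(prof = mito_profile(0.01), kappa = 10,
                        Q = c(1, 10, 1, 1, 10, 1)))) {
    gt <- simulate_gene_genealogy(st, cfg$prof,
                                  c(sp1 = 2, sp2 = 2, sp3 = 1, sp4 = 1),
                                  rng_seed = 3)
    aln <- evolve_alignment(gt, rng_seed = 4)
    parent <- as.integer(gt$parent) - 1L
    parent[gt$parent == 0] <- -1L
    cp <- compress_patterns(aln$mat[gt$tip_labels, ])
    loc <- list(parent = parent, age = gt$ages,
                tipsp = match(gt$tip_species, st$labels) - 1L,
                rate = cfg$prof$rate_multiplier, hered = 1,
                hered_prior_mean = 1, kappa = cfg$kappa,
                patterns = cp$patterns, wt = cp$wt)
    ll <- coaldelta:::jc_loglik_cpp(loc)
    chmat <- matrix(coaldelta:::NUC[aln$mat], nrow(aln$mat),
                    dimnames = list(aln$labels, NULL))
    fit <- phangorn::pml(as_phylo(gt), phangorn::phyDat(chmat),
                         Q = cfg$Q, bf = rep(0.25, 4))
    expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-8)
  }
})

test_that("the mcmc profiles expose the documented chain settings", {
  p <- mcmc_settings(profile = "paper")
  expect_equal(p$n_gen, 1000000L)
  expect_equal(p$burnin, 150000L)
  expect_equal(p$sample_every, 100L)
  ci <- mcmc_settings()
  expect_lt(ci$n_gen, p$n_gen)
})
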