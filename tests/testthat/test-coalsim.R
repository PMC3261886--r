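test_that("degenerate samples behave as the coalescent dictates", {
  st <- focal_tree_default()
  # a single lineage never coalesces
  g1 <- simulate_gene_genealogy(st, nuclear_profile(), c(sp1 = 1),
                                rng_seed = 1)
  expect_equal(g1$ntip, 1L)
  expect_equal(gene_tmrca(g1), 0)
  # theta -> 0: instant coalescence right above the split
  st0 <- build_focal_tree(2.5e-10, 0.01, 5)   # tau1 = 0.005, theta ~ 1e-10
  g0 <- simulate_gene_genealogy(st0, nuclear_profile(), c(sp1 = 1, sp2 = 1),
                                rng_seed = 2)
  expect_equal(gene_tmrca(g0), 0.005, tolerance = 1e-5)
  expect_error(simulate_gene_genealogy(st, nuclear_profile(),
                                       c(bogus = 2)))
  expect_error(simulate_gene_genealogy(st, nuclear_profile(),
                                       c(sp1 = 0)))
})

test_that("pairwise and n-lineage mean coalescent times match closed forms", {
  # pairwise: E[tMRCA] = tau1 + theta/2 (constant theta above the split)
  st <- species_tree("(sp1,sp2);", c(0, 0, 0.005), 0.025)
  set.seed(101)
  n <- 6000
  tm <- replicate(n, gene_tmrca(
    simulate_gene_genealogy(st, nuclear_profile(), c(sp1 = 1, sp2 = 1))))
  se <- stats::sd(tm) / sqrt(n)
  expect_lt(abs(mean(tm) - (0.005 + 0.025 / 2)), 3 * se)
  # 10 lineages in one population: E[tMRCA] = theta * (1 - 1/10)
  set.seed(102)
  tm10 <- replicate(n, max(sim_single_pop_tree(10L, "sp1", 0.025,
                                               nuclear_profile())$ages))
  se10 <- stats::sd(tm10) / sqrt(n)
  expect_lt(abs(mean(tm10) - 0.025 * (1 - 1 / 10)), 3 * se10)
})

test_that("gene trees are ultrametric and respect population floors", {
  st <- focal_tree_default()
  mrca_pop <- function(gt, v, masks, fn) fn(masks[v])
  for (seed in 1:25) {
    gt <- simulate_gene_genealogy(st, mito_profile(0.01), focal_samples,
                                  rng_seed = seed)
    phy <- as_phylo(gt)
    expect_true(ape::is.ultrametric(phy, tol = 1e-8))
    expect_false(is.infinite(msc_log_density(gt, st)))
  }
})

test_that("msc_log_density matches the closed form and flags violations", {
  st <- species_tree("(sp1,sp2);", c(0, 0, 0.005), 0.01)
  gt <- two_tip_gene_tree(0.007)
  # one event in pop12 after waiting 0.002: log(2/theta) - (2/theta)*0.002
  expect_equal(msc_log_density(gt, st), log(200) - 200 * 0.002)
  # single-population closed form at theta_eff with a heredity multiplier
  mp <- mito_profile()   # h = 0.25 -> theta_eff = 0.0025 above the split
  gt_m <- two_tip_gene_tree(0.007, profile = mp)
  expect_equal(msc_log_density(gt_m, st),
               log(2 / 0.0025) - 2 / 0.0025 * 0.002)
  # a coalescence below the species split is impossible
  bad <- two_tip_gene_tree(0.004)
  d <- msc_log_density(bad, st)
  expect_true(is.infinite(d) && d < 0)
  expect_true(attr(d, "invalid"))
})

test_that("R and C++ density implementations agree on simulated trees", {
  st <- focal_tree_default()
  for (seed in 1:10) {
    gt <- simulate_gene_genealogy(st, mito_profile(0.01), focal_samples,
                                  rng_seed = seed)
    parent <- as.integer(gt$parent) - 1L
    parent[gt$parent == 0] <- -1L
    r_val <- msc_log_density(gt, st)
    c_val <- coaldelta:::msc_logdensity_cpp(
      coaldelta:::sp_to_clist(st),
      list(parent = parent, age = gt$ages,
           tipsp = match(gt$tip_species, st$labels) - 1L,
           rate = 10, hered = 0.25, hered_prior_mean = 0.25,
           patterns = NULL, wt = NULL))
    expect_equal(r_val, c_val, tolerance = 1e-10)
  }
})

test_that("simulated pairwise tMRCA matches the analytic density (KS)", {
  # tMRCA - tau ~ Exp(2/theta) for a pair in an infinite root population
  st <- species_tree("(sp1,sp2);", c(0, 0, 0.003), 0.01)
  set.seed(33)
  tm <- replicate(4000, gene_tmrca(
    simulate_gene_genealogy(st, nuclear_profile(), c(sp1 = 1, sp2 = 1))))
  ks <- stats::ks.test(tm - 0.003, "pexp", 2 / 0.01)
  expect_gt(ks$p.value, 0.01)
})

test_that("three-species concordance follows (2/3) exp(-T)", {
  # one lineage per species; internal branch x = theta_nuc -> T = 2
  st <- focal_tree_default()
  set.seed(7)
  n <- 4000
  disc <- replicate(n, {
    gt <- simulate_gene_genealogy(st, nuclear_profile(),
                                  c(sp1 = 1, sp2 = 1, sp3 = 1))
    # discordant iff sp1,sp2 do not form a cherry
    p12 <- gt$parent[1] != gt$parent[2]
    p12
  })
  expected <- 2 / 3 * exp(-2)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(disc) - expected), 3 * se)
})

test_that("individual labels are exchangeable within species", {
  st <- focal_tree_default()
  set.seed(12)
  a <- replicate(1500, {
    gt <- simulate_gene_genealogy(st, nuclear_profile(),
                                  c(sp1 = 3, sp2 = 2))
    anc <- gt$ages[gt$parent[1]]    # coalescence age above individual 1
    anc
  })
  b <- replicate(1500, {
    gt <- simulate_gene_genealogy(st, nuclear_profile(),
                                  c(sp1 = 3, sp2 = 2))
    gt$ages[gt$parent[3]]           # same statistic for individual 3
  })
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})

test_that("mean excess of the 5+5 sample sits in the theory bracket", {
  # mean(tMRCA - tau1) must lie within [theta_locus/2, theta_locus]
  st <- focal_tree_default(1)     # tau1 = 0.001, theta_eff(mito) = 0.0025
  set.seed(5)
  tm <- replicate(1200, gene_tmrca(
    simulate_gene_genealogy(st, mito_profile(0.01), focal_samples),
    c("sp1", "sp2")))
  excess <- mean(tm) - 0.001
  expect_gt(excess, 0.0025 / 2)
  expect_lt(excess, 0.0025)
})
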