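test_that("delta is the percent excess over the true split", {
  expect_equal(delta_statistic(2.7, 1), 170)
  expect_equal(delta_statistic(2.0, 0.5), 300)
  expect_equal(delta_statistic(1, 1), 0)
  expect_equal(delta_statistic(c(1.2, 0.8), 1), c(20, -20))
  expect_error(delta_statistic(1, 0))
})

test_that("whisker summary follows the IQ +/- 1.5 IQR convention", {
  w <- whisker_summary(c(0, 10, 20, 30, 1000))
  expect_equal(w$q1, 10)
  expect_equal(w$q3, 30)
  expect_equal(w$whisker_high, 30)   # fence at 60 excludes 1000
  expect_equal(w$whisker_low, 0)
  expect_equal(w$mean, 212)
  # constant input: degenerate whiskers at the value
  wc <- whisker_summary(rep(7, 6))
  expect_equal(c(wc$whisker_low, wc$whisker_high, wc$mean), c(7, 7, 7))
  # outliers beyond the fence never move the whiskers, always the mean
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  w1 <- whisker_summary(base)
  w2 <- whisker_summary(c(base, 500))
  expect_equal(w2$whisker_high, w1$whisker_high)
  expect_gt(w2$mean, w1$mean)
  expect_error(whisker_summary(1:3))
})

test_that("replicate seeds are deterministic and locus-independent", {
  st <- focal_tree_default()
  s1 <- simulate_replicate(st, nuc_strategy(2), 3, seed = 99)
  s2 <- simulate_replicate(st, nuc_strategy(2), 3, seed = 99)
  expect_identical(s1$gene_trees[[1]]$ages, s2$gene_trees[[1]]$ages)
  expect_identical(s1$alignments[[2]]$mat, s2$alignments[[2]]$mat)
  s3 <- simulate_replicate(st, nuc_strategy(2), 3, seed = 100)
  expect_false(identical(s1$gene_trees[[1]]$ages, s3$gene_trees[[1]]$ages))
})

test_that("discordance grids are reproducible and theta-sensitive", {
  cond <- study_condition(0.025, 0.01, 1, list(mito_profile(0.01)),
                          n_per_species = 5L, n_replicates = 6L)
  g1 <- run_discordance_grid(list(cond), seed = 7)
  g2 <- run_discordance_grid(list(cond), seed = 7)
  expect_identical(g1$mean_delta, g2$mean_delta)
  # vanishing theta removes the coalescent excess entirely
  tiny <- study_condition(1e-9, 0.01, 1, list(mito_profile(0.01)),
                          n_per_species = 5L, n_replicates = 6L)
  # residual delta is pure estimation noise (a few percent), far below
  # the coalescent excess at theta_mit = 0.025
  g0 <- run_discordance_grid(list(tiny), seed = 7)
  expect_lt(abs(g0$mean_delta), 20)
  expect_gt(g1$mean_delta, 80)
})

test_that("mean delta declines with split depth and rises with nuclear loci", {
  strategies <- list("1mit" = list(mito_profile(0.01)),
                     "5nuc" = nuc_strategy(5))
  grid <- list()
  for (t1 in c(0.5, 1, 3, 10)) for (s in names(strategies))
    grid[[paste(t1, s)]] <- study_condition(
      0.025, 0.01, t1, strategies[[s]], 5L, 12L,
      id = paste(t1, s))
  res <- run_discordance_grid(grid, seed = 31)
  for (s in names(strategies)) {
    sub <- res[grep(s, res$condition), ]
    sub <- sub[order(sub$tau1_myr), ]
    expect_true(all(diff(sub$mean_delta) < 0),
                info = paste("monotone decline for", s))
  }
  # nuclear-only strategies coalesce deeper than the mitochondrial locus
  for (t1 in c(0.5, 1)) {
    d_mit <- res$mean_delta[res$condition == paste(t1, "1mit")]
    d_nuc <- res$mean_delta[res$condition == paste(t1, "5nuc")]
    expect_gt(d_nuc, d_mit)
  }
})

test_that("the MB sampler improves on gene-tree dating at shallow splits", {
  cond <- study_condition(0.025, 0.01, 3, nuc_strategy(5),
                          n_per_species = 5L, n_replicates = 4L)
  mb <- run_mb_grid(list(cond), seed = 11,
                    mcmc = mcmc_settings(3000, 800, 5))
  gt <- run_discordance_grid(list(cond), seed = 11)
  # gene-tree delta is a large positive bias; MB error is centered
  expect_gt(gt$mean_delta, 40)
  expect_lt(abs(mb$mean_percent_error), 40)
  expect_lt(mb$mean_percent_error, gt$mean_delta)
})

test_that("whisker width shrinks as nuclear loci are added", {
  # at test-scale replication only the single-locus vs multilocus
  # contrast is resolvable; the 5-vs-10 gap needs the full 50-replicate
  # design (see the methods vignette)
  mk <- function(k) study_condition(0.025, 0.01, 3, nuc_strategy(k),
                                    n_per_species = 5L, n_replicates = 10L,
                                    id = paste0(k, "loc"))
  res <- run_mb_grid(list(mk(1), mk(5), mk(10)), seed = 17,
                     mcmc = mcmc_settings(2500, 700, 5))
  width <- res$whisker_high - res$whisker_low
  expect_gt(width[1], width[2])
  expect_gt(width[1], width[3])
})
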