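test_that("pairwise ML distance recovers the JC closed form at kappa = 1", {
  prof <- marker_profile("nuclear", kappa = 1, gamma_shape = 1,
                         n_categories = 1L, length = 1000L)
  mat <- rbind(rep(1L, 1000), c(rep(2L, 100), rep(1L, 900)))
  rownames(mat) <- c("a", "b")
  aln <- structure(list(mat = mat, labels = c("a", "b"), profile = prof),
                   class = "locus_alignment")
  D <- ml_pairwise_distances(aln)
  expect_equal(D["a", "b"], -3 / 4 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-5)
  # cross-check against the independent K80 distance implementation
  prof2 <- marker_profile("nuclear", kappa = 10, gamma_shape = 1,
                          n_categories = 1L, length = 2000L)
  gt <- two_tip_gene_tree(0.05, profile = prof2)
  a2 <- evolve_alignment(gt, rng_seed = 4)
  dna <- ape::as.DNAbin(matrix(coaldelta:::NUC[a2$mat], 2,
                               dimnames = list(a2$labels, NULL)))
  d_ape <- as.matrix(ape::dist.dna(dna, model = "K80"))[1, 2]
  d_pkg <- ml_pairwise_distances(a2)[1, 2]
  # same data, per-pair kappa free in ape vs fixed truth here
  expect_equal(d_pkg, d_ape, tolerance = 0.02)
})

test_that("saturated pairs are capped with a warning", {
  prof <- marker_profile("nuclear", kappa = 1, gamma_shape = 1,
                         n_categories = 1L, length = 1000L)
  # 90% differing sites: beyond the JC saturation bound of 0.749
  mat <- rbind(rep(1L, 1000),
               c(rep(2L, 300), rep(3L, 300), rep(4L, 300), rep(1L, 100)))
  rownames(mat) <- c("a", "b")
  aln <- structure(list(mat = mat, labels = c("a", "b"), profile = prof),
                   class = "locus_alignment")
  expect_warning(D <- ml_pairwise_distances(aln, d_max = 4), "saturated")
  expect_equal(D["a", "b"], 4)
})

test_that("NJ on long sequences recovers topology and branch lengths", {
  # near-exact distances: statistical consistency check at L = 500000
  st <- focal_tree_default(3)
  prof <- nuclear_profile(); prof$length <- 500000L
  gt <- simulate_gene_genealogy(st, prof,
                                c(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 1),
                                rng_seed = 8)
  aln <- evolve_alignment(gt, rng_seed = 9)
  est <- estimate_gene_tree(aln)
  true_phy <- as_phylo(gt)
  expect_equal(rf_distance(est$phylo, true_phy), 0)
  d_true <- ape::cophenetic.phylo(true_phy)
  d_est <- ape::cophenetic.phylo(est$phylo)[rownames(d_true), colnames(d_true)]
  off <- upper.tri(d_true)
  expect_lt(max(abs(d_est[off] - d_true[off]) / d_true[off]), 0.02)
})

test_that("zero-divergence alignments fall back to a flagged star tree", {
  prof <- nuclear_profile()
  mat <- matrix(1L, 4, 50,
                dimnames = list(paste0("sp", 1:4, "_1"), NULL))
  aln <- structure(list(mat = mat, labels = rownames(mat), profile = prof),
                   class = "locus_alignment")
  est <- estimate_gene_tree(aln)
  expect_true("zero_divergence" %in% est$flags)
  expect_true(all(est$phylo$edge.length == 0))
  clk <- langley_fitch_clock(est)
  expect_true("zero_divergence" %in% clk$flags)
  expect_error(kscore_rescale(clk, est), "all-zero")
})

test_that("Langley-Fitch clock solves the two-branch case analytically", {
  phy <- ape::read.tree(text = "(a:0.1,b:0.2);")
  clk <- langley_fitch_clock(phy, site_count = 1000)
  expect_equal(clk$ages[3], 0.15, tolerance = 1e-6)
  expect_error(langley_fitch_clock(ape::rtree(4, rooted = FALSE),
                                   site_count = 100), "rooted")
})

test_that("Langley-Fitch matches a brute-force optimizer on 3 taxa", {
  phy <- ape::read.tree(text = "((a:0.12,b:0.07):0.05,c:0.31);")
  L <- 500
  clk <- langley_fitch_clock(phy, site_count = L)
  # independent brute force over (root age, interior fraction); the two
  # root-child branches share one Poisson observation on the summed
  # duration (the root splits an unrooted branch at an arbitrary point)
  counts <- phy$edge.length * L
  nll <- function(par) {
    A <- exp(par[1]); f <- stats::plogis(par[2])
    t_ab <- f * A
    d <- c(t_ab, t_ab, A - t_ab + A)   # a, b, (ab stem + c as one branch)
    n <- c(counts[2], counts[3], counts[1] + counts[4])
    -sum(n * log(d) - d * L)
  }
  opt <- stats::optim(c(log(0.1), 0), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  A_bf <- exp(opt$par[1])
  f_bf <- stats::plogis(opt$par[2])
  expect_equal(clk$ages[4], A_bf, tolerance = 1e-4)
  expect_equal(clk$ages[5], f_bf * A_bf, tolerance = 1e-4)
})

test_that("clock refit of an ultrametric tree keeps its ages", {
  st <- focal_tree_default()
  gt <- simulate_gene_genealogy(st, mito_profile(0.01), focal_samples,
                                rng_seed = 3)
  phy <- as_phylo(gt)
  clk <- langley_fitch_clock(phy, site_count = 1000)
  ages_true <- attr(phy, "ages")
  expect_equal(max(clk$ages), max(ages_true), tolerance = 1e-5)
  expect_true(ape::is.ultrametric(clk$phylo, tol = 1e-8))
})

test_that("K-score rescaling is the least-squares-through-origin scalar", {
  st <- focal_tree_default()
  dat <- sim_locus(st, mito_profile(0.01), seed = 17)
  est <- estimate_gene_tree(dat$aln)
  clk <- langley_fitch_clock(est)
  # identity and exact-proportionality cases
  self <- kscore_rescale(clk, clk)
  expect_equal(self$scale_factor, 1)
  half <- clk; half$phylo$edge.length <- 2 * clk$phylo$edge.length
  expect_equal(kscore_rescale(half, clk)$scale_factor, 0.5)
  # brute-force 1-D minimization over the merged-root branch sets
  res <- kscore_rescale(clk, est)
  e <- clk$phylo$edge
  rootk <- e[, 1] == length(clk$phylo$tip.label) + 1L
  bc <- c(clk$phylo$edge.length[!rootk], sum(clk$phylo$edge.length[rootk]))
  br <- c(est$phylo$edge.length[!rootk], sum(est$phylo$edge.length[rootk]))
  obj <- function(k) sum((br - k * bc)^2)
  k_bf <- stats::optimize(obj, c(0, 10), tol = 1e-12)$minimum
  expect_equal(res$scale_factor, k_bf, tolerance = 1e-6)
})

test_that("tMRCA extraction converts ages to Myr with the right rate", {
  st <- build_focal_tree(0.025, 0.01, 5)   # tau1 = 0.005 nuclear
  st0 <- build_focal_tree(2.5e-10, 0.01, 5)
  gt <- simulate_gene_genealogy(st0, nuclear_profile(), focal_samples,
                                rng_seed = 2)
  expect_equal(tmrca_sp1_sp2(gt), 5, tolerance = 1e-3)
  # mito gene tree: ages x10 on the locus scale, divided by u_mit
  gtm <- simulate_gene_genealogy(st0, mito_profile(0.01), focal_samples,
                                 rng_seed = 2)
  expect_equal(tmrca_sp1_sp2(gtm), 5, tolerance = 1e-3)
  # explicit clock tree: MRCA age 0.027 at u = 0.01 -> 2.7 Myr
  fake <- list(phylo = NULL, ages = NULL, mean_rate = 0.01)
  dat <- sim_locus(st, mito_profile(0.01), seed = 30)
  est <- estimate_gene_tree(dat$aln)
  clk <- langley_fitch_clock(est)
  tips <- grep("^sp[12]_", clk$phylo$tip.label)
  node <- ape::getMRCA(clk$phylo, tips)
  clk$ages[node] <- 0.027
  expect_equal(tmrca_sp1_sp2(clk, rate = 0.01), 2.7)
})

test_that("tau_prior_mean is the mean of per-tree minimum pair divergences", {
  st <- focal_tree_default()
  dat1 <- sim_locus(st, nuclear_profile(), seed = 41)
  dat2 <- sim_locus(st, nuclear_profile(), seed = 42)
  t1 <- langley_fitch_clock(estimate_gene_tree(dat1$aln))
  t2 <- langley_fitch_clock(estimate_gene_tree(dat2$aln))
  m <- tau_prior_mean(list(t1, t2), rate_ratio = 1)
  # brute force: half the min patristic distance, per tree, averaged
  mins <- vapply(list(t1, t2), function(t) {
    d <- ape::cophenetic.phylo(t$phylo)
    i <- grep("^sp1_", rownames(d)); j <- grep("^sp2_", colnames(d))
    min(d[i, j]) / 2
  }, numeric(1))
  expect_equal(m, mean(mins))
  expect_lt(mins[1], {
    d <- ape::cophenetic.phylo(t1$phylo)
    mean(d[grep("^sp1_", rownames(d)), grep("^sp2_", colnames(d))]) / 2
  })
  # mitochondrial rescaling divides by the rate ratio
  expect_equal(tau_prior_mean(list(t1, t2), rate_ratio = 10), m / 10)
  expect_error(tau_prior_mean(list()))
})

test_that("estimated clock tMRCAs track the coalescent signal end to end", {
  st <- focal_tree_default(1)
  est_t <- true_t <- numeric(30)
  for (i in 1:30) {
    dat <- sim_locus(st, mito_profile(0.01), seed = 500 + i)
    est <- estimate_gene_tree(dat$aln)
    clk <- kscore_rescale(langley_fitch_clock(est), est)
    est_t[i] <- tmrca_sp1_sp2(clk)
    true_t[i] <- tmrca_sp1_sp2(dat$gt)
  }
  expect_lt(abs(mean(est_t) - mean(true_t)) / mean(true_t), 0.10)
})
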