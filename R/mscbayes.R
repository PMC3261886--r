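#' Gamma prior for theta from a mean and a 95% interval
#'
#' Finds the Gamma(shape, scale) distribution with the requested mean
#' (shape * scale) whose central 95% quantiles match the requested
#' interval to within 10% relative error, by a 1-D search over the shape
#' parameter.  The defaults reproduce typical mammalian mitochondrial
#' diversity: mean theta 0.025 with a 0.003--0.07 interval, which is
#' matched by Gamma(shape = 2, scale = 0.0125).
#'
#' @param mean Prior mean, substitutions/site.
#' @param ci95 Length-2 vector: central 95% interval.
#' @param tol Relative tolerance on the quantile match.
#' @return List with `shape`, `scale`, and the achieved `ci95`.
#' @export
derive_theta_prior <- function(mean = 0.025, ci95 = c(0.003, 0.07),
                               tol = 0.10) {
  stopifnot(mean > 0, length(ci95) == 2, ci95[1] > 0,
            ci95[1] < mean, mean < ci95[2])
  objective <- function(log_shape) {
    shape <- exp(log_shape)
    q <- stats::qgamma(c(0.025, 0.975), shape = shape,
                       scale = mean / shape)
    max(abs(q - ci95) / ci95)
  }
  # shapes above ~100 would make the prior implausibly informative for a
  # population parameter; intervals needing more are rejected as infeasible
  opt <- stats::optimize(objective, c(log(0.05), log(100)))
  shape <- exp(opt$minimum)
  q <- stats::qgamma(c(0.025, 0.975), shape = shape, scale = mean / shape)
  if (opt$objective > tol)
    stop(sprintf(
      "no Gamma with mean %g matches CI [%g, %g] within %g%%; best: shape %.3g with CI [%.3g, %.3g]",
      mean, ci95[1], ci95[2], 100 * tol, shape, q[1], q[2]))
  list(shape = shape, scale = mean / shape, ci95 = q)
}

#' Prior specification for the multispecies-coalescent sampler
#'
#' @param theta_mean,theta_ci Mean and central 95% interval of the Gamma
#'   prior on every population theta (see [derive_theta_prior()]).
#' @param tau_mean Mean of the exponential prior on the sp1--sp2 split
#'   (and of the ladder increments for the deeper nodes), in
#'   substitutions/site.  Typically set from data via [tau_prior_mean()].
#' @param root_mean Mean of the exponential root-age prior used when the
#'   topology is sampled (non-root ages are then jointly uniform over
#'   the order polytope below the root).
#' @param rate_dir_alpha Concentration of the mean-one Dirichlet prior
#'   on locus rate multipliers when rates are estimated; moderate values
#'   pull the rates toward equality, which is what makes internal rate
#'   estimation with a fast mitochondrial locus biased.
#' @param hered_shape Shape of the Gamma prior on heredity multipliers
#'   when they are estimated (mean 1 for nuclear loci, 0.25 for mtDNA).
#' @export
msc_priors <- function(theta_mean = 0.025, theta_ci = c(0.003, 0.07),
                       tau_mean = 0.01, root_mean = 3 * tau_mean,
                       rate_dir_alpha = 2, hered_shape = 4) {
  th <- derive_theta_prior(theta_mean, theta_ci)
  structure(list(theta_shape = th$shape, theta_scale = th$scale,
                 tau_mean = tau_mean, root_mean = root_mean,
                 rate_dir_alpha = rate_dir_alpha,
                 hered_shape = hered_shape),
            class = "msc_priors")
}

#' MCMC run settings
#'
#' `profile = "paper"` uses 1,000,000 generations with 150,000 burn-in
#' sampled every 100 (one "generation" here is a full sweep over all
#' move types).  `profile = "ci"` is the scaled-down profile used by the
#' test-suite-sized experiments: 12,000 sweeps, 3,000 burn-in, thin 5.
#'
#' @param n_gen Total sweeps.
#' @param burnin Burn-in sweeps (also the adaptation window).
#' @param sample_every Thinning interval.
#' @param adapt Auto-tune proposal step sizes during burn-in toward
#'   acceptance rates of 0.2--0.5.
#' @param profile Shortcut: `"paper"` or `"ci"` presets.
#' @export
mcmc_settings <- function(n_gen = NULL, burnin = NULL, sample_every = NULL,
                          adapt = TRUE, profile = c("ci", "paper")) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   paper = list(n_gen = 1000000L, burnin = 150000L,
                                sample_every = 100L),
                   ci = list(n_gen = 12000L, burnin = 3000L,
                             sample_every = 5L))
  list(n_gen = as.integer(n_gen %||% preset$n_gen),
       burnin = as.integer(burnin %||% preset$burnin),
       sample_every = as.integer(sample_every %||% preset$sample_every),
       adapt = adapt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- bridges to the C++ sampler -----------------------------------------

sp_to_clist <- function(st) {
  if (inherits(st, "species_tree_single"))
    return(list(parent = -1L, tau = 0, theta = as.numeric(st$theta),
                labels = st$labels))
  parent <- st_parents(st$phylo) - 1L
  parent[parent == -1L] <- -1L
  root <- length(st$labels) + 1L
  parent[root] <- -1L
  list(parent = as.integer(parent), tau = as.numeric(st$ages),
       theta = as.numeric(st$theta), labels = st$labels)
}

compress_patterns <- function(mat) {
  key <- apply(mat, 2, paste, collapse = "\r")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = matrix(as.integer(mat[, first] - 1L), nrow(mat)),
       wt = as.numeric(tab))
}

locus_to_clist <- function(gt, aln, st, rate, hered, hered_prior_mean,
                           kappa = 1) {
  parent <- as.integer(gt$parent) - 1L
  parent[gt$parent == 0] <- -1L
  tipsp <- match(gt$tip_species, st$labels) - 1L
  out <- list(parent = parent, age = as.numeric(gt$ages),
              tipsp = as.integer(tipsp),
              rate = rate, hered = hered,
              hered_prior_mean = hered_prior_mean,
              kappa = kappa,
              patterns = NULL, wt = NULL)
  if (!is.null(aln)) {
    m <- aln$mat[gt$tip_labels, , drop = FALSE]
    cp <- compress_patterns(m)
    out$patterns <- cp$patterns
    out$wt <- cp$wt
  }
  out
}

# plain Kingman coalescent for a single population (initialization only)
sim_single_pop_tree <- function(n, label, theta, profile) {
  nnode <- 2L * n - 1L
  parent <- integer(nnode); ages <- numeric(nnode)
  lin <- seq_len(n); t <- 0; nxt <- n + 1L
  while (length(lin) > 1) {
    k <- length(lin)
    t <- t + stats::rexp(1, k * (k - 1) / theta)
    pair <- sample.int(k, 2)
    parent[lin[pair]] <- nxt; ages[nxt] <- t
    lin <- c(lin[-pair], nxt); nxt <- nxt + 1L
  }
  structure(list(parent = parent, ages = ages,
                 tip_species = rep(label, n),
                 tip_labels = paste0(label, "_", seq_len(n)),
                 ntip = n, profile = profile),
            class = "gene_tree")
}

# single-population pseudo species tree (one species, one theta)
single_pop_tree <- function(label, theta0) {
  structure(list(phylo = NULL, ages = 0, theta = theta0, labels = label),
            class = c("species_tree_single", "species_tree"))
}

is_single_pop <- function(topology) {
  is.character(topology) && length(topology) == 1 &&
    !grepl("[(,]", topology)
}

# ladder initialization of internal-node ages for a species-tree topology
init_species_tree <- function(topology, tau_mean, theta0, labels = NULL) {
  if (is_single_pop(topology))
    return(single_pop_tree(sub(";$", "", topology), theta0))
  if (inherits(topology, "species_tree")) {
    phy <- topology$phylo
  } else if (inherits(topology, "phylo")) {
    phy <- topology
  } else phy <- ape::read.tree(text = topology)
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  parent <- st_parents(phy)
  # level = 1 + max levels below
  level <- integer(nn)
  for (v in rev(preorder_nodes(parent, n + 1L))) {
    p <- parent[v]
    level[p] <- max(level[p], level[v] + 1L)
  }
  level[seq_len(n)] <- 0L
  ages <- level * tau_mean
  species_tree(phy, ages, theta0)
}

#' Sample the posterior of species-tree times and population sizes
#'
#' Runs the package's Bayesian MCMC sampler for the multispecies
#' coalescent on a fixed species-tree topology: the target is the joint
#' posterior of divergence times tau, population parameters theta,
#' per-locus gene trees, and (optionally) per-locus substitution-rate
#' and heredity multipliers, given per-locus sequence alignments.  The
#' sequence likelihood is Jukes-Cantor (the deliberately simple model of
#' the classic MCMCcoal implementation, which is what produces the
#' documented mitochondrial model-mismatch bias); gene trees are
#' integrated over by node-age and constrained subtree-regrafting moves;
#' species times use rubber-band proposals that rescale the enclosed
#' gene-tree ages.
#'
#' Rate handling (`rate_mode`): `"fixed_true"` fixes each locus rate at
#' its marker-profile multiplier (mtDNA 10, nuclear ~1), so tau is on
#' the nuclear scale; `"estimated_internal"` samples rates under a
#' mean-one Dirichlet prior; `"fixed_external"` fixes them at
#' [estimate_rate_ratios_external()] values.  In the latter two modes
#' tau is on the locus-mean-rate scale and the returned `tau_scale`
#' (the nominal mean of the class rates) converts it back to nuclear.
#'
#' @param alignments List of `locus_alignment` (one per locus).
#' @param topology Species-tree topology: a `species_tree`, `phylo`, or
#'   Newick string.  Node ages/theta of a supplied `species_tree` are
#'   ignored (they are sampled).
#' @param priors An [msc_priors()] object.
#' @param loci List of [marker_profile()]s, one per locus.
#' @param mcmc [mcmc_settings()].
#' @param rng_seed Integer seed.
#' @param rate_mode,heredity_mode See Details.
#' @param external_rates Optional fixed rate multipliers
#'   (`rate_mode = "fixed_external"`).
#' @param likelihood_on Set `FALSE` to sample from the prior (used by
#'   the sampler-correctness tests).
#' @param init_state Optional state list from a previous run (resumes
#'   from it; used by the joint-distribution tests).
#' @param topology_moves Enable species-tree NNI moves (used by
#'   [sample_topology_posterior()]; switches the divergence-time prior
#'   to the root-exponential / order-polytope form).
#' @param seq_model Sequence likelihood: `"jc"` (Jukes-Cantor, the
#'   MCMCcoal-style default) or `"hky"` (K80 with each locus's kappa).
#' @return An `msc_trace`: matrices `tau`, `theta`, `rate`, `hered`,
#'   vectors `loglik`/`logmsc`, vector `tau1` (the sp1--sp2 node, on the
#'   sampler scale), scalar `tau_scale`, acceptance counts, and `state`.
#' @export
sample_msc_posterior <- function(alignments, topology, priors, loci,
                                 mcmc = mcmc_settings(), rng_seed = 1L,
                                 rate_mode = c("fixed_true",
                                               "estimated_internal",
                                               "fixed_external"),
                                 heredity_mode = c("fixed_true", "estimated"),
                                 external_rates = NULL,
                                 likelihood_on = TRUE,
                                 init_state = NULL,
                                 topology_moves = FALSE,
                                 seq_model = c("jc", "hky")) {
  rate_mode <- match.arg(rate_mode)
  seq_model <- match.arg(seq_model)
  heredity_mode <- match.arg(heredity_mode)
  nloc <- length(loci)
  stopifnot(nloc >= 1)
  if (!is.null(alignments) && length(alignments) != nloc)
    stop("one alignment per locus required")
  set.seed(as.integer(rng_seed %% .Machine$integer.max))

  st0 <- init_species_tree(topology, priors$tau_mean,
                           priors$theta_shape * priors$theta_scale)
  nominal <- vapply(loci, function(p)
    ifelse(p$marker_class == "mitochondrial", 10, 1), numeric(1))
  rates <- switch(rate_mode,
    fixed_true = vapply(loci, `[[`, numeric(1), "rate_multiplier"),
    estimated_internal = rep(1, nloc),
    fixed_external = {
      if (is.null(external_rates)) stop("external_rates required")
      external_rates / mean(external_rates)
    })
  tau_scale <- if (rate_mode == "fixed_true") 1 else mean(nominal)
  hered_means <- ifelse(nominal > 1, 0.25, 1)
  hereds <- vapply(loci, `[[`, numeric(1), "heredity_multiplier")
  if (heredity_mode == "estimated") hereds <- hered_means

  clist <- vector("list", nloc)
  for (l in seq_len(nloc)) {
    if (!is.null(init_state)) {
      stl <- init_state$loci[[l]]
      gt <- list(parent = ifelse(stl$parent < 0, 0L, stl$parent + 1L),
                 ages = stl$age,
                 tip_species = sub("_.*$", "", alignments[[l]]$labels),
                 tip_labels = alignments[[l]]$labels,
                 ntip = length(alignments[[l]]$labels),
                 profile = loci[[l]])
      class(gt) <- "gene_tree"
      rates[l] <- stl$rate
      hereds[l] <- stl$hered
    } else {
      labs <- if (!is.null(alignments)) alignments[[l]]$labels else
        unlist(lapply(st0$labels, function(s) paste0(s, "_1")))
      spp <- sub("_.*$", "", labs)
      samples <- table(factor(spp, levels = st0$labels))
      sim_prof <- loci[[l]]
      sim_prof$heredity_multiplier <- hereds[l]
      if (inherits(st0, "species_tree_single")) {
        gt <- sim_single_pop_tree(as.integer(samples[1]), st0$labels,
                                  st0$theta * hereds[l], sim_prof)
      } else {
        gt <- simulate_gene_genealogy(st0, sim_prof,
                                      stats::setNames(as.integer(samples),
                                                      names(samples)))
      }
      # align tip order with the alignment labels
      if (!is.null(alignments)) {
        perm <- match(alignments[[l]]$labels, gt$tip_labels)
        stopifnot(!anyNA(perm))
        inv <- integer(gt$ntip)
        nn <- length(gt$parent)
        map <- c(perm, (gt$ntip + 1L):nn)
        map_inv <- order(map)
        gt$parent <- ifelse(gt$parent[map] == 0L, 0L,
                            map_inv[gt$parent[map]])
        gt$ages <- gt$ages[map]
        gt$tip_species <- gt$tip_species[map[seq_len(gt$ntip)]]
        gt$tip_labels <- alignments[[l]]$labels
      }
    }
    if (!is.null(init_state) && !is.null(alignments)) {
      aln <- alignments[[l]]
    } else aln <- if (is.null(alignments)) NULL else alignments[[l]]
    kap <- if (seq_model == "hky") loci[[l]]$kappa else 1
    clist[[l]] <- locus_to_clist(gt, aln, st0, rates[l], hereds[l],
                                 hered_means[l], kappa = kap)
  }

  sp_list <- sp_to_clist(st0)
  if (!is.null(init_state)) {
    sp_list$tau <- init_state$tau
    sp_list$theta <- init_state$theta
    sp_list$parent <- init_state$sp_parent
  }
  opts <- list(
    priors = list(theta_shape = priors$theta_shape,
                  theta_scale = priors$theta_scale,
                  tau_mean = priors$tau_mean,
                  root_mean = priors$root_mean,
                  tau_mode = if (topology_moves) 1L else 0L,
                  rate_dir_alpha = priors$rate_dir_alpha,
                  hered_shape = priors$hered_shape),
    likelihood_on = isTRUE(likelihood_on) && !is.null(alignments),
    estimate_rates = rate_mode == "estimated_internal",
    estimate_heredity = heredity_mode == "estimated",
    topology_moves = topology_moves,
    n_gen = mcmc$n_gen, burnin = mcmc$burnin,
    sample_every = mcmc$sample_every, adapt = mcmc$adapt)
  if (!is.null(mcmc$moves_on)) opts$moves_on <- mcmc$moves_on

  raw <- msc_mcmc_cpp(sp_list, clist, opts)
  tau1_col <- grep("^tau_\\(sp1,sp2\\)$", colnames(raw$tau))
  out <- list(tau = raw$tau, theta = raw$theta, rate = raw$rate,
              hered = raw$hered, loglik = raw$loglik, logmsc = raw$logmsc,
              topology = if (topology_moves) as.character(raw$topology) else NULL,
              tau1 = if (length(tau1_col)) raw$tau[, tau1_col[1]] else NULL,
              tau_scale = tau_scale,
              accept = raw$accept, propose = raw$propose,
              state = raw$state, settings = mcmc,
              rate_mode = rate_mode, heredity_mode = heredity_mode,
              seq_model = seq_model)
  class(out) <- "msc_trace"
  out
}

#' @export
print.msc_trace <- function(x, ...) {
  cat(sprintf("<msc_trace> %d samples; tau columns: %s\n",
              nrow(x$tau), paste(colnames(x$tau), collapse = ", ")))
  if (!is.null(x$tau1))
    cat(sprintf("  tau1 posterior mean %.5g (sampler scale; tau_scale %.3g)\n",
                mean(x$tau1), x$tau_scale))
  invisible(x)
}

#' Externally calculated locus rate multipliers
#'
#' Computes per-locus substitution-rate multipliers from independently
#' estimated (non-clock) gene trees as each tree's total branch length
#' divided by the across-loci mean, i.e. multipliers normalized to mean
#' one.  These are intended to be passed to [sample_msc_posterior()]
#' with `rate_mode = "fixed_external"`, mirroring the practice of fixing
#' relative rates from ML gene trees instead of estimating them inside
#' the coalescent sampler.
#'
#' @param gene_trees List of `estimated_gene_tree` (one per locus).
#' @return Numeric vector of multipliers, mean 1.
#' @export
estimate_rate_ratios_external <- function(gene_trees) {
  if (length(gene_trees) < 2) stop("need at least two loci")
  tl <- vapply(gene_trees, function(t) sum(t$phylo$edge.length), numeric(1))
  if (any(tl == 0)) stop("zero-length tree: rates undefined")
  tl / mean(tl)
}

#' Percent error of the posterior-mean divergence time
#'
#' `100 * (posterior mean of tau1 - truth) / truth`, with the posterior
#' mean first converted to the nuclear scale via the trace's
#' `tau_scale`.
#'
#' @param trace An `msc_trace`.
#' @param true_tau1 True sp1--sp2 split, substitutions/site (nuclear).
#' @export
summarize_percent_error <- function(trace, true_tau1) {
  stopifnot(inherits(trace, "msc_trace"), true_tau1 > 0)
  if (is.null(trace$tau1) || !length(trace$tau1)) stop("empty trace")
  est <- mean(trace$tau1) / trace$tau_scale
  100 * (est - true_tau1) / true_tau1
}
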