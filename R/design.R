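#' Marker profiles: the per-locus evolutionary contract
#'
#' A marker profile records everything a locus needs to be simulated and
#' analysed: its class (mitochondrial or nuclear), its substitution-rate
#' multiplier relative to the nuclear mean rate, its heredity multiplier
#' (the ploidy/inheritance scaling of the population parameter theta), the
#' HKY85 transition/transversion ratio kappa, the discrete-Gamma shape used
#' for among-site rate variation, and the locus length in base pairs.
#'
#' Defaults follow typical mammalian values: mitochondrial loci evolve ten
#' times faster than the nuclear mean (`rate_multiplier = 10`) and have a
#' quarter of the autosomal effective size (`heredity_multiplier = 0.25`),
#' so the effective mitochondrial theta is 2.5 times the nuclear theta
#' (e.g. 0.025 vs 0.01 substitutions/site).  kappa is 10 for mtDNA and 2
#' for nuclear loci; both use a Gamma shape of 1 with 4 rate categories
#' and 1000-bp loci.
#'
#' @param marker_class `"mitochondrial"` or `"nuclear"`.
#' @param rate_multiplier Locus substitution rate divided by the nuclear
#'   mean rate (10 for mtDNA; around 1 for nuclear loci, possibly drawn
#'   from a 0.7--1.4 band to emulate among-loci rate variation).
#' @param heredity_multiplier Locus theta divided by the nuclear theta at
#'   equal rate (0.25 for mtDNA, 1 for autosomes).
#' @param kappa HKY85 transition/transversion rate ratio (alpha/beta).
#' @param gamma_shape Shape of the Gamma distribution of site rates.
#' @param n_categories Number of discrete Gamma categories.
#' @param length Locus length in base pairs.
#' @param per_lineage_rate Absolute per-lineage substitution rate of the
#'   locus, in substitutions/site/Myr (used to convert ages to Myr).
#' @return An object of class `marker_profile`.
#' @export
marker_profile <- function(marker_class = c("nuclear", "mitochondrial"),
                           rate_multiplier = 1,
                           heredity_multiplier = 1,
                           kappa = 2,
                           gamma_shape = 1,
                           n_categories = 4L,
                           length = 1000L,
                           per_lineage_rate = 0.001) {
  marker_class <- match.arg(marker_class)
  stopifnot(rate_multiplier > 0, heredity_multiplier > 0, kappa > 0,
            gamma_shape > 0, n_categories >= 1, length >= 1,
            per_lineage_rate > 0)
  structure(
    list(marker_class = marker_class,
         rate_multiplier = rate_multiplier,
         heredity_multiplier = heredity_multiplier,
         kappa = kappa,
         gamma_shape = gamma_shape,
         n_categories = as.integer(n_categories),
         length = as.integer(length),
         per_lineage_rate = per_lineage_rate),
    class = "marker_profile")
}

#' @rdname marker_profile
#' @param u_mit Mitochondrial per-lineage rate in substitutions/site/Myr.
#' @export
mito_profile <- function(u_mit = 0.01, length = 1000L) {
  marker_profile("mitochondrial", rate_multiplier = 10,
                 heredity_multiplier = 0.25, kappa = 10,
                 gamma_shape = 1, length = length,
                 per_lineage_rate = u_mit)
}

#' @rdname marker_profile
#' @param u_nuc Mean nuclear per-lineage rate in substitutions/site/Myr.
#' @export
nuclear_profile <- function(u_nuc = 0.001, rate_multiplier = 1,
                            length = 1000L) {
  marker_profile("nuclear", rate_multiplier = rate_multiplier,
                 heredity_multiplier = 1, kappa = 2,
                 gamma_shape = 1, length = length,
                 per_lineage_rate = u_nuc * rate_multiplier)
}

#' @export
print.marker_profile <- function(x, ...) {
  cat(sprintf(
    "<marker_profile> %s: r=%g h=%g kappa=%g alpha=%g (%d cat) L=%d bp u=%g subs/site/Myr\n",
    x$marker_class, x$rate_multiplier, x$heredity_multiplier, x$kappa,
    x$gamma_shape, x$n_categories, x$length, x$per_lineage_rate))
  invisible(x)
}

#' Species tree with node ages and per-population theta
#'
#' Builds the central container of the package: a rooted binary species
#' tree whose internal-node ages (tau) and per-population mutation-scaled
#' sizes (theta) are expressed in substitutions/site at the nuclear mean
#' rate.  Each node of the tree indexes the population on the branch
#' directly above it; the root node indexes the root stem population,
#' which extends indefinitely into the past.
#'
#' @param topology An `ape::phylo` rooted binary tree, or a Newick string.
#'   Branch lengths, if present, are ignored; ages are taken from `ages`.
#' @param ages Numeric vector of node ages (tips then internal nodes, in
#'   `ape` node order), in substitutions/site.  Tip ages must be 0.
#' @param theta Per-population theta, one value per node (tips then
#'   internal nodes), or a single value recycled to all populations.
#' @return An object of class `species_tree` with elements `phylo`,
#'   `ages`, `theta`, `labels`.
#' @export
species_tree <- function(topology, ages, theta) {
  if (is.character(topology)) topology <- ape::read.tree(text = topology)
  stopifnot(inherits(topology, "phylo"))
  if (!ape::is.rooted(topology) || !ape::is.binary(topology))
    stop("species tree topology must be rooted and binary")
  n <- length(topology$tip.label)
  nn <- n + topology$Nnode
  ages <- as.numeric(ages)
  if (length(ages) != nn) stop("ages must have one entry per node")
  if (length(theta) == 1) theta <- rep(theta, nn)
  theta <- as.numeric(theta)
  if (length(theta) != nn) stop("theta must have one entry per node (or one value)")
  st <- structure(
    list(phylo = topology, ages = ages, theta = theta,
         labels = topology$tip.label),
    class = "species_tree")
  validate_species_tree(st)
  st
}

validate_species_tree <- function(st) {
  n <- length(st$labels)
  if (any(st$ages[seq_len(n)] != 0)) stop("tip ages must be 0")
  if (any(st$ages < 0)) stop("node ages must be non-negative")
  if (any(st$theta <= 0)) stop("all theta must be > 0")
  e <- st$phylo$edge
  if (any(st$ages[e[, 1]] <= st$ages[e[, 2]]))
    stop("every parent age must exceed its child ages")
  invisible(st)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d species: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  nt <- length(x$labels)
  intn <- (nt + 1):(nt + x$phylo$Nnode)
  cat("  node ages (subs/site):",
      paste(sprintf("%g", x$ages[intn]), collapse = ", "), "\n")
  cat("  theta range:", sprintf("%g..%g", min(x$theta), max(x$theta)), "\n")
  invisible(x)
}

# parent node id for each node (0 for the root), ape numbering
st_parents <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  p <- integer(nn)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

# node id of the MRCA of a set of tip labels
st_mrca <- function(st, species) {
  idx <- match(species, st$labels)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(species[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(idx)
  ape::getMRCA(st$phylo, idx)
}

#' Four-taxon asymmetric species tree of the divergence-time experiments
#'
#' Constructs the focal asymmetric tree `(((sp1,sp2),sp3),sp4)` used to
#' study how deep coalescence inflates the apparent sp1--sp2 divergence.
#' The sp1--sp2 split is placed at `tau1_myr` Myr and converted to
#' substitutions/site with the nuclear mean rate (one tenth of the
#' mitochondrial rate `u_mit`).  The two internal branches are fixed at
#' 4 Ne and 8 Ne generations, which on the nuclear scale equal
#' `theta_nuc` and `2 * theta_nuc` substitutions/site; these rooting
#' branches are long enough to make outgroup lineage sorting negligible.
#' Every population receives the same theta (`theta_mit / 2.5`).
#'
#' @param theta_mit Mitochondrial population parameter in
#'   substitutions/site (typical mammalian values: 0.025, 0.01).
#' @param u_mit Mitochondrial per-lineage substitution rate in
#'   substitutions/site/Myr (0.01 or 0.02).
#' @param tau1_myr True sp1--sp2 split time in Myr.
#' @return A [species_tree()].
#' @export
build_focal_tree <- function(theta_mit, u_mit, tau1_myr) {
  stopifnot(theta_mit > 0, u_mit > 0, tau1_myr > 0)
  theta_nuc <- theta_mit / 2.5
  u_nuc <- u_mit / 10
  tau1 <- tau1_myr * u_nuc
  x <- theta_nuc        # 4 Ne generations = (4/4) * theta_nuc subs/site
  y <- 2 * theta_nuc    # 8 Ne generations
  tau2 <- tau1 + x
  tau3 <- tau2 + y
  phy <- ape::read.tree(text = "(((sp1,sp2),sp3),sp4);")
  # ape numbers tips 1..4 in label order of the string; internal: 5 root,
  # then preorder.  Map ages by node depth instead of assuming order.
  ages <- numeric(7)
  ages[st_mrca_ids(phy, c("sp1", "sp2"))] <- tau1
  ages[st_mrca_ids(phy, c("sp1", "sp3"))] <- tau2
  ages[st_mrca_ids(phy, c("sp1", "sp4"))] <- tau3
  species_tree(phy, ages, theta_nuc)
}

st_mrca_ids <- function(phy, species) {
  ape::getMRCA(phy, match(species, phy$tip.label))
}

#' Five-taxon radiation species trees
#'
#' Builds the asymmetric 5-taxon tree `((((sp1,sp2),sp3),sp4),sp5)` with
#' internal branch lengths chosen to represent either a moderate or a
#' fast (extreme) species radiation.  Branch durations are specified in
#' units of Ne generations and converted to substitutions/site through
#' theta (g Ne generations = (g/4) * theta_nuc): the sp1--sp2 split sits
#' at 8 Ne; the two internal branches x and y are 0.5 Ne and 1.6 Ne for
#' the moderate scenario and 0.1 Ne and 0.2 Ne for the fast one (the
#' latter deep in anomalous-gene-tree territory); the branch subtending
#' the first four species is 12 Ne.
#'
#' @param scenario `"moderate"` or `"fast"`.
#' @param theta_nuc Nuclear theta in substitutions/site (all populations).
#' @return A [species_tree()].
#' @export
build_radiation_tree <- function(scenario = c("moderate", "fast"),
                                 theta_nuc = 0.01) {
  scenario <- match.arg(scenario)
  stopifnot(theta_nuc > 0)
  gens <- switch(scenario,
                 moderate = c(x = 0.5, y = 1.6),
                 fast     = c(x = 0.1, y = 0.2))
  per_ne <- theta_nuc / 4           # 1 Ne generation in subs/site
  tau1 <- 8 * per_ne
  tau2 <- tau1 + gens[["x"]] * per_ne
  tau3 <- tau2 + gens[["y"]] * per_ne
  tau4 <- tau3 + 12 * per_ne
  phy <- ape::read.tree(text = "((((sp1,sp2),sp3),sp4),sp5);")
  ages <- numeric(9)
  ages[st_mrca_ids(phy, c("sp1", "sp2"))] <- tau1
  ages[st_mrca_ids(phy, c("sp1", "sp3"))] <- tau2
  ages[st_mrca_ids(phy, c("sp1", "sp4"))] <- tau3
  ages[st_mrca_ids(phy, c("sp1", "sp5"))] <- tau4
  species_tree(phy, ages, theta_nuc)
}

#' Convert between the study's time units
#'
#' All quantities in the package live on one of four scales: absolute time
#' in Myr, branch durations in units of Ne generations, coalescent units,
#' and expected substitutions/site at the locus rate.  Conversions need a
#' locus context (its per-lineage rate, rate multiplier and heredity
#' multiplier) and the nuclear theta:
#' Myr * per_lineage_rate = subs/site; g Ne generations =
#' (g/4) * rate_multiplier * theta_nuc subs/site; coalescent units =
#' 2 * subs / theta_locus with theta_locus = heredity * rate * theta_nuc.
#'
#' @param value Numeric value(s) to convert.
#' @param from,to One of `"myr"`, `"generations_Ne"`, `"coalescent_units"`,
#'   `"subs_per_site"`.
#' @param profile A [marker_profile()] supplying the rate context.
#' @param theta_nuc Nuclear theta in substitutions/site (needed for
#'   generation and coalescent-unit conversions).
#' @return Converted numeric value(s).
#' @export
convert_units <- function(value, from, to, profile = nuclear_profile(),
                          theta_nuc = NULL) {
  units <- c("myr", "generations_Ne", "coalescent_units", "subs_per_site")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)
  needs_theta <- c(from, to) %in% c("generations_Ne", "coalescent_units")
  if (any(needs_theta) && is.null(theta_nuc))
    stop("theta_nuc is required to convert generations or coalescent units")
  to_subs <- function(v, u) {
    switch(u,
           subs_per_site = v,
           myr = v * profile$per_lineage_rate,
           generations_Ne = v / 4 * profile$rate_multiplier * theta_nuc,
           coalescent_units = v / 2 * theta_locus(profile, theta_nuc))
  }
  from_subs <- function(v, u) {
    switch(u,
           subs_per_site = v,
           myr = v / profile$per_lineage_rate,
           generations_Ne = v * 4 / (profile$rate_multiplier * theta_nuc),
           coalescent_units = v * 2 / theta_locus(profile, theta_nuc))
  }
  from_subs(to_subs(value, from), to)
}

#' Effective locus theta on the locus substitution scale
#'
#' `theta_locus = heredity * rate * theta_nuc`: with mitochondrial
#' defaults (h = 0.25, r = 10) this reproduces theta_mit = 2.5 theta_nuc.
#' @inheritParams convert_units
#' @export
theta_locus <- function(profile, theta_nuc) {
  profile$heredity_multiplier * profile$rate_multiplier * theta_nuc
}

#' Study conditions and the default condition grid
#'
#' A study condition bundles the diversity parameters (mitochondrial theta
#' and substitution rate), a split depth, a multilocus strategy (a list of
#' marker profiles), the number of sequences sampled per ingroup species,
#' and the replicate count.
#'
#' @param theta_mit Mitochondrial theta in substitutions/site.
#' @param u_mit Mitochondrial rate in substitutions/site/Myr.
#' @param tau1_myr sp1--sp2 split depth in Myr.
#' @param strategy List of [marker_profile()] objects (one per locus).
#' @param n_per_species Sequences sampled per ingroup species per locus.
#' @param n_replicates Number of replicate data sets.
#' @param id Optional condition label.
#' @return An object of class `study_condition`.
#' @export
study_condition <- function(theta_mit, u_mit, tau1_myr, strategy,
                            n_per_species = 5L, n_replicates = 50L,
                            id = NULL) {
  stopifnot(theta_mit > 0, u_mit > 0, tau1_myr > 0,
            length(strategy) >= 1, n_per_species >= 1, n_replicates >= 1)
  if (is.null(id))
    id <- sprintf("th%g_u%g_t%g_%dloc_n%d", theta_mit, u_mit, tau1_myr,
                  length(strategy), n_per_species)
  structure(list(theta_mit = theta_mit, u_mit = u_mit,
                 tau1_myr = tau1_myr, strategy = strategy,
                 n_per_species = as.integer(n_per_species),
                 n_replicates = as.integer(n_replicates), id = id),
            class = "study_condition")
}

#' @rdname study_condition
#' @details `default_strategies()` returns the four multilocus strategies
#'   of the gene-tree discordance experiment: 1 mitochondrial locus,
#'   1 mitochondrial + 4 nuclear, 5 nuclear, and 10 nuclear loci.
#' @export
default_strategies <- function(u_mit = 0.01) {
  u_nuc <- u_mit / 10
  nucs <- function(k) replicate(k, nuclear_profile(u_nuc), simplify = FALSE)
  list(
    "1mit"      = list(mito_profile(u_mit)),
    "1mit+4nuc" = c(list(mito_profile(u_mit)), nucs(4)),
    "5nuc"      = nucs(5),
    "10nuc"     = nucs(10))
}

#' @rdname study_condition
#' @param strategies Named list of strategies (default
#'   [default_strategies()]).
#' @param tau1_grid Split depths in Myr.
#' @export
condition_grid <- function(theta_mit = c(0.025, 0.01),
                           u_mit = c(0.01, 0.02),
                           tau1_grid = c(0.5, 1, 3, 5, 10),
                           strategies = NULL,
                           n_per_species = 5L, n_replicates = 50L) {
  out <- list()
  for (th in theta_mit) for (u in u_mit) {
    strat <- if (is.null(strategies)) default_strategies(u) else strategies
    for (t1 in tau1_grid) for (s in names(strat)) {
      cond <- study_condition(th, u, t1, strat[[s]],
                              n_per_species, n_replicates,
                              id = sprintf("th%g_u%g_t%g_%s", th, u, t1, s))
      out[[cond$id]] <- cond
    }
  }
  out
}

#' Serialize a species tree to annotated Newick
#'
#' Writes the topology with branch lengths equal to time durations in
#' substitutions/site and per-population theta recorded in square-bracket
#' comments (`[&theta=...]`).
#' @param st A [species_tree()].
#' @param file Optional path; when `NULL` the string is returned.
#' @export
write_species_tree <- function(st, file = NULL) {
  phy <- st$phylo
  dur <- st$ages[phy$edge[, 1]] - st$ages[phy$edge[, 2]]
  phy$edge.length <- dur
  nwk <- ape::write.tree(phy)
  anno <- sprintf("[&theta_root=%g]", st$theta[length(st$labels) + 1])
  out <- paste0(sub(";$", "", nwk), anno, ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}
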