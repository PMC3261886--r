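#' Simulate a gene genealogy under the multispecies coalescent
#'
#' Draws one random gene tree embedded in a species tree under the
#' neutral multispecies coalescent: within every population with
#' effective parameter theta, j lineages coalesce after an exponential
#' waiting time with rate j(j-1)/theta, the coalescing pair is chosen
#' uniformly, and lineages that fail to coalesce before the top of a
#' population are handed to the parent population.  The root population
#' extends indefinitely, so coalescence always completes.  There is no
#' migration and no recombination within the locus.
#'
#' Node ages are kept on the canonical nuclear-mean substitutions/site
#' scale; the coalescent within each population therefore uses the
#' effective parameter `heredity_multiplier * theta` (the locus rate
#' multiplier cancels on this scale and only enters when branch lengths
#' are expressed in locus substitution units, e.g. for sequence
#' simulation).
#'
#' @param st A [species_tree()].
#' @param profile A [marker_profile()] for the locus.
#' @param samples Named integer vector: sequences sampled per species,
#'   e.g. `c(sp1 = 5, sp2 = 5, sp3 = 1, sp4 = 1)`.  Species absent from
#'   the vector are not sampled.
#' @param rng_seed Optional integer; when given, the draw is a
#'   deterministic function of it.
#' @return An object of class `gene_tree`: `parent` (0 for the root),
#'   `ages` (nuclear scale), `tip_species`, `tip_labels` (`"spK_i"`),
#'   `profile`.
#' @export
simulate_gene_genealogy <- function(st, profile, samples, rng_seed = NULL) {
  stopifnot(inherits(st, "species_tree"), inherits(profile, "marker_profile"))
  if (is.null(names(samples)) || any(!names(samples) %in% st$labels))
    stop("samples must be a named vector over the species labels")
  samples <- samples[samples > 0]
  ntip_total <- sum(samples)
  if (ntip_total < 1) stop("at least one lineage must be sampled")

  phy <- st$phylo
  nsp <- length(st$labels)
  parent_sp <- st_parents(phy)
  h <- profile$heredity_multiplier

  # tip bookkeeping
  tip_species <- rep(names(samples), samples)
  tip_labels <- unlist(lapply(names(samples), function(s)
    paste0(s, "_", seq_len(samples[[s]]))), use.names = FALSE)

  nnode <- max(2 * ntip_total - 1, 1)
  parent <- integer(nnode)
  ages <- numeric(nnode)
  next_node <- ntip_total + 1L

  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed %% .Machine$integer.max))

  # active lineages per species-tree population, processed bottom-up
  pop_order <- order(st$ages)
  pending <- vector("list", nsp + phy$Nnode)
  for (s in names(samples)) {
    sp_id <- match(s, st$labels)
    pending[[sp_id]] <- which(tip_species == s)
  }
  root_sp <- nsp + 1L
  for (v in pop_order) {
    lin <- pending[[v]]
    if (is.null(lin)) lin <- integer(0)
    t0 <- st$ages[v]
    t_end <- if (v == root_sp) Inf else st$ages[parent_sp[v]]
    theta_eff <- st$theta[v] * h
    t <- t0
    k <- length(lin)
    while (k >= 2) {
      wait <- stats::rexp(1, rate = k * (k - 1) / theta_eff)
      if (t + wait >= t_end) break
      t <- t + wait
      pair <- sample.int(k, 2)
      node <- next_node
      next_node <- next_node + 1L
      parent[lin[pair]] <- node
      ages[node] <- t
      lin <- c(lin[-pair], node)
      k <- k - 1L
    }
    if (v != root_sp) {
      up <- parent_sp[v]
      pending[[up]] <- c(pending[[up]], lin)
    } else if (k > 1) stop("internal error: root population did not coalesce")
  }

  structure(list(parent = parent, ages = ages,
                 tip_species = tip_species, tip_labels = tip_labels,
                 ntip = ntip_total, profile = profile),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d tips (%s), tMRCA %.5g subs/site (nuclear scale)\n",
              x$ntip, paste(unique(x$tip_species), collapse = ","),
              if (x$ntip > 1) max(x$ages) else 0))
  invisible(x)
}

#' Convert a gene tree to an `ape::phylo`
#'
#' Branch lengths are expressed in locus substitution units (age
#' differences times the locus rate multiplier), matching what a
#' sequence simulator or an estimated tree would see.
#' @param gt A `gene_tree`.
#' @param scale `"locus"` (default) or `"nuclear"` branch-length scale.
#' @export
as_phylo <- function(gt, scale = c("locus", "nuclear")) {
  scale <- match.arg(scale)
  r <- if (scale == "locus") gt$profile$rate_multiplier else 1
  n <- gt$ntip
  if (n == 1) stop("cannot convert a single-tip gene tree to phylo")
  nnode <- 2L * n - 1L
  root_old <- which(gt$parent == 0)
  # renumber internals in preorder from the root (ape convention)
  newid <- integer(nnode)
  newid[seq_len(n)] <- seq_len(n)
  kids <- split(seq_len(nnode)[-root_old], gt$parent[-root_old])
  nxt <- n + 1L
  stack <- root_old
  order_old <- integer(n - 1L)
  k <- 0L
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    k <- k + 1L
    order_old[k] <- v
    newid[v] <- n + k
    ch <- kids[[as.character(v)]]
    stack <- c(ch[ch > n], stack)
  }
  edge <- cbind(newid[gt$parent[-root_old]], newid[seq_len(nnode)[-root_old]])
  len <- (gt$ages[gt$parent[-root_old]] - gt$ages[seq_len(nnode)[-root_old]]) * r
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = gt$tip_labels, Nnode = n - 1L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "ages") <- c(numeric(n), gt$ages[order_old] * r)
  phy
}

# species bitmask of each gene-tree node (bit i = species i of st$labels)
gt_species_masks <- function(gt, st) {
  nnode <- 2L * gt$ntip - 1L
  mask <- integer(nnode)
  mask[seq_len(gt$ntip)] <- bitwShiftL(1L, match(gt$tip_species, st$labels) - 1L)
  for (v in order(gt$ages)) {
    p <- gt$parent[v]
    if (p > 0) mask[p] <- bitwOr(mask[p], mask[v])
  }
  mask
}

# species-tree node that is the MRCA of a species bitmask
st_mrca_of_mask <- function(st) {
  phy <- st$phylo
  nsp <- length(st$labels)
  parent_sp <- st_parents(phy)
  nn <- nsp + phy$Nnode
  node_mask <- integer(nn)
  node_mask[seq_len(nsp)] <- bitwShiftL(1L, seq_len(nsp) - 1L)
  for (v in order(st$ages)) {
    p <- parent_sp[v]
    if (p > 0) node_mask[p] <- bitwOr(node_mask[p], node_mask[v])
  }
  function(mask) {
    cand <- which(vapply(node_mask, function(m)
      bitwAnd(m, mask) == mask, logical(1)))
    cand[which.min(st$ages[cand])]
  }
}

#' Log density of a gene tree under the multispecies coalescent
#'
#' Evaluates the Rannala--Yang density of a genealogy given the species
#' tree: within each population the product over inter-event intervals of
#' the exponential survival terms `exp(-j(j-1)/theta * dt)` and, for each
#' coalescence, the rate `2/theta`, with theta the effective locus
#' parameter `heredity_multiplier * theta_pop`.  A genealogy violating
#' the population age constraints (a cross-species coalescence younger
#' than the corresponding species split) yields `-Inf` with attribute
#' `invalid = TRUE` rather than an error, so samplers can reject it.
#'
#' @inheritParams as_phylo
#' @param st A [species_tree()].
#' @return Scalar log density (nuclear time scale).
#' @export
msc_log_density <- function(gt, st, profile = gt$profile) {
  nsp <- length(st$labels)
  phy <- st$phylo
  parent_sp <- st_parents(phy)
  nn <- nsp + phy$Nnode
  h <- profile$heredity_multiplier
  mask <- gt_species_masks(gt, st)
  mrca_fun <- st_mrca_of_mask(st)

  # assign each coalescence to its population
  npop_events <- vector("list", nn)
  ninternal <- gt$ntip - 1L
  for (v in (gt$ntip + 1L):(2L * gt$ntip - 1L)) {
    base <- mrca_fun(mask[v])
    if (gt$ages[v] < st$ages[base] - 1e-15)
      return(structure(-Inf, invalid = TRUE))
    p <- base
    while (p != nsp + 1L && gt$ages[v] >= st$ages[parent_sp[p]]) p <- parent_sp[p]
    npop_events[[p]] <- c(npop_events[[p]], gt$ages[v])
  }

  # lineages entering each population, bottom-up
  entering <- integer(nn)
  for (s in unique(gt$tip_species))
    entering[match(s, st$labels)] <- sum(gt$tip_species == s)
  logd <- 0
  for (v in order(st$ages)) {
    j <- entering[v]
    theta_eff <- st$theta[v] * h
    t <- st$ages[v]
    t_end <- if (v == nsp + 1L) Inf else st$ages[parent_sp[v]]
    ev <- sort(npop_events[[v]])
    for (a in ev) {
      if (j < 2) return(structure(-Inf, invalid = TRUE))
      logd <- logd + log(2 / theta_eff) - j * (j - 1) / theta_eff * (a - t)
      j <- j - 1L
      t <- a
    }
    if (is.finite(t_end)) {
      if (j >= 2) logd <- logd - j * (j - 1) / theta_eff * (t_end - t)
      entering[parent_sp[v]] <- entering[parent_sp[v]] + j
    }
  }
  logd
}

#' Time to the most recent common ancestor of a gene tree
#'
#' @param gt A `gene_tree`.
#' @param species Optional subset of species; default all tips.
#' @return Age of the MRCA of the selected tips, in nuclear-scale
#'   substitutions/site (0 for a single lineage).
#' @export
gene_tmrca <- function(gt, species = NULL) {
  tips <- if (is.null(species)) seq_len(gt$ntip) else
    which(gt$tip_species %in% species)
  if (!length(tips)) stop("no tips for the requested species")
  if (length(tips) == 1) return(0)
  # walk each tip's ancestor chain; MRCA is the shallowest common node
  anc <- lapply(tips, function(v) {
    path <- integer(0)
    while (v != 0) { path <- c(path, v); v <- gt$parent[v] }
    path
  })
  common <- Reduce(intersect, anc)
  min(gt$ages[common])
}
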