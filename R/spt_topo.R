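#' Rooted Robinson-Foulds distance
#'
#' Counts the symmetric difference of the non-trivial clade sets of two
#' rooted trees over the same tips (clades of size 2 to n-1; the root
#' clade and the single tips are shared by construction).  This is the
#' rooted-clade convention: two rooted 5-taxon trees can differ by at
#' most 6.
#'
#' @param a,b Rooted trees: `phylo`, Newick strings, or `species_tree`.
#' @return Integer distance.
#' @export
rf_distance <- function(a, b) {
  ca <- rooted_clades(a)
  cb <- rooted_clades(b)
  if (!setequal(attr(ca, "tips"), attr(cb, "tips")))
    stop("trees must share an identical tip set")
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

rooted_clades <- function(x) {
  if (inherits(x, "species_tree")) x <- x$phylo
  if (is.character(x)) x <- ape::read.tree(text = x)
  stopifnot(inherits(x, "phylo"))
  n <- length(x$tip.label)
  clades <- character(0)
  for (v in (n + 2L):(n + x$Nnode)) {  # skip the root (n+1)
    tips <- sort(x$tip.label[tip_descendants(x, v)])
    if (length(tips) >= 2 && length(tips) <= n - 1)
      clades <- c(clades, paste(tips, collapse = "|"))
  }
  structure(unique(clades), tips = sort(x$tip.label))
}

tip_descendants <- function(phy, node) {
  n <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, phy$edge[phy$edge[, 1] == v, 2])
  }
  out
}

# canonical topology string (sorted children), matching the sampler's
canonical_topology <- function(x) {
  if (inherits(x, "species_tree")) x <- x$phylo
  if (is.character(x)) x <- ape::read.tree(text = x)
  rec <- function(v) {
    n <- length(x$tip.label)
    if (v <= n) return(x$tip.label[v])
    ch <- x$edge[x$edge[, 1] == v, 2]
    parts <- sort(vapply(ch, rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(length(x$tip.label) + 1L)
}

#' Joint posterior of the species-tree topology
#'
#' Extends [sample_msc_posterior()] with species-tree
#' nearest-neighbour-interchange moves (re-attaching a species subtree
#' across an internal branch with a re-draw of the affected divergence
#' time; gene trees are retained and the move is accepted or rejected
#' through the multispecies-coalescent density, which vetoes
#' incompatible combinations).  Under topology sampling the divergence
#' times use an exponential prior on the root age with the non-root
#' ages jointly uniform over the order polytope, and the topology prior
#' is uniform.
#'
#' @inheritParams sample_msc_posterior
#' @param start_topology Newick string for the initial topology; by
#'   default a random rooted topology drawn from the label set.
#' @return A `topology_posterior`: data frame `topologies` (canonical
#'   Newick, posterior frequency), `map_topology`, and the underlying
#'   `msc_trace`.
#' @export
sample_topology_posterior <- function(alignments, priors, loci,
                                      mcmc = mcmc_settings(),
                                      rng_seed = 1L,
                                      rate_mode = "fixed_true",
                                      heredity_mode = "fixed_true",
                                      external_rates = NULL,
                                      start_topology = NULL,
                                      seq_model = "hky") {
  species <- sort(unique(sub("_.*$", "", alignments[[1]]$labels)))
  if (is.null(start_topology)) {
    set.seed(as.integer(rng_seed %% .Machine$integer.max))
    phy <- ape::rtree(length(species), tip.label = sample(species))
    start_topology <- ape::write.tree(phy)
  }
  tr <- sample_msc_posterior(alignments, start_topology, priors, loci,
                             mcmc = mcmc, rng_seed = rng_seed,
                             rate_mode = rate_mode,
                             heredity_mode = heredity_mode,
                             external_rates = external_rates,
                             topology_moves = TRUE, seq_model = seq_model)
  tab <- sort(table(tr$topology), decreasing = TRUE)
  topologies <- data.frame(topology = paste0(names(tab), ";"),
                           frequency = as.numeric(tab) / sum(tab))
  structure(list(topologies = topologies,
                 map_topology = topologies$topology[1],
                 trace = tr),
            class = "topology_posterior")
}

#' @export
print.topology_posterior <- function(x, ...) {
  cat("<topology_posterior> MAP:", x$map_topology, "\n")
  print(utils::head(x$topologies, 5), row.names = FALSE)
  invisible(x)
}

#' Accuracy summary of a set of topology estimates
#'
#' @param results List of pairs `list(map_topology =, true_tree =)`, or
#'   a data frame with columns `map` and `truth` (Newick).
#' @return List with `percent_correct` and `mean_rf`.
#' @export
radiation_summary <- function(results) {
  if (is.data.frame(results))
    results <- lapply(seq_len(nrow(results)), function(i)
      list(map_topology = results$map[i], true_tree = results$truth[i]))
  if (!length(results)) stop("no results")
  correct <- vapply(results, function(r)
    canonical_topology(r$map_topology) == canonical_topology(r$true_tree),
    logical(1))
  rf <- vapply(results, function(r)
    rf_distance(r$map_topology, r$true_tree), numeric(1))
  list(percent_correct = 100 * mean(correct), mean_rf = mean(rf))
}
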