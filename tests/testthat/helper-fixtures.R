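# shared builders for small simulated fixtures (everything is generated
# in code; no stored data)

# internal helpers exercised directly by the tests
st_mrca_ids <- coaldelta:::st_mrca_ids
validate_species_tree <- coaldelta:::validate_species_tree
compress_patterns <- coaldelta:::compress_patterns
sim_single_pop_tree <- coaldelta:::sim_single_pop_tree
canonical_topology <- coaldelta:::canonical_topology

focal_tree_default <- function(tau1 = 1) build_focal_tree(0.025, 0.01, tau1)

focal_samples <- c(sp1 = 5L, sp2 = 5L, sp3 = 1L, sp4 = 1L)

sim_locus <- function(st, profile, samples = focal_samples, seed = 1) {
  gt <- simulate_gene_genealogy(st, profile, samples, rng_seed = seed)
  aln <- evolve_alignment(gt, rng_seed = seed + 5e5)
  list(gt = gt, aln = aln)
}

# manual two-tip gene tree at a fixed coalescence age (nuclear scale)
two_tip_gene_tree <- function(age, species = c("sp1", "sp2"),
                              profile = nuclear_profile()) {
  structure(list(parent = c(3L, 3L, 0L), ages = c(0, 0, age),
                 tip_species = species,
                 tip_labels = paste0(species, "_1"),
                 ntip = 2L, profile = profile),
            class = "gene_tree")
}

nuc_strategy <- function(k, u_nuc = 0.001)
  replicate(k, nuclear_profile(u_nuc), simplify = FALSE)

mixed_strategy <- function(u_mit = 0.01)
  c(list(mito_profile(u_mit)), nuc_strategy(4, u_mit / 10))
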