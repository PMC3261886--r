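# coaldelta

Deep coalescence and multilocus species-tree inference for shallow
mammalian phylogenies.

## The problem

When species diverged recently — as in most mammalian radiations of the
last few million years — the genealogy of any single locus predates the
species split: gene copies sampled from two sister species coalesce in
the ancestral population, not at the speciation event.  For a locus with
population parameter θ (substitutions/site), the expected excess is
between θ/2 (a single pair of lineages) and θ (many lineages), which for
typical mammalian mitochondrial diversity (θ ≈ 0.025) and rates (υ ≈
0.01 substitutions/site/Myr) amounts to *millions of years*.  A
phylogenetic (gene-tree) dating of a shallow split is therefore biased
upward, sometimes severely; coalescent-aware Bayesian species-tree
methods are not.  The practical question is then: how many loci, and of
which kind — slow nuclear loci with large θ, or a fast mitochondrial
locus with small θ — does the multilocus Bayesian approach need to
recover split times and topologies reliably?

`coaldelta` is a self-contained simulation-and-inference toolkit for
this question:

* **Simulation** — gene genealogies under the neutral multispecies
  coalescent (MSC) within parameterized 4- and 5-taxon species trees,
  and 1000-bp alignments under HKY85 with discrete-Γ(α = 1, 4 category)
  rate heterogeneity (κ = 10 mitochondrial, κ = 2 nuclear, equal base
  frequencies).
* **Gene-tree dating pipeline** — per-partition maximum-likelihood
  pairwise distances, neighbor joining, Langley–Fitch molecular-clock
  ultrametricization (Poisson-count ML), K-score rescaling, and the
  sp1–sp2 tMRCA in Myr.
* **Bayesian MSC sampler** (C++) — joint posterior of divergence times
  τ, population sizes θ, per-locus gene trees, and optionally per-locus
  rate and heredity multipliers, given per-locus alignments; Gamma θ
  priors, exponential/empirical τ priors; optional species-tree
  topology (NNI) sampling for 5-taxon radiations.
* **Experiment grids** — the δ discordance statistic
  (δ = 100·(tMRCA − τ)/τ), IQ ± 1.5·IQR whisker summaries, and
  orchestration over the study's condition grid
  (θ_mit ∈ {0.025, 0.01}, υ_mit ∈ {0.01, 0.02}, splits 0.5–10 Myr,
  strategies from 1 mitochondrial to 10 nuclear loci).

## Worked example

Measure the coalescent overestimation of a 1-Myr split dated from a
single mitochondrial gene (θ_mit = 0.025, υ_mit = 0.01), then estimate
the same split with the Bayesian multilocus sampler from 10 nuclear
loci:

```r
library(coaldelta)

cond_mit <- study_condition(0.025, 0.01, tau1_myr = 1,
                            strategy = list(mito_profile(0.01)),
                            n_per_species = 5, n_replicates = 50)
run_discordance_grid(list(cond_mit), seed = 1)[, c("mean_tmrca_myr", "mean_delta")]
#>   mean_tmrca_myr mean_delta
#> 1       2.731534   173.1534

cond_nuc <- study_condition(0.025, 0.01, tau1_myr = 1,
                            strategy = replicate(10, nuclear_profile(0.001),
                                                 simplify = FALSE),
                            n_per_species = 5, n_replicates = 10)
run_mb_grid(list(cond_nuc), seed = 1,
            mcmc = mcmc_settings(4000, 1000, 5))[, c("mean_percent_error",
                                                     "whisker_low", "whisker_high")]
#>   mean_percent_error whisker_low whisker_high
#> 1           10.50398   -37.46745     44.75588
```

The gene-tree approach dates the 1-Myr split at 2.7 Myr on average — a
δ of about 170%, i.e. the coalescent excess of roughly 1.5–2 N
generations that single-locus dating cannot see.  The Bayesian
multispecies-coalescent estimate from 10 nuclear loci is centered near
the truth (here −9% mean error across 10 replicates), with a whisker
range reflecting the irreducible coalescent variance at this depth.

Topology recovery for a 5-taxon moderate radiation
(internal branches of 0.5 and 1.6 N generations):

```r
r <- run_radiation_experiment("moderate",
                              replicate(10, nuclear_profile(0.001), simplify = FALSE),
                              n_replicates = 30, seed = 3,
                              mcmc = mcmc_settings(3000, 800, 4))
r$percent_correct
#> [1] 60
```

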