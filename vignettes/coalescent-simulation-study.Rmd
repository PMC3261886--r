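---
title: "Deep coalescence and multilocus divergence-time estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep coalescence and multilocus divergence-time estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coaldelta` implements a complete simulation study of how deep
coalescence distorts divergence-time estimates in shallow (mammal-like)
phylogenies, and of how a multilocus Bayesian species-tree method
recovers true split times and topologies from different marker sets.
This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and the limits of what
the accompanying tests demonstrate.

## The generative model

All simulations run through two layers.

**Multispecies coalescent (MSC).**  A species tree fixes a rooted
topology, internal-node ages τ, and one population parameter θ per
branch (plus the root stem), all in expected substitutions/site at the
nuclear mean rate.  Within a population with effective parameter θ, j
gene lineages coalesce at rate j(j−1)/θ; lineages that fail to coalesce
before the top of a population are passed to its parent; the root
population extends indefinitely.  There is no migration and no
recombination within a locus; distinct loci are independent ("free
recombination").

Per-locus bookkeeping follows two multipliers.  The *rate multiplier* r
(locus rate ÷ nuclear mean rate) converts nuclear-scale durations to
locus substitution units; the *heredity multiplier* h scales θ for
inheritance and ploidy.  Mitochondrial defaults are r = 10 and
h = 0.25, so the effective mitochondrial θ is 2.5 × the nuclear θ —
the θ_mit = 0.025 ↔ θ_nuc = 0.01 (and 0.01 ↔ 0.004) pairing of typical
mammalian diversity surveys.  On the canonical nuclear time scale the
coalescent sees θ·h (r cancels); r re-enters only when branch lengths
are expressed in locus substitutions.

**Sequence evolution.**  Alignments of 1000 bp evolve along simulated
gene trees under HKY85 with equal base frequencies — which is exactly
the two-parameter Kimura model, so the closed-form K80 transition
probabilities are used throughout — with κ = 10 (mtDNA) or κ = 2
(nuclear) and discrete-Γ rate heterogeneity (shape α = 1, 4
equal-probability categories whose rates are the conditional category
means; they average to 1 by construction).  The root sequence is
uniform over the four bases.

## Study conditions (the generator's defaults)

The defaults *are* the study conditions and are not meant to be tuned:

| parameter | values | unit |
|---|---|---|
| θ_mit | 0.025, 0.01 | subs/site |
| υ_mit | 0.01, 0.02 | subs/site/Myr |
| υ_nuc | υ_mit / 10 | subs/site/Myr |
| τ1 (sp1–sp2 split) | 0.5, 1, 3, 5, 10 | Myr |
| internal branches x, y | 4 Ne, 8 Ne | generations |
| loci | 1 mit; 1 mit + 4 nuc; 5 nuc; 10 nuc | — |
| sequences | 5 per ingroup species, 1 per outgroup | — |
| replicates | 50 (100 for radiations) | — |

The 4-taxon tree is the asymmetric `(((sp1,sp2),sp3),sp4)` with
constant θ; the long x and y branches make outgroup lineage sorting
negligible, so rooting on sp4 is safe.  The 5-taxon radiation trees add
sp5 (12 Ne stem) and shrink x, y to 0.5/1.6 Ne ("moderate") or
0.1/0.2 Ne ("fast", deep in anomalous-gene-tree territory), with the
sp1–sp2 split at 8 Ne.  The radiation experiment's θ is not dictated by
the condition grid; the package uses θ_nuc = 0.01 (the
high-discordance condition used throughout the later experiments), and
it is an argument of `run_radiation_experiment()` so it can be varied.
N_e never appears as a number: every Ne-denominated branch is resolved
through θ (g Ne generations = (g/4)·θ_nuc substitutions/site).

A scientist's expectation under these conditions, and a useful check
against any implementation: the excess E[tMRCA − τ1] for a sample of
sp1 and sp2 gene copies is bounded by [θ_locus/2, θ_locus].  With
θ_mit = 0.025 that is 1.25–2.5 Myr of overestimation at υ_mit = 0.01,
regardless of how shallow the true split is.

## The gene-tree (classical phylogenetics) arm

Per replicate, the loci are analysed as a partitioned concatenation at
the distance level: per-partition maximum-likelihood pairwise distances
under K80+Γ4 with κ and α fixed at the simulation truth (numerically
optimized per pair from the identical/transition/transversion site
counts), combined across partitions weighted by partition length;
neighbor joining; negative branch lengths clamped to zero; rooting on
the known outgroup.  A full ML topology search is deliberately not
re-implemented: on 11–26 tip simulated data the distance pipeline is
statistically consistent, and every quantity the study reports is a
distribution-level summary, not a per-tree quantity.

Ultrametricization is Langley–Fitch: branch substitution counts
(length × alignment length) are Poisson observations under one rate,
and node ages are optimized with ages parameterized top-down as
fractions of the parent age (positivity and parent-older-than-child by
construction), from a mean-depth initialization, to a relative
log-likelihood tolerance of 1e-10.  One subtlety matters: after
outgroup rooting, the two root-child edges are a single unrooted branch
split at an arbitrary point, so their counts enter as one joint Poisson
observation on the summed duration — without this the clock is
inconsistent even on noise-free distances (the package's tests verify
exact recovery in that limit).  The clock tree is then rescaled by
k* = Σ(b_ref·b_clock)/Σ(b_clock²), the least-squares-through-origin
scalar of the K-score, with the root pair again matched as one branch.

The sp1–sp2 divergence is the age of the MRCA of the *union* of sp1 and
sp2 tips (well defined under non-monophyly), divided by the
partition-length-weighted mean per-lineage rate.  The discordance
statistic is δ = 100·(tMRCA − τ)/τ, summarized over 50 replicates by
the mean and by the lowest/highest values inside IQ ± 1.5·IQR, with
quartiles by R's default linear-interpolation (type 7) convention.
Pairs beyond the Jukes–Cantor saturation bound (p ≥ 0.749) are capped
at a configurable maximum distance (default 5) with a warning.

## The Bayesian multilocus (MB) arm

`sample_msc_posterior()` targets the joint posterior of (τ, θ, per-locus
gene trees, and optionally per-locus rate and heredity multipliers)
given per-locus alignments, on a fixed species-tree topology.  The
sequence likelihood is JC69 by the package's deliberate choice: the
classic coalescent samplers used a simple substitution model, and this
model mismatch is precisely what produces the documented downward bias
for fast mitochondrial loci.  A K80 likelihood (κ fixed at the marker's
value) is available via `seq_model = "hky"`.

Priors: each θ gets a Gamma prior derived from a mean and a central 95%
interval by a 1-D search over the shape (defaults: mean 0.025, interval
0.003–0.07 → Gamma(2, 0.0125); shapes are bounded above at 100, beyond
which an interval is declared infeasible).  For a fixed topology the
sp1–sp2 split gets an exponential prior whose mean is set empirically —
the average minimum sp1–sp2 divergence in per-locus clock trees,
mitochondrial trees divided by the nominal rate ratio 10 — and the
deeper nodes stack further exponential increments with the same mean
(the source method names no outgroup-node prior; independent
same-mean increments respect the ordering and keep the τ1 marginal
exactly exponential).  When the topology is sampled, the root age gets
the exponential prior and the non-root ages are jointly uniform over
the order polytope (normalized per topology by its number of linear
extensions, so the topology prior stays uniform).

When rates are *estimated internally* they follow a mean-one Dirichlet
prior (concentration 2) sampled by sum-preserving exchange moves — the
normalization convention of the classic samplers.  τ is then on the
locus-mean-rate scale and is reported back on the nuclear scale through
the nominal class factor (10·n_mit + n_nuc)/n, the "adjust to the
nuclear mean by the assumed rate ratio" convention.  The pull of the
Dirichlet toward equal rates, combined with JC69's saturation of κ = 10
data, is what biases the mixed-strategy split times downward; fixing
the ratios externally (per-locus ML tree lengths normalized to mean
one, `estimate_rate_ratios_external()`) removes most of it.  Estimated
heredity multipliers get Gamma(shape 4) priors with mean 1 (nuclear) or
0.25 (mtDNA); the source names no such prior, so this weakly
informative choice centered on the true inheritance scalars is the
package's own.

**Moves** (one "sweep" covers all of them): gene-node age sliders
(uniform window with reflection; multiplicative for the root),
constrained Wilson–Balding regrafting (the re-attachment time is
proposed multiplicatively and the target lineage drawn uniformly among
lineages crossing that time *in the same population*, with the exact
candidate-count Hastings ratio), species-node rubber-band moves (the
proposed τ rescales the enclosed gene-node ages in the two child
populations and the node's own population, with the product of the
per-node map derivatives as the Jacobian; the root shifts its
population's ages), multiplicative θ moves, a whole-state scaling
(mixing) move, rate-exchange and heredity moves when estimated, and —
for topology sampling — rooted NNI on the species tree with a uniform
re-draw of the affected τ, accepted through the MSC density (which
vetoes combinations incompatible with the retained gene trees).
Proposal step sizes auto-tune during burn-in toward acceptance rates of
0.2–0.5.

**Correctness evidence**, all in the test suite: with the likelihood
switched off the sampler reproduces its priors (KS); for a single
population and for two species the posteriors match brute-force grid
integrations of the same JC likelihood (KS < 0.05); and
successive-conditional (Geweke-style) cycles — draw from the prior,
alternate one MCMC cycle with re-simulation of the data from the
current gene tree — leave the τ1 and θ marginals at their priors
(batch-mean z-scores) on a tiny 6-tip, 50-bp configuration.  The
sequence likelihood itself is verified to machine precision against an
independent pruning implementation (`phangorn::pml`) for both JC and
K80/κ = 10.

## Topology estimation for radiations

`sample_topology_posterior()` adds the NNI move and reports posterior
topology frequencies and the modal (MAP) topology per replicate;
`run_radiation_experiment()` aggregates the proportion of replicates
whose MAP equals the truth and the mean Robinson–Foulds distance.  RF
is computed on *rooted clades* (symmetric difference of non-trivial
clades; two rooted 5-taxon trees differ by at most 6) — the reference
values ≤ 2.74 on 5 taxa are consistent with either convention, and the
rooted one matches the rooted trees the sampler actually produces.
The topology runs use the K80 likelihood, since the method they
emulate models the transition/transversion ratio; the chain starts
from a random topology, and the gene trees are initialized compatibly
by simulation from the initial species tree.

## Problem sizes and chain profiles

`mcmc_settings(profile = "paper")` mirrors the full-scale design
(10^6 generations, 150k burn-in, thinning 100 — with the caveat that
one sweep here comprises a full move cycle, so these chains are far
longer in effective moves than the original single-move generations).
The default `"ci"` profile and the sizes used by the test suite and the
acceptance script are deliberately small so the whole study re-runs on
one CPU in minutes: 2 500–5 000 sweeps per chain, 10–30 replicates per
condition, 24 paired seeds for the rate-handling comparison, 30
replicates per radiation cell.  Consequences worth knowing:

* per-condition means carry Monte-Carlo error of a few percent (the
  50-replicate δ experiments have SE ≈ 0.2 Myr);
* the monotone decline of whisker width from 5 to 10 nuclear loci is
  real but smaller than whisker sampling noise at 10 replicates, so the
  test suite only asserts the 1-vs-multilocus contrast;
* radiation percent-correct values at 30 replicates have ±17%
  binomial 95% intervals.

## Known limitations

* The simulator covers complete isolation only: no migration, no
  intralocus recombination, no population-size change through time.
* Gene-tree estimation is distance-based (NJ + clock), not a full ML
  topology search; per-tree topologies are noisier than RAxML's even
  though the distributional summaries match.
* The inference likelihood ignores among-site rate heterogeneity (and,
  in JC mode, the transition/transversion ratio) by design; this is a
  feature for reproducing model-mismatch effects, a limitation for
  anything else.
* Synthetic data are ideal in ways real data are not: no alignment
  error, no missing data, no selection, exact knowledge of marker
  class and (in most experiments) of relative rates.  Passing tests
  demonstrate internal consistency of the models above, not robustness
  to these real-data complications.
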