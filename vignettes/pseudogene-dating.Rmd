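---
title: "Modeling gene and pseudogene evolution with pdlrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene and pseudogene evolution with pdlrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdlrs)
```

## The model

`pdlrs` models the evolution of an extended gene family — genes together
with pseudogenes — inside a dated species tree `S`. A single gene lineage
enters at the degree-one root of `S` and evolves towards the leaves under a
two-type linear birth–death process:

* a **gene** lineage duplicates at rate `delta`, is lost at rate `mu`, and
  converts irreversibly into a **pseudogene** lineage at rate `psi`;
* a pseudogene lineage duplicates and is lost at the same `delta` and `mu`
  but never converts back;
* at every speciation vertex a lineage bifurcates deterministically, one
  copy per descendant species edge.

Lineages without extant descendants are pruned. Conversions survive
pruning as degree-two *pseudogenization vertices* of the gene tree; the set
of these vertices (`Psi`) is an antichain — no two of them can sit on one
root-to-leaf path — and every extant pseudogene must descend from exactly
one of them.

Branch lengths arise from a relaxed molecular clock: each edge draws an
independent rate from a gamma distribution parameterized by a mean and a
coefficient of variation (shape `1/cv^2`, scale `mean*cv^2`), and the edge
length is rate times duration, in expected substitutions per codon site.
Sequences evolve along the tree under GY94-style codon models: zero rate
between codons differing at more than one position, a `kappa` factor for
transitions, and an `omega` (dN/dS) factor for nonsynonymous changes. Gene
lineages use an `omega` estimated from the data over the 61 sense codons
(no rates touching stops); pseudogene lineages use a neutral model
(`omega = 1`) over all 64 codons in which single-position changes into and
out of stop codons are allowed. Codon equilibrium frequencies are shared
by both modes; we estimate them by F64 counting with add-one pseudocounts
over the complete codons of all sequences, renormalizing over the sense
codons for the gene mode. The root state distribution is the gene-mode
equilibrium — the root predates every pseudogenization by construction.

## The gene-tree prior

The probability density of a gene tree with lengths and pseudogenization
vertices, `p(G, l | theta, Psi, S)`, is computed by dynamic programming
over a *discretized* species tree: every edge of `S` is augmented with
equidistant interior time points (default: one point per `height/30` of
edge duration, floor 3 per edge, configurable) and the time integrals over
event placements are approximated by sums over those points, each interior
point carrying its slice width as quadrature weight.

The table entry `s(x, y, u)` is the density that a single lineage starting
at point `x` generates the observed subtree hanging from gene-tree vertex
`u`, with `u`'s event at point `y`. Leaves anchor at their species leaf;
at its species-tree MRCA a binary vertex multiplies the two side-restricted
descendant sums; at interior points a binary vertex is a duplication with
factor `2*delta*dt` and a pseudogenization vertex (single child) a
conversion with factor `psi*dt`; and path extension one point upward
multiplies

* the per-slice "1-to-1" probability `p11` of the edge's mode (gene or
  pseudogene, depending on whether the parent vertex already emits
  pseudogene lineages),
* at a speciation vertex, the extinction probability of the unobserved
  sibling-side copy, and
* the replacement of the induced length density `g(l, t) = rho(l/t)/t`
  over the shorter span by the one over the longer span, so each gene-tree
  edge retains exactly one length-density factor.

Two details of this construction were design choices:

* **Side sums at speciations.** The descendant sums consumed by the
  speciation case exclude the sibling-side extinction factor on the final
  step into the speciation vertex: there the sibling side is occupied by
  the other child, so no off-path copy exists. Without this distinction a
  single-copy family at zero event rates would receive probability zero;
  with it the generative density integrates to one over lengths on forced
  topologies (verified by an exact importance-sampling identity in the
  tests) and agrees with forward-simulation frequencies.
* **The conversion case.** The event factor for a pseudogenization vertex
  mirrors the duplication case with rate `psi` and a single child (an
  unordered unary event, hence no factor 2), and conversions are placed
  only at interior points — event times at speciation vertices have
  measure zero in continuous time. This case is validated against the
  forward simulator (`simulation_consistency_check`), which makes no use
  of the dynamic program.

The extinction probabilities solve the coupled Riccati system
`Ep' = mu - (delta+mu)Ep + delta*Ep^2` and
`Eg' = mu - (delta+mu+psi)Eg + delta*Eg^2 + psi*Ep`; because conversion
does not change survival rates, `Eg = Ep` exactly, which the
implementation asserts to tolerance while keeping the two-type machinery.
Both are integrated by fixed-step RK4 with 20 substeps per discretization
slice (smooth scalar dynamics; fixed steps keep runs bit-reproducible),
jointly with the running integral of the extinction curve, from which the
per-slice 1-to-1 factor is
`exp(2*delta*int(eps) - (delta+mu[+psi])*dt)`; per-path values compose
multiplicatively. The per-vertex DP tables are rescaled by their maximum
with the log-scale tracked separately, so deep trees do not underflow.

## Sequence likelihood

`sequence_log_likelihood` runs Felsenstein pruning in the unified 64-codon
state space (the gene matrix is embedded with zero rates touching stops,
which provably gives the same result as a 61-state pruning — tested), so a
single partial-likelihood vector passes through mode switches at
pseudogenization vertices. The edge above a pseudogenization vertex
evolves in gene mode for its full length; the vertex itself is the switch
point. Site patterns are compressed; codons containing gaps or ambiguity
are fully missing (all-one partials); underflow is controlled by scalar
rescaling per internal vertex. Transition matrices come from the cached
spectral decomposition of the reversible generator.

## Posterior sampling

The sampler is Metropolis–Hastings over `(G, l, theta, Psi)` with the
factorization `P(D|G,l,Psi) * p(G,l|theta,Psi,S) * p(theta)`; the
normalizing constant cancels in the acceptance ratio. Default priors are
exponential(0.1) on `delta`, `mu`, `psi`, log-normal(0,1) on the edge-rate
mean, exponential(1) on its coefficient of variation, and uniform on the
proposal truncation boxes `[0,10]` for `omega` and `[0,100]` for `kappa`;
all are configurable.

Moves, chosen by configurable weights (defaults 30% lengths, 20% scalar
parameters, 20% pseudogenization, 30% topology; 0% topology in fixed-tree
mode):

* **Scalars and lengths**: truncated-normal random walks on their support,
  with the exact truncated-normal Hastings correction; proposal scales
  adapt towards 20–40% acceptance during burn-in only.
* **Pseudogenization**: an up-move merges two sibling pseudogenization
  vertices into one on the parent edge; a down-move splits one vertex
  through the binary vertex below it onto the two child edges. Up and
  down directions are proposed with equal probability; since the number
  of vertices (and hence of free sub-edge lengths) changes, the moves are
  reversible-jump with uniform position draws and the corresponding
  length Jacobians, plus the menu-size asymmetry. These moves connect all
  valid antichain covers of the pseudogene leaves; the position of a
  vertex along its edge is sampled by the ordinary length moves.
* **Topology**: NNI and rooted SPR on the suppressed skeleton, with
  pseudogenization vertices riding on their edges. Menus are restricted
  to moves that keep the configuration valid (a subtree containing genes
  or pseudogenization vertices cannot regraft below an existing
  pseudogenization vertex; a subtree with uncovered pseudogene leaves
  must), and the Hastings ratio accounts for the menu sizes and, for SPR,
  the detach/attach length Jacobians. Regrafting onto the stem edge
  relocates the root, which covers rerooting.

Chains start from a neighbor-joining tree on codon-level p-distances
(midpoint-rooted, short branches floored) with the minimal valid
pseudogenization placement: one vertex at the midpoint of the parent edge
of each maximal all-pseudogene clade. In fixed-tree mode a supplied tree
is used and topology moves are disabled while `Psi`, lengths and
parameters are still sampled. Default run lengths mirror the protocol the
model family was introduced with (5,000,000 iterations, burn-in 2,500,000,
thinning 500); all analyses in this package's tests use much shorter
chains, as listed below. Convergence is monitored by effective sample
size and split-Rhat on the scalar traces.

Sampler correctness is checked two ways rather than by inspection: with
the data-dependent factors disabled and only scalar moves active the
marginal samples must reproduce the priors (this isolates the
truncated-normal proposal machinery; with the gene-tree prior left on,
the theta-marginal would be tilted by the probability that the fixed leaf
set is generated, so the clean reference target is the prior itself), and
on a three-leaf, two-codon problem with fixed lengths the chain's law
over topology-and-placement must match direct enumeration.

## Realizations and pseudogenization dating

Given a state, a dated realization maps gene-tree vertices to
discretization points by the standard top-down stochastic backtrace
through the DP tables (root child proportional to its root row, children
conditionally on their parent, side-restricted at speciation placements).
A pseudogenization vertex is then dated by linear interpolation between
the realized times of its endpoints, weighted by its two incident edge
lengths — the two sub-edges carry independent rate draws, so the length
fraction is the natural proxy for the time fraction. Realization times
strictly decrease along every path, and interpolated times stay inside
their bracketing interval (asserted in tests).

## Comparing pseudogenization configurations

Suppressing the degree-two vertices of two configurations of one family
yields the same binary tree; each configuration becomes a set of marked
edges with origins (and, with a realization, origin times). A marked edge
of one set with the corresponding edges of the other set strictly below
it is a *roof* and those edges its *shade*; identical edges roof
themselves at distance zero. The edge distance is the number of internal
vertices on the unique shortest path containing both edges. The average
topological distance `D_a` is the mean over roofs of the mean roof–shade
distance, the maximum `D_m` the max of maxima; temporal analogues use
absolute origin-time differences. Posterior summaries report the
posterior-weighted expectation `E_*` and, over the support, the maximum
`M_*` of the per-sample distances; we take the maximum without the
posterior weight factor, since a probability-weighted maximum has no
coherent reading as a distance. Samples whose suppressed topology differs
from the reference cannot be compared edge-by-edge and are counted
separately.

## The synthetic-data generator

`simulate_gene_tree`/`simulate_alignment` implement the generative model
directly (Gillespie simulation of the two-type process, per-edge gamma
rates, codon sampling down the tree) and double as the independent oracle
for the analytical machinery. `synthetic_study` reproduces the study
design the model family was evaluated under: 25 families, one per cell of
`omega in {0.3, 0.6, 0.8, 1.2, 1.8} x kappa in {0.2, 0.8, 1.2, 1.6, 2.0}`,
pseudogenization rate 0.5, uniform codon frequencies, on a nine-taxon
amniote host tree scaled to depth 1.0 (one unit = 400 million years) with
a 0.1 stem. The duplication–loss regime of the original study is not
recoverable from its description; we set `delta = mu = 0.5` per unit time,
comparable to the stated conversion rate and yielding family sizes in the
single digits to low tens, and expose both as arguments. The host tree's
topology and times are a synthetic stand-in assembled from consensus
vertebrate divergence times, not a download. Families that go fully
extinct or contain no pseudogene leaf (or fewer than two leaves) are
redrawn, mirroring the study's selection of families with pseudogenes;
the default 300 codon sites is our choice. The generator emulates
duplication, loss, conversion and rate variation but none of several
features of real pseudogene data: alignment error and fragmentary
pseudogenes, indels and frameshifts, processed (retrotransposed)
pseudogenes, selection heterogeneity across sites, or dating error in the
host tree — so passing tests speak to the inference machinery, not to
robustness against those artifacts.

## Problem sizes used in the test suite

The automated tests favor many small, sharply-checked instances:
oracle-equivalence tests use two- to four-species hosts with two to six
codon columns; the prior-recovery check uses 10,000 thinned samples; the
toy-enumeration check 30,000 iterations; the parameter-recovery study 40
four-species families of 60 codons with fixed-tree chains of 6,000
iterations; and the grid replication runs the full 25-family design at
120 codon sites with fixed-tree chains of a few thousand iterations over
the true and neighbor-joining candidate trees. These sizes are
deliberate scale-downs of the original protocol chosen to keep the whole
suite runnable on a laptop; the package itself runs arbitrarily long
chains.

Two design points of the parameter-recovery (credible-interval coverage)
study deserve emphasis. First, its families are simulated
*unconditionally* at the known rates, apart from requiring survival and
at least two leaves: selecting families that contain a pseudogene leaf —
as the grid study does, mirroring how real pseudogene families are
assembled — enriches for histories with many or early conversions and
shifts the conversion-rate posterior above the generating value, so a
coverage study run on such selected families would measure the
ascertainment bias rather than the sampler. Second, its chains weight
parameter moves more heavily than the default mix (45% versus 20%),
since the scalar parameters are the quantity being summarized and the
tree is held fixed.

## Known limitations

* The discretized time integrals converge at first order in the slice
  width; very coarse grids bias the prior (the refinement test quantifies
  this).
* The supplementary derivations of the original 1-to-1 probabilities are
  not public; our ODE formulation is pinned to the verbal definitions and
  validated against forward simulation, not against the original
  binaries.
* Rate variation is edge-wise i.i.d.; no site-rate heterogeneity, no
  codon-position models, no indel model.
* The sampler updates one component per iteration; for large families the
  topology moves' menu enumeration is the bottleneck.
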