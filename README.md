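# pdlrs

Probabilistic inference of gene-tree evolution for extended gene families
— genes together with their pseudogenes — inside a dated species tree,
with explicit dating of pseudogenization events.

Many gene families (olfactory receptors and KRAB zinc fingers are classic
examples) contain large numbers of pseudogenes, and some of those are old
and surprisingly conserved. Deciding *when* a lineage stopped being a gene
requires treating genes and pseudogenes jointly: this package implements a
generative model in which a gene lineage evolving inside a dated species
tree undergoes

* duplication at rate δ, loss at rate μ, and irreversible
  gene-to-pseudogene conversion at rate ψ (pseudogene lineages keep
  duplicating and dying, and bifurcate deterministically at speciations);
* a relaxed molecular clock — independent Γ(mean m, CV c) rate per edge,
  edge length = rate × duration; and
* GY94-style codon substitution with transition/transversion ratio κ:
  dN/dS = ω over the 61 sense codons for genes, and a neutral (ω = 1)
  64-codon model for pseudogenes in which changes into and out of stop
  codons are allowed.

Conversions appear as degree-two vertices of the gene tree. The package
provides the likelihood machinery (Felsenstein pruning with a model
switch at those vertices; a dynamic program over a discretized species
tree for the gene-tree prior, built on the extinction and "1-to-1"
probabilities of the two-type birth–death process), a Metropolis–Hastings
sampler over trees, lengths, conversion configurations and parameters, a
forward simulator, posterior sampling of dated realizations, and
topological/temporal distance metrics between pseudogenization
configurations with their posterior summaries.

## A worked example

Simulate a three-species family, then sample the posterior of its
pseudogenization configuration and dates on the true tree:

```r
library(pdlrs)
set.seed(7)
st <- parse_dated_species_tree(
  "((human:0.25,dog:0.25):0.75,opossum:1.0):0.1;")
pi_u <- rep(1/64, 64)
gm <- build_rate_matrix(2, 0.4, pi_u, "gene")
pm <- build_rate_matrix(2, 1, pi_u, "pseudogene")
repeat {
  sim <- simulate_gene_tree(st, bd_rates(0.5, 0.5, 0.5))
  if (!sim$extinct && sum(sim$state$is_leaf) >= 3 &&
      any(sim$state$leaf_class[sim$state$is_leaf] == "pseudogene")) break
}
gs  <- assign_lengths(sim, 1, 0.5)
aln <- simulate_alignment(gs, gm, pm, 150)

tr <- run_chain(aln, st,
        config = chain_config(iterations = 4000, burn_in = 1000,
                              thinning = 10, seed = 1, fixed_tree = gs,
                              sample_realizations = TRUE))
round(colMeans(tr$samples[c("delta", "mu", "psi", "kappa", "omega")]), 2)
#> delta    mu   psi kappa omega
#>  0.69  0.54  2.31  2.15  0.39

truth <- psi_configuration(gs, sim$time)
cfgs <- lapply(seq_along(tr$trees), function(i)
  psi_configuration(tr$trees[[i]], tr$realizations[[i]]$time))
posterior_summaries(truth, cfgs, temporal = TRUE)[c("E_Da", "E_Ta")]
#> $E_Da
#> [1] 0.1516667
#> $E_Ta
#> [1] 0.3229179
```

The simulated family has four pseudogene leaves under three conversion
events (true times 0.30, 0.46 and 0.02 on a tree of depth 1). The
posterior means of the model parameters sit near the simulation values
for δ, μ, κ, ω (ψ is weakly identified by a single family against its
diffuse exponential prior). `E_Da` is the posterior expectation of the
average topological distance between the inferred and true conversion
configurations — 0.15 edges here, i.e. the sampled configurations almost
always coincide with the truth — and `E_Ta` the corresponding expected
average dating error in tree-depth units. A short free-topology run
(`fixed_tree = NULL`) starts from a neighbor-joining tree instead and
also samples the topology by NNI/SPR.

A thin command-line wrapper with `simulate`, `infer` and `distances`
subcommands is installed at `system.file("cli/pdlrs", package="pdlrs")`.

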