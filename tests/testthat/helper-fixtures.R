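# shared fixtures: all data are generated in code

two_species_tree <- function(t_spec = 1, stem = 0.5) {
  parse_dated_species_tree(
    sprintf("(A:%g,B:%g):%g;", t_spec, t_spec, stem))
}

three_species_tree <- function() {
  parse_dated_species_tree("((A:1,B:1):1,C:2):0.5;")
}

four_species_tree <- function() {
  parse_dated_species_tree("((A:0.5,B:0.5):0.5,(C:0.6,D:0.6):0.4):0.3;")
}

# leaf map from the labels of a state (labels ending in P = pseudogene)
leaf_map_of <- function(gs) {
  lv <- which(gs$is_leaf)
  data.frame(id = gs$label[lv], species = gs$leaf_species[lv],
             class = gs$leaf_class[lv], stringsAsFactors = FALSE)
}

# build a gene-tree state from Newick where leaf labels are
# <species>_<copy>[P]; a trailing P marks a pseudogene
toy_state <- function(newick, stem_length = 0.3) {
  lab <- ape::read.tree(text = newick)$tip.label
  lm <- data.frame(id = lab,
                   species = sub("_.*$", "", lab),
                   class = ifelse(grepl("P$", lab), "pseudogene", "gene"),
                   stringsAsFactors = FALSE)
  read_gene_tree(newick, lm, stem_length = stem_length)
}

# a simulated non-extinct family with at least one pseudogene leaf
sim_family <- function(st, rates, rate_mean = 1, rate_cv = 0.5,
                       n_codons = 40, kappa = 2, omega = 0.5,
                       need_pseudo = TRUE, min_leaves = 2) {
  pi_u <- rep(1 / 64, 64)
  gm <- build_rate_matrix(kappa, omega, pi_u, "gene")
  pm <- build_rate_matrix(kappa, 1, pi_u, "pseudogene")
  repeat {
    sim <- simulate_gene_tree(st, rates)
    if (sim$extinct) next
    nl <- sum(sim$state$is_leaf)
    np <- sum(sim$state$leaf_class[sim$state$is_leaf] == "pseudogene")
    if (nl >= min_leaves && (!need_pseudo || np >= 1)) break
  }
  gs <- assign_lengths(sim, rate_mean, rate_cv)
  aln <- simulate_alignment(gs, gm, pm, n_codons)
  list(gs = gs, aln = aln, time = sim$time, gm = gm, pm = pm)
}
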