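test_that("with all rates zero the family mirrors the species tree", {
  st <- nine_taxon_species_tree()
  sim <- simulate_gene_tree(st, bd_rates(0, 0, 0), seed = 1)
  expect_false(sim$extinct)
  gs <- sim$state
  expect_equal(sum(gs$is_leaf), 9L)
  expect_equal(sort(gs$leaf_species[gs$is_leaf]),
               sort(st$label[st$is_leaf]))
  expect_equal(sum(gs$is_psi), 0L)
  expect_true(all(gs$leaf_class[gs$is_leaf] == "gene"))
})

test_that("pure-birth expected family size matches the Yule formula", {
  # one species, stem time T: E[#leaves] = exp(delta * T)
  st <- structure(list(parent = c(2L, NA_integer_),
                       children = list(integer(0), 1L),
                       time = c(0, 1), is_leaf = c(TRUE, FALSE),
                       label = c("A", NA), root = 2L, n_vertices = 2L),
                  class = "dated_species_tree")
  delta <- 0.8
  set.seed(13)
  sizes <- replicate(2500, {
    sim <- simulate_gene_tree(st, bd_rates(delta, 0, 0))
    sum(sim$state$is_leaf)
  })
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - exp(delta)), 3 * se)
})

test_that("pseudogene content increases with the conversion rate and the
           leaf classes always respect the configuration", {
  st <- four_species_tree()
  set.seed(14)
  frac <- vapply(c(0.1, 0.5, 1.5), function(p) {
    hits <- 0
    for (k in 1:200) {
      sim <- simulate_gene_tree(st, bd_rates(0.3, 0.3, p))
      if (!sim$extinct && any(sim$state$is_psi)) hits <- hits + 1
      if (!sim$extinct) {
        v <- validate_state(sim$state)
        # lengths unset at this stage: ignore length violations
        expect_false(any(grepl("pseudogenization ancestor|descends from",
                               v$violations)))
      }
    }
    hits / 200
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("relaxed-clock lengths have the right moments and independence", {
  st <- nine_taxon_species_tree()
  m <- 1.4; cv <- 0.5
  set.seed(15)
  ratios <- numeric(0)
  pairs <- matrix(numeric(0), ncol = 2)
  while (length(ratios) < 2500) {
    sim <- simulate_gene_tree(st, bd_rates(0.5, 0.5, 0.5))
    if (sim$extinct) next
    gs <- assign_lengths(sim, m, cv)
    for (v in seq_len(gs$n)) {
      p <- gs$parent[v]
      if (is.na(p)) next
      span <- sim$time[p] - sim$time[v]
      if (span < 1e-6) next
      ratios <- c(ratios, gs$edge_length[v] / span)
      if (!is.na(gs$parent[p]) && sim$time[gs$parent[p]] - sim$time[p] > 1e-6)
        pairs <- rbind(pairs, c(gs$edge_length[v] / span,
                                gs$edge_length[p] /
                                  (sim$time[gs$parent[p]] - sim$time[p])))
    }
  }
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - m), 3 * se)
  # parent/child rates uncorrelated
  r <- cor(pairs[, 1], pairs[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(pairs)))
  # the clock limit: cv -> 0 pins every rate at the mean
  gs0 <- assign_lengths(sim, m, 1e-4)
  for (v in seq_len(gs0$n)) {
    p <- gs0$parent[v]
    if (is.na(p)) next
    span <- sim$time[p] - sim$time[v]
    if (span < 1e-6) next
    expect_equal(gs0$edge_length[v] / span, m, tolerance = 0.01)
  }
})

test_that("sequence simulation: zero lengths copy the root, pseudogene
           branches accumulate stops, gene leaves never hold stops", {
  cs <- codon_space()
  pi_u <- rep(1 / 64, 64)
  gm <- build_rate_matrix(2, 0.5, pi_u, "gene")
  pm <- build_rate_matrix(2, 1, pi_u, "pseudogene")
  gs <- toy_state("(A_1:1e-9,(B_1P:1e-9)PSG:1e-9);", stem_length = 1e-9)
  aln0 <- simulate_alignment(gs, gm, pm, 50, seed = 16)
  expect_equal(aln0$codons["A_1", ], aln0$codons["B_1P", ])
  # long branches
  gs2 <- toy_state("(A_1:2,(B_1P:2)PSG:0.5);", stem_length = 0.2)
  aln2 <- simulate_alignment(gs2, gm, pm, 400, seed = 17)
  stops <- cs$codons[cs$is_stop]
  expect_gt(sum(aln2$codons["B_1P", ] %in% stops), 0)
  expect_equal(sum(aln2$codons["A_1", ] %in% stops), 0L)
  # expected substitution flux on one branch: P(change) = 1 - sum pi_i P_ii
  gs3 <- toy_state("(A_1:0.5,B_1:1e-9);", stem_length = 1e-9)
  n <- 2000
  aln3 <- simulate_alignment(gs3, gm, pm, n, seed = 18)
  P <- transition_matrix(gm, 0.5, full64 = TRUE)
  pii <- pdlrs:::pi64(gm)
  p_change <- 1 - sum(pii * diag(P))
  obs <- mean(aln3$codons["A_1", ] != aln3$codons["B_1", ])
  expect_lt(abs(obs - p_change), 3 * sqrt(p_change * (1 - p_change) / n))
})

test_that("the synthetic study emits one family per grid cell under the
           stated conditions", {
  fams <- synthetic_study(seed = 2, n_codons = 9, max_attempts = 500)
  expect_length(fams, 25L)
  grid <- unique(data.frame(w = vapply(fams, `[[`, 0, "omega"),
                            k = vapply(fams, `[[`, 0, "kappa")))
  expect_equal(nrow(grid), 25L)
  for (f in fams) {
    lv <- which(f$state$is_leaf)
    expect_gte(sum(f$state$leaf_class[lv] == "pseudogene"), 1L)
    expect_gte(length(lv), 2L)
  }
})
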