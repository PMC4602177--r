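test_that("the posterior rejects invalid configurations and scales
           linearly in the data", {
  st <- three_species_tree()
  set.seed(23)
  fam <- sim_family(st, bd_rates(0.4, 0.4, 0.5), n_codons = 12)
  ctx <- make_context(fam$aln, st, n_discretization = 3)
  theta <- model_params(0.4, 0.4, 0.5, 1, 0.5)
  lp <- log_unnormalized_posterior(fam$gs, theta, ctx)
  expect_true(is.finite(lp$total))
  # break validity: relabel a pseudogene leaf as a gene
  bad <- fam$gs
  i <- which(bad$is_leaf & bad$leaf_class == "pseudogene")[1]
  if (!is.na(i)) {
    bad$leaf_class[i] <- "gene"
    expect_identical(log_unnormalized_posterior(bad, theta, ctx)$total,
                     -Inf)
  }
  # doubling the alignment doubles exactly the likelihood term (at fixed
  # codon frequencies; the context re-estimates them from counts)
  dbl <- codon_alignment(apply(fam$aln$codons[, rep(seq_len(12), 2)], 1,
                               paste, collapse = ""), fam$aln$ids)
  ll1 <- sequence_log_likelihood(fam$aln, fam$gs, fam$gm, fam$pm)
  ll2 <- sequence_log_likelihood(dbl, fam$gs, fam$gm, fam$pm)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-8)
})

test_that("proposal moves always produce valid states", {
  st <- four_species_tree()
  set.seed(24)
  for (k in 1:5) {
    fam <- sim_family(st, bd_rates(0.5, 0.4, 0.8), n_codons = 3,
                      min_leaves = 3)
    gs <- fam$gs
    for (it in 1:30) {
      pr <- switch(1 + it %% 3,
                   pdlrs:::propose_psi(gs),
                   pdlrs:::propose_nni(gs),
                   pdlrs:::propose_spr(gs))
      if (is.null(pr)) next
      v <- validate_state(pr$gs)
      expect_true(v$ok)
      expect_true(is.finite(pr$log_hr))
      gs <- pr$gs             # random walk across the state space
    }
    # leaf classification is preserved by every move
    expect_equal(sort(gs$label[gs$is_leaf]),
                 sort(fam$gs$label[fam$gs$is_leaf]))
  }
})

test_that("pseudogenization split/merge moves are reversible with
           matching menus", {
  gs <- toy_state("(A_1:1,((B_1P:1,C_1P:1):0.5)PSG:0.5);")
  set.seed(25)
  # down move must exist (split through the cherry), up move must not
  expect_length(pdlrs:::psi_merge_candidates(gs), 0L)
  expect_length(pdlrs:::psi_split_candidates(gs), 1L)
  repeat {
    pr <- pdlrs:::propose_psi(gs)
    if (!is.null(pr)) break
  }
  expect_equal(sum(pr$gs$is_psi), 2L)
  # and back
  expect_length(pdlrs:::psi_merge_candidates(pr$gs), 1L)
  expect_length(pdlrs:::psi_split_candidates(pr$gs), 0L)
})

test_that("NNI proposals on a four-leaf tree hit each neighbor equally", {
  gs <- toy_state("((A_1:1,B_1:1):0.5,(C_1:1,D_1:1):0.5);")
  cands <- pdlrs:::nni_candidates(gs)
  expect_gt(length(cands), 1)
  set.seed(26)
  tops <- replicate(400, {
    pr <- pdlrs:::propose_nni(gs)
    pdlrs:::canonical_topology(pr$gs)
  })
  tab <- table(tops)
  expect_equal(length(tab), length(unique(vapply(cands, function(mv)
    pdlrs:::canonical_topology(pdlrs:::apply_nni(gs, mv)), ""))))
  chi <- sum((tab - 400 / length(tab))^2 / (400 / length(tab)))
  expect_lt(chi, qchisq(1 - 1e-4, length(tab) - 1))
})

test_that("chains are deterministic given the seed and fixed-tree mode
           disables topology moves", {
  st <- three_species_tree()
  set.seed(27)
  fam <- sim_family(st, bd_rates(0.4, 0.4, 0.5), n_codons = 10)
  lm <- leaf_map_of(fam$gs)
  cfg <- chain_config(iterations = 400, burn_in = 100, thinning = 10,
                      seed = 5, n_discretization = 2, auto_tune = FALSE)
  tr1 <- run_chain(fam$aln, st, lm, config = cfg)
  tr2 <- run_chain(fam$aln, st, lm, config = cfg)
  expect_identical(tr1$samples, tr2$samples)
  cfg_f <- chain_config(iterations = 400, burn_in = 100, thinning = 10,
                        seed = 6, n_discretization = 2,
                        fixed_tree = fam$gs)
  trf <- run_chain(fam$aln, st, config = cfg_f)
  topo <- trf$acceptance[trf$acceptance$move == "topology", ]
  expect_equal(topo$proposed, 0)
  # the fixed suppressed topology never changes
  expect_equal(unique(vapply(trf$trees, pdlrs:::canonical_topology, "")),
               pdlrs:::canonical_topology(fam$gs))
})

test_that("the MAP tree selection prefers the higher posterior and breaks
           ties first-seen", {
  mk <- function(lp) structure(list(map = list(log_posterior = lp,
                                               state = lp, theta = NULL)),
                               class = "pdlrs_trace")
  expect_equal(select_map_tree(list(mk(-10)))$index, 1L)
  expect_equal(select_map_tree(list(mk(-10), mk(-2), mk(-5)))$index, 2L)
  expect_equal(select_map_tree(list(mk(-3), mk(-3)))$index, 1L)
  expect_error(select_map_tree(list()), "no traces")
})
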