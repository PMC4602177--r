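# a 6-leaf caterpillar with four pseudogene leaves, used across tests
caterpillar <- function() {
  toy_state(paste0("(A_1:1,(B_1:1,(C_1P:1,(D_1P:1,",
                   "(E_1P:1,F_1P:1):1):1):1):1);"))
}

test_that("edge distance: identity, adjacency, and BFS oracle agreement", {
  gs <- caterpillar()
  edges <- which(!is.na(gs$parent))
  e1 <- edges[1]
  expect_equal(edge_distance(gs, e1, e1), 0L)
  # adjacent edges share exactly one vertex
  ch <- gs$children[[gs$children[[gs$root]][1]]][1]
  par_edge <- gs$children[[gs$root]][1]
  expect_equal(edge_distance(gs, par_edge, ch), 1L)
  for (a in edges) for (b in edges) {
    expect_equal(edge_distance(gs, a, b), edge_distance_bfs(gs, a, b))
  }
})

test_that("roof/shade relations partition the configuration edges", {
  # config A: one early vertex above the whole pseudogene clade
  a_gs <- toy_state(paste0("(A_1:1,(B_1:1,((C_1P:1,(D_1P:1,",
                           "(E_1P:1,F_1P:1):1):1):0.5)PSG:0.5):1);"))
  # config B: vertices further down (C alone; D+(E,F) clade)
  b_gs <- toy_state(paste0("(A_1:1,(B_1:1,((C_1P:0.5)PSG:0.5,((D_1P:1,",
                           "(E_1P:1,F_1P:1):1):0.5)PSG:0.5):1):1);"))
  a <- psi_configuration(a_gs)
  b <- psi_configuration(b_gs)
  expect_identical(a$topology, b$topology)
  rel <- roofs_and_shades(a, b)
  expect_length(rel, 1L)                 # one roof covering both B edges
  expect_equal(rel[[1]]$roof_set, 1L)
  expect_length(rel[[1]]$shade, 2L)
  # every configuration edge appears exactly once across relations
  n_cfg <- length(a$edges) + length(b$edges)
  n_in_rel <- sum(vapply(rel, function(r)
    1L + length(r$shade), 1L))
  expect_equal(n_in_rel, n_cfg)
  # identical configurations: every edge roofs itself at distance zero
  rel0 <- roofs_and_shades(a, a)
  expect_length(rel0, length(a$edges))
  expect_true(all(vapply(rel0, function(r)
    identical(r$shade, r$roof), TRUE)))
  expect_equal(topological_distance(a, a), c(D_a = 0, D_m = 0))
})

test_that("the worked six-leaf example reproduces the two-roof arithmetic", {
  # roof 1 shades two edges at distances {1, 1}; roof 2 shades three at
  # {1, 2, 2}: D_a = ((1+1)/2 + (1+2+2)/3)/2, D_m = max(1, 2)
  gs_a <- toy_state(paste0(
    "(((A_1P:1,B_1P:1):0.5)PSG:0.5,",
    "((C_1P:1,(D_1P:1,(E_1P:1,F_1P:1):1):1):0.5)PSG:0.5);"))
  gs_b <- toy_state(paste0(
    "(((A_1P:0.5)PSG:0.5,(B_1P:0.5)PSG:0.5):1,",
    "((C_1P:0.5)PSG:0.5,((D_1P:0.5)PSG:0.5,",
    "((E_1P:1,F_1P:1):0.5)PSG:0.5):1):1);"))
  a <- psi_configuration(gs_a)
  b <- psi_configuration(gs_b)
  rel <- roofs_and_shades(a, b)
  expect_length(rel, 2L)
  d <- topological_distance(a, b)
  expect_equal(unname(d["D_a"]), ((1 + 1) / 2 + (1 + 2 + 2) / 3) / 2)
  expect_equal(unname(d["D_m"]), max(max(1, 1), max(1, 2, 2)))
  # symmetry under swapping the two configurations
  expect_equal(topological_distance(b, a), d)
  # D_a never exceeds D_m
  expect_lte(d[["D_a"]], d[["D_m"]])
})

test_that("temporal distances difference origin times and scale linearly", {
  gs_a <- toy_state("(A_1:1,((B_1P:1,C_1P:1):0.5)PSG:0.5);")
  gs_b <- toy_state("(A_1:1,((B_1P:0.5)PSG:0.5,(C_1P:0.5)PSG:0.5):1);")
  ta <- rep(NA_real_, gs_a$n); ta[gs_a$is_psi] <- 0.5
  tb <- rep(NA_real_, gs_b$n); tb[gs_b$is_psi] <- c(0.3, 0.2)
  a <- psi_configuration(gs_a, ta)
  b <- psi_configuration(gs_b, tb)
  tt <- temporal_distance(a, b)
  expect_equal(unname(tt["T_a"]), mean(c(0.2, 0.3)))
  expect_equal(unname(tt["T_m"]), 0.3)
  # identical configurations and times
  expect_equal(temporal_distance(a, a), c(T_a = 0, T_m = 0))
  # scale equivariance
  a2 <- psi_configuration(gs_a, ta * 3)
  b2 <- psi_configuration(gs_b, tb * 3)
  expect_equal(temporal_distance(a2, b2), 3 * tt, tolerance = 1e-12)
})

test_that("posterior summaries weight means and track maxima", {
  truth <- psi_configuration(
    toy_state("(A_1:1,((B_1P:1,C_1P:1):0.5)PSG:0.5);"))
  same <- psi_configuration(
    toy_state("(A_1:1,((B_1P:1,C_1P:1):0.5)PSG:0.5);"))
  far <- psi_configuration(
    toy_state("(A_1:1,((B_1P:0.5)PSG:0.5,(C_1P:0.5)PSG:0.5):1);"))
  d_far <- topological_distance(truth, far)
  s <- posterior_summaries(truth, list(same, far))
  expect_equal(s$E_Da, d_far[["D_a"]] / 2)
  expect_equal(s$M_Da, d_far[["D_a"]])
  expect_lte(s$E_Da, s$M_Da)
  expect_lte(s$E_Dm, s$M_Dm)
  # posterior concentrated on the truth
  s0 <- posterior_summaries(truth, list(same, same))
  expect_equal(unlist(s0[c("E_Da", "M_Da", "E_Dm", "M_Dm")]),
               c(E_Da = 0, M_Da = 0, E_Dm = 0, M_Dm = 0))
  # a sample with a different suppressed topology is excluded and counted
  other <- psi_configuration(
    toy_state("(B_1P:1,((A_1:1,C_1P:1):0.5)PSG:0.5);",
              stem_length = 0.3))
  expect_error(posterior_summaries(truth, list(other)), "no comparable")
  s1 <- posterior_summaries(truth, list(same, other))
  expect_equal(s1$n_excluded, 1L)
})
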