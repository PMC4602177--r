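test_that("an event-free single-species family reduces to the induced
           length density over the stem", {
  # species tree: one leaf below a degree-one root at time 1.3
  st <- structure(list(parent = c(2L, NA_integer_),
                       children = list(integer(0), 1L),
                       time = c(0, 1.3), is_leaf = c(TRUE, FALSE),
                       label = c("A", NA), root = 2L, n_vertices = 2L),
                  class = "dated_species_tree")
  dsp <- discretize(st, n_points = 5)
  gs <- pdlrs:::new_gene_tree_state(
    parent = c(2L, NA_integer_), children = list(integer(0), 1L),
    edge_length = c(1.1, NA), is_psi = c(FALSE, FALSE),
    label = c("A_1", NA), leaf_species = c("A", NA),
    leaf_class = c("gene", NA))
  theta <- model_params(0, 0, 0, rate_mean = 1, rate_cv = 0.6)
  lp <- gene_tree_log_prior(gs, theta, dsp)
  expect_equal(lp, log(pdlrs:::glen_density(1.1, 1.3, theta)),
               tolerance = 1e-9)
})

test_that("the prior density is positive for valid states and symmetric
           under child relabeling", {
  st <- three_species_tree()
  dsp <- discretize(st, n_points = 3)
  theta <- model_params(0.4, 0.4, 0.5, 1, 0.5)
  gs <- toy_state("((A_1:1,B_1:1):1,(C_1P:1)PSG:1);")
  lp <- gene_tree_log_prior(gs, theta, dsp)
  expect_true(is.finite(lp))
  # swap children at both internal vertices
  gs2 <- toy_state("((C_1P:1)PSG:1,(B_1:1,A_1:1):1);")
  expect_equal(gene_tree_log_prior(gs2, theta, dsp), lp, tolerance = 1e-10)
})

test_that("with psi = 0 and no pseudogenization vertices the prior matches
           an independently coded duplication-loss DP", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  st <- three_species_tree()
  dsp <- discretize(st, n_points = 3)
  for (k in 1:6) {
    theta <- model_params(runif(1, 0.1, 1), runif(1, 0.1, 1), 0,
                          runif(1, 0.5, 1.5), runif(1, 0.3, 0.9))
    fam <- sim_family(st, bd_rates(theta$delta, theta$mu, 0),
                      rate_mean = theta$rate_mean,
                      rate_cv = theta$rate_cv,
                      n_codons = 3, need_pseudo = FALSE)
    lp <- gene_tree_log_prior(fam$gs, theta, dsp)
    lo <- dlrs_prior_oracle(fam$gs, theta, dsp)
    expect_equal(lp, lo, tolerance = 1e-8)
  }
})

test_that("the cherry-duplication prior matches direct numerical
           integration over the duplication time", {
  skip_if_not_installed("deSolve")
  # two-species host; gene tree: two copies in species A only
  st <- two_species_tree(t_spec = 1, stem = 0.5)
  theta <- model_params(0.6, 0.4, 0, 1, 0.5)
  gs <- toy_state("(A_1:0.5,A_2:0.8);", stem_length = 0.4)
  lens <- c(A_1 = 0.5, A_2 = 0.8, stem = 0.4)
  # continuous-time formula: eps/p11 from deSolve on a fine grid
  delta <- theta$delta; mu <- theta$mu
  f <- function(t, y, parms)
    list(c(mu - (delta + mu) * y[1] + delta * y[1]^2, y[1]))
  # extinction and its time-integral on the leaf edges (E(0) = 0) and on
  # the stem, where a lineage at the speciation dies only if both copies
  # do: E_stem(1) = E_edge(1)^2
  tg1 <- seq(0, 1, length.out = 2001)
  s1 <- deSolve::lsoda(c(E = 0, I = 0), tg1, f, rtol = 1e-11, atol = 1e-13)
  E1 <- approxfun(tg1, s1[, "E"])
  I1 <- approxfun(tg1, s1[, "I"])
  tg2 <- seq(1, 1.5, length.out = 1001)
  s2 <- deSolve::lsoda(c(E = E1(1)^2, I = 0), tg2 - 1, f,
                       rtol = 1e-11, atol = 1e-13)
  E2 <- approxfun(tg2, s2[, "E"])
  I2 <- approxfun(tg2, s2[, "I"])           # int_1^t E_stem ds
  Iall <- function(t) if (t <= 1) I1(t) else I1(1) + I2(t)
  p11f <- function(t_hi, t_lo)              # 1-to-1 between times
    exp(2 * delta * (Iall(t_hi) - Iall(t_lo)) -
          (delta + mu) * (t_hi - t_lo))
  gshape <- 1 / theta$rate_cv^2
  gscale <- theta$rate_mean * theta$rate_cv^2
  g <- function(l, t) dgamma(l / t, gshape, scale = gscale) / t
  integrand <- function(tau) {
    # duplication at time tau on the A lineage; below the speciation the
    # root path pays the B-side extinction once, above it each child
    # crosses the speciation and pays it separately
    side_child <- if (tau > 1) E1(1) else 1
    side_root <- if (tau <= 1) E1(1) else 1
    child <- function(l) p11f(tau, 0) * side_child * g(l, tau)
    root_part <- p11f(1.5, tau) * side_root * g(lens["stem"], 1.5 - tau)
    2 * delta * root_part * child(lens["A_1"]) * child(lens["A_2"])
  }
  taus <- seq(1e-4, 1.5 - 1e-4, length.out = 3000)
  vals <- vapply(taus, integrand, 0)
  direct <- sum(vals) * (taus[2] - taus[1])
  # DP side, at two discretization densities: error shrinks
  lp1 <- gene_tree_log_prior(gs, theta, discretize(st, n_points = 8))
  lp2 <- gene_tree_log_prior(gs, theta, discretize(st, n_points = 32))
  err1 <- abs(exp(lp1) - direct)
  err2 <- abs(exp(lp2) - direct)
  expect_lt(err2, err1)
  expect_lt(err2 / direct, 0.05)
})

test_that("refining the discretization is a Cauchy sequence and the prior
           integrates to one for forced topologies", {
  st <- three_species_tree()
  theta <- model_params(0.5, 0.5, 0.5, 1, 0.5)
  gs <- toy_state("((A_1:1,B_1:1):1,(C_1P:1)PSG:1);")
  lps <- vapply(c(2, 4, 8, 16), function(np)
    gene_tree_log_prior(gs, theta, discretize(st, n_points = np)), 0)
  d <- abs(diff(lps))
  expect_true(all(diff(d) < 0))
  # zero-rate single-copy family: density over lengths integrates to 1
  # (importance sampling with the exact generative density is exact)
  theta0 <- model_params(0, 0, 0, 1, 0.5)
  dsp <- discretize(st, n_points = 4)
  tpl <- pdlrs:::single_copy_state(st)
  spans <- pdlrs:::single_copy_spans(st)
  set.seed(31)
  vals <- replicate(200, {
    l <- pmax(rgamma(length(spans), shape = pdlrs:::gamma_shape(theta0),
                     scale = pdlrs:::gamma_scale(theta0)) * spans, 1e-10)
    g2 <- tpl
    g2$edge_length[!is.na(g2$edge_length)] <- l
    exp(gene_tree_log_prior(g2, theta0, dsp) -
          sum(log(pdlrs:::glen_density(l, spans, theta0))))
  })
  expect_equal(mean(vals), 1, tolerance = 1e-6)
})

test_that("raising the pseudogenization rate favors configurations with
           pseudogenization vertices", {
  st <- three_species_tree()
  dsp <- discretize(st, n_points = 4)
  gs_psi <- toy_state("((A_1:1,B_1:1):1,(C_1P:1)PSG:1);")
  gs_none <- toy_state("((A_1:1,B_1:1):1,C_1:2);")
  # at small rates the single-event factor (linear in psi) dominates the
  # exponential 1-to-1 penalty along gene lineages
  lp_psi <- vapply(c(0.02, 0.05, 0.1, 0.2), function(p)
    gene_tree_log_prior(gs_psi, model_params(0.4, 0.4, p, 1, 0.5), dsp), 0)
  lp_none <- vapply(c(0.02, 0.05, 0.1, 0.2), function(p)
    gene_tree_log_prior(gs_none, model_params(0.4, 0.4, p, 1, 0.5), dsp), 0)
  expect_true(all(diff(lp_psi) > 0))
  expect_true(all(diff(lp_none) < 0))
})

test_that("the prior is consistent with forward-simulation frequencies", {
  st <- two_species_tree(1, 0.5)
  theta <- model_params(0.3, 0.3, 0.2, 1, 0.5)
  chk <- simulation_consistency_check(theta, st, n_reps = 3000,
                                      n_draws = 300, seed = 5,
                                      n_points = 12)
  expect_lt(abs(chk$z), 3.5)
  # no events possible: the single-copy topology has probability one
  theta0 <- model_params(0, 0, 0, 1, 0.5)
  chk0 <- simulation_consistency_check(theta0, st, n_reps = 200,
                                       n_draws = 100, seed = 6,
                                       n_points = 8)
  expect_equal(chk0$p_sim, 1)
  expect_equal(chk0$p_dp, 1, tolerance = 1e-6)
})
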