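test_that("pure-death extinction matches the closed form", {
  st <- two_species_tree(t_spec = 1, stem = 0.5)
  dsp <- discretize(st, n_points = 6)
  mu <- 0.8
  bd <- extinction_tables(dsp, bd_rates(0, mu, 0))
  # below the speciation: eps = 1 - exp(-mu t); at the speciation both
  # copies must die; on the stem the pure-death flow continues from there
  spec <- st$children[[st$root]][1]
  E_spec <- (1 - exp(-mu * 1))^2
  for (i in seq_len(dsp$n_points)) {
    t <- dsp$pt_time[i]
    expected <- if (t < 1) 1 - exp(-mu * t)
      else if (i == dsp$vertex_point[spec]) E_spec
      else 1 - (1 - E_spec) * exp(-mu * (t - 1))
    expect_equal(bd$eps_g[i], expected, tolerance = 1e-8)
    expect_equal(bd$eps_p[i], expected, tolerance = 1e-8)
  }
})

test_that("nothing dies when the loss rate is zero", {
  dsp <- discretize(three_species_tree(), n_points = 4)
  bd <- extinction_tables(dsp, bd_rates(1.3, 0, 0.7))
  expect_equal(max(bd$eps_g), 0)
  expect_equal(max(bd$eps_p), 0)
})

test_that("negative rates are rejected", {
  expect_error(bd_rates(-1, 0, 0), "nonnegative")
})

test_that("gene and pseudogene extinction coincide (conversion is neutral
           for survival) while the machinery stays two-type", {
  dsp <- discretize(three_species_tree(), n_points = 5)
  set.seed(42)
  for (k in 1:5) {
    r <- bd_rates(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    bd <- extinction_tables(dsp, r)
    expect_equal(bd$eps_g, bd$eps_p, tolerance = 1e-9)
  }
})

test_that("1-to-1 probabilities: identity, exponential limit, composition,
           monotonicity", {
  st <- two_species_tree(1, 1)
  dsp <- discretize(st, n_points = 8)
  mu <- 0.6
  bd0 <- extinction_tables(dsp, bd_rates(0, mu, 0))
  leaf <- dsp$vertex_point[which(dsp$st$label == "A")]
  expect_equal(p11(dsp, bd0, leaf, leaf, "gene"), 1)
  # delta = psi = 0: pure exponential survival of the tracked lineage
  x <- dsp$pt_parent[dsp$pt_parent[leaf]]
  t_xy <- time_between(dsp, x, leaf)
  expect_equal(p11(dsp, bd0, x, leaf, "gene"), exp(-mu * t_xy),
               tolerance = 1e-9)
  # composition along a path
  bd <- extinction_tables(dsp, bd_rates(0.9, 0.7, 0.4))
  y <- leaf
  m <- dsp$pt_parent[y]
  x <- dsp$pt_parent[m]
  expect_equal(p11(dsp, bd, x, y, "gene"),
               p11(dsp, bd, x, m, "gene") * p11(dsp, bd, m, y, "gene"),
               tolerance = 1e-12)
  # monotone non-increasing in t(x, y) when mu > 0
  vals <- numeric(0)
  z <- leaf
  while (!is.na(dsp$pt_parent[z])) {
    vals <- c(vals, p11(dsp, bd, dsp$pt_parent[z], leaf, "gene"))
    z <- dsp$pt_parent[z]
  }
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("Monte-Carlo oracle sanity: no deaths, pure death closed form", {
  st <- two_species_tree(1, 1)
  basal <- st$children[[st$root]][1]
  r0 <- mc_oracle(st, bd_rates(0.5, 0, 0.2),
                  start = list(edge = basal, time = st$time[st$root]),
                  n_reps = 2000, seed = 11)
  expect_equal(unname(r0$extinction["estimate"]), 0)
  # pure death over the stem + tree: extinction of a lineage over time 1
  # on the A edge alone
  leafA <- which(st$label == "A")
  r1 <- mc_oracle(st, bd_rates(0, 1, 0),
                  start = list(edge = leafA, time = 1),
                  n_reps = 20000, seed = 12)
  expect_lt(abs(r1$extinction["estimate"] - (1 - exp(-1))),
            3 * r1$extinction["se"])
})

test_that("ODE tables agree with forward simulation on random rates", {
  st <- two_species_tree(1, 0.8)
  dsp <- discretize(st, n_points = 5)
  leafA <- which(st$label == "A")
  set.seed(99)
  for (k in 1:3) {
    r <- bd_rates(runif(1, 0.2, 1.5), runif(1, 0.2, 1.5),
                  runif(1, 0.2, 1.5))
    bd <- extinction_tables(dsp, r)
    # extinction from the top of the A edge
    topA <- dsp$pt_vertex
    x <- dsp$vertex_point[leafA]
    for (j in 1:5) x <- dsp$pt_parent[x]   # top interior point of A edge
    mc <- mc_oracle(st, r, start = list(edge = leafA, time = dsp$pt_time[x]),
                    n_reps = 3e4, seed = 100 + k)
    se <- max(mc$extinction["se"], 1e-4)
    expect_lt(abs(mc$extinction["estimate"] - bd$eps_g[x]), 3.5 * se)
    # 1-to-1 from x down to the leaf end of the slice chain
    y <- dsp$vertex_point[leafA]
    mc2 <- mc_oracle(st, r, start = list(edge = leafA, time = dsp$pt_time[x]),
                     n_reps = 3e4, seed = 200 + k,
                     target = list(time = dsp$pt_time[y] + 1e-9,
                                   type = "gene"))
    se2 <- max(mc2$one_to_one["se"], 1e-4)
    expect_lt(abs(mc2$one_to_one["estimate"] - p11(dsp, bd, x, y, "gene")),
              3.5 * se2)
  }
})
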