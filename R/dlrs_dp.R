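#' Compound model parameters
#'
#' @param delta,mu,psi duplication, loss and pseudogenization rates
#' @param rate_mean,rate_cv mean and coefficient of variation of the
#'   gamma distribution of per-edge substitution rates (relaxed clock);
#'   the gamma shape is \code{1/cv^2} and the scale \code{mean * cv^2}
#' @param kappa transition/transversion ratio of the codon models
#' @param omega dN/dS ratio of the gene-mode codon model (pseudogene mode
#'   is neutral, omega = 1)
#' @return A list of class \code{model_params}.
#' @export
model_params <- function(delta, mu, psi, rate_mean, rate_cv,
                         kappa = 2, omega = 0.5) {
  stopifnot(delta >= 0, mu >= 0, psi >= 0, rate_mean > 0, rate_cv > 0,
            kappa >= 0, omega >= 0)
  structure(list(delta = delta, mu = mu, psi = psi,
                 rate_mean = rate_mean, rate_cv = rate_cv,
                 kappa = kappa, omega = omega),
            class = "model_params")
}

gamma_shape <- function(theta) 1 / theta$rate_cv^2
gamma_scale <- function(theta) theta$rate_mean * theta$rate_cv^2

# edge-length density induced by the gamma rate density over a span t
glen_density <- function(l, t, theta) {
  dgamma(l / t, shape = gamma_shape(theta), scale = gamma_scale(theta)) / t
}

# precomputed point-level arrays shared by DP calls on one discretization
dp_point_arrays <- function(dsp) {
  n <- dsp$n_points
  kind <- integer(n)
  for (i in seq_len(n)) {
    v <- dsp$pt_vertex[i]
    kind[i] <- if (is.na(v)) 0L
      else if (v == dsp$st$root) 3L
      else if (dsp$st$is_leaf[v]) 2L else 1L
  }
  sibling <- rep(-1L, n)
  side <- rep(-1L, n)
  for (x in seq_len(n)) {
    if (kind[x] == 1L) {
      kids <- dsp$pt_children[[x]]
      stopifnot(length(kids) == 2L)
      sibling[kids[1]] <- kids[2] - 1L
      sibling[kids[2]] <- kids[1] - 1L
      side[kids[1]] <- 0L
      side[kids[2]] <- 1L
    }
  }
  wt <- ifelse(kind == 0L, dsp$slice_dt, 0)
  wt[is.na(wt)] <- 0
  list(parent = ifelse(is.na(dsp$pt_parent), -1L, dsp$pt_parent - 1L),
       time = dsp$pt_time, kind = kind, wt = wt,
       sibling = sibling, side = side)
}

# gene-tree arrays for the DP (0-based); postorder excludes the
# degree-one gene-tree root, whose single child carries the stem edge.
# The topology-dependent parts are cached on the state object (length
# moves reuse the same structure with one length changed).
dp_gene_arrays <- function(gs, dsp) {
  topo <- attr(gs, "dp_topo")
  if (is.null(topo)) {
    sig <- sigma(gs, dsp$st)
    n <- gs$n
    child1 <- child2 <- rep(-1L, n)
    for (u in seq_len(n)) {
      kids <- gs$children[[u]]
      if (length(kids) >= 1L) child1[u] <- kids[1] - 1L
      if (length(kids) == 2L) child2[u] <- kids[2] - 1L
    }
    post <- setdiff(gene_postorder(gs), gs$root)
    em <- edge_mode_pseudo(gs)
    topo <- list(post = post - 1L, child1 = child1, child2 = child2,
                 is_leaf = gs$is_leaf, is_psi = gs$is_psi,
                 edge_mode = ifelse(is.na(em), 0L, as.integer(em)),
                 sigma_pt = dsp$vertex_point[sig] - 1L,
                 root_child = gs$children[[gs$root]][1] - 1L)
  }
  c(topo, list(elen = ifelse(is.na(gs$edge_length), 0, gs$edge_length)))
}

# attach the cached topology-dependent structures to a state (invalidated
# by any structural edit, which builds a fresh object)
with_dp_cache <- function(gs, dsp) {
  if (is.null(attr(gs, "dp_topo"))) {
    ga <- dp_gene_arrays(gs, dsp)
    attr(gs, "dp_topo") <- ga[setdiff(names(ga), "elen")]
    attr(gs, "postorder") <- gene_postorder(gs)
    attr(gs, "edge_mode") <- edge_mode_pseudo(gs)
  }
  gs
}

#' Gene-tree prior under the pseudogenization-duplication-loss model
#'
#' Dynamic program over (species-tree point, species-tree point, gene-tree
#' vertex): the probability density that a single gene lineage starting at
#' a point generates the observed gene tree with its edge lengths, with
#' the vertex's event at a second point.  Leaves anchor at their species
#' leaf; speciation vertices multiply left/right descendant sums;
#' duplication events at interior points carry rate \code{2 delta} and the
#' slice width; pseudogenization (degree-two) vertices carry rate
#' \code{psi} and the slice width; path extension multiplies per-slice
#' 1-to-1 factors, off-path extinction at speciations, and exchanges the
#' edge-length density for the one over the longer span.  The returned
#' value is the log of the sum over placements of the root's single child
#' below the degree-one species-tree root.
#'
#' @param gs a valid \code{gene_tree_state}
#' @param theta a \code{model_params}
#' @param dsp a \code{discretized_species_tree}
#' @param bd matching \code{bd_tables} (computed when NULL)
#' @param return_tables keep the per-vertex DP tables (needed for
#'   realization sampling)
#' @return If \code{return_tables} is FALSE, the log prior density; else a
#'   list with \code{log_prior}, \code{tables}, \code{logscale}.
#' @export
gene_tree_log_prior <- function(gs, theta, dsp, bd = NULL,
                                return_tables = FALSE) {
  if (is.null(bd))
    bd <- extinction_tables(dsp, bd_rates(theta$delta, theta$mu, theta$psi))
  pa <- if (!is.null(dsp$dp_arrays)) dsp$dp_arrays else dp_point_arrays(dsp)
  ga <- dp_gene_arrays(gs, dsp)
  res <- dp_stable_cpp(pa$parent, pa$time, pa$kind, pa$wt, pa$sibling,
                       pa$side, bd$eps_arc_g, bd$eps_arc_p,
                       bd$p11_g, bd$p11_p,
                       ga$post, ga$child1, ga$child2, ga$is_leaf, ga$is_psi,
                       ga$edge_mode, ga$elen, ga$sigma_pt, ga$root_child,
                       dsp$vertex_point[dsp$st$root] - 1L,
                       theta$delta, theta$psi,
                       gamma_shape(theta), gamma_scale(theta),
                       return_tables)
  if (!return_tables) return(res$log_prior)
  res
}

#' Consistency of the gene-tree prior with the forward process
#'
#' Estimates the probability of the single-copy, event-free family (one
#' gene leaf per species, no duplications and no pseudogenizations) in two
#' independent ways: by forward simulation frequency, and from the dynamic
#' program via importance sampling over edge lengths (for that family the
#' vertex times coincide with the speciation times, so the generative
#' length density factorizes over edges), and reports the z-score of the
#' disagreement.
#'
#' @param theta a \code{model_params}
#' @param st a small \code{dated_species_tree}
#' @param n_reps forward-simulation replicates
#' @param n_draws importance-sampling draws for the DP-side estimate
#' @param seed RNG seed
#' @param n_points discretization points per edge (denser grids tighten
#'   the DP-side estimate)
#' @return List with \code{p_sim}, \code{p_dp}, standard errors and
#'   \code{z}.
#' @export
simulation_consistency_check <- function(theta, st, n_reps = 2000,
                                         n_draws = 400, seed = 1,
                                         n_points = NULL) {
  set.seed(seed)
  rates <- bd_rates(theta$delta, theta$mu, theta$psi)
  hit <- 0L
  nsp <- sum(st$is_leaf)
  for (r in seq_len(n_reps)) {
    sim <- simulate_gene_tree(st, rates)
    if (sim$extinct) next
    gs <- sim$state
    ok <- sum(gs$is_leaf) == nsp && !any(gs$is_psi) &&
      !anyDuplicated(gs$leaf_species[gs$is_leaf])
    if (ok) hit <- hit + 1L
  }
  p_sim <- hit / n_reps
  se_sim <- sqrt(p_sim * (1 - p_sim) / n_reps)
  # DP side: build the single-copy state; importance-sample lengths from
  # the generative density at the known (speciation) spans
  dsp <- discretize(st, n_points = n_points)
  bd <- extinction_tables(dsp, rates)
  template <- single_copy_state(st)
  spans <- single_copy_spans(st)
  vals <- numeric(n_draws)
  for (k in seq_len(n_draws)) {
    r <- rgamma(length(spans), shape = gamma_shape(theta),
                scale = gamma_scale(theta))
    l <- pmax(r * spans, 1e-12)
    gs <- template
    gs$edge_length[!is.na(gs$edge_length)] <- l
    lp <- gene_tree_log_prior(gs, theta, dsp, bd)
    lq <- sum(log(glen_density(l, spans, theta)))
    vals[k] <- exp(lp - lq)
  }
  p_dp <- mean(vals)
  se_dp <- sd(vals) / sqrt(n_draws)
  z <- (p_sim - p_dp) / sqrt(se_sim^2 + se_dp^2 + 1e-300)
  list(p_sim = p_sim, se_sim = se_sim, p_dp = p_dp, se_dp = se_dp, z = z)
}

# gene-tree state with exactly one gene leaf per species, mirroring the
# species-tree topology (edge lengths unset)
single_copy_state <- function(st) {
  n <- st$n_vertices
  parent <- st$parent
  children <- st$children
  label <- ifelse(st$is_leaf, paste0(st$label, "_1"), NA_character_)
  leaf_species <- ifelse(st$is_leaf, st$label, NA_character_)
  leaf_class <- ifelse(st$is_leaf, "gene", NA_character_)
  elen <- ifelse(is.na(parent), NA_real_, 1.0)
  new_gene_tree_state(parent, children, elen,
                      rep(FALSE, n), label, leaf_species, leaf_class)
}

# edge time spans of the single-copy state, ordered as the non-NA
# edge-length slots of single_copy_state()
single_copy_spans <- function(st) {
  idx <- which(!is.na(st$parent))
  st$time[st$parent[idx]] - st$time[idx]
}
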