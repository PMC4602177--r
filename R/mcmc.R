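#' Priors on model parameters
#'
#' Independent priors: exponential(rate 0.1) on the duplication, loss and
#' pseudogenization rates, log-normal(0, 1) on the edge-rate mean,
#' exponential(1) on the edge-rate coefficient of variation, and uniform
#' on the proposal truncation boxes for omega ([0, 10]) and kappa
#' ([0, 100]).  Every component can be replaced by a
#' \code{list(log_d = function(x) ..., lower =, upper =)} entry.
#'
#' @return Named list of prior specifications.
#' @export
default_priors <- function() {
  expo <- function(rate) list(log_d = function(x) dexp(x, rate, log = TRUE),
                              lower = 0, upper = Inf)
  list(delta = expo(0.1), mu = expo(0.1), psi = expo(0.1),
       rate_mean = list(log_d = function(x) dlnorm(x, 0, 1, log = TRUE),
                        lower = 1e-8, upper = Inf),
       rate_cv = list(log_d = function(x) dexp(x, 1, log = TRUE),
                      lower = 1e-8, upper = Inf),
       omega = list(log_d = function(x) dunif(x, 0, 10, log = TRUE),
                    lower = 0, upper = 10),
       kappa = list(log_d = function(x) dunif(x, 0, 100, log = TRUE),
                    lower = 0, upper = 100))
}

log_theta_prior <- function(theta, priors = default_priors()) {
  tot <- 0
  for (nm in names(priors)) {
    x <- theta[[nm]]
    p <- priors[[nm]]
    if (x < p$lower || x > p$upper) return(-Inf)
    tot <- tot + p$log_d(x)
  }
  tot
}

#' Model context for repeated posterior evaluations
#'
#' Bundles the alignment (with compressed site patterns), the discretized
#' species tree and the shared empirical codon frequencies.
#'
#' @param aln a \code{codon_alignment}
#' @param st a \code{dated_species_tree}
#' @param n_discretization interior points per species-tree edge
#'   (NULL = duration-proportional default)
#' @return A list of class \code{model_context}.
#' @export
make_context <- function(aln, st, n_discretization = NULL) {
  cs <- codon_space()
  dsp <- discretize(st, n_points = n_discretization)
  structure(list(aln = aln, st = st, dsp = dsp, cs = cs,
                 patterns = compress_patterns(aln, cs),
                 pi = estimate_frequencies(aln, cs)),
            class = "model_context")
}

new_eval_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$bd_key <- ""
  e$model_key <- ""
  e$Pcache <- new.env(parent = emptyenv())
  e
}

# two-slot memo: a rejected rate proposal must not force rebuilding the
# current state's tables on the next evaluation
cache_bd <- function(cache, ctx, theta) {
  key <- paste(theta$delta, theta$mu, theta$psi)
  if (!identical(cache$bd_key, key)) {
    old <- cache$bd
    old_key <- cache$bd_key
    if (identical(cache$bd_prev_key, key)) {
      cache$bd <- cache$bd_prev
    } else {
      cache$bd <- extinction_tables(ctx$dsp,
                                    bd_rates(theta$delta, theta$mu,
                                             theta$psi))
    }
    cache$bd_prev <- old
    cache$bd_prev_key <- old_key
    cache$bd_key <- key
  }
  cache$bd
}

cache_models <- function(cache, ctx, theta) {
  drop_keys <- function(prefix) {
    keys <- grep(prefix, ls(cache$Pcache), value = TRUE)
    if (length(keys)) rm(list = keys, envir = cache$Pcache)
  }
  gkey <- paste(theta$kappa, theta$omega)
  if (!identical(cache$model_key, gkey)) {
    old <- cache$gene_model
    old_key <- cache$model_key
    if (identical(cache$gene_prev_key, gkey)) {
      cache$gene_model <- cache$gene_prev
    } else {
      cache$gene_model <- build_rate_matrix(theta$kappa, theta$omega,
                                            ctx$pi, "gene", ctx$cs)
    }
    cache$gene_prev <- old
    cache$gene_prev_key <- old_key
    cache$model_key <- gkey
    drop_keys("^g")
  }
  # the pseudogene model is neutral (omega fixed at 1): kappa-only key,
  # so omega moves keep its spectral decomposition and cached matrices
  pkey <- paste(theta$kappa)
  if (!identical(cache$pseudo_key, pkey)) {
    old <- cache$pseudo_model
    old_key <- cache$pseudo_key
    if (identical(cache$pseudo_prev_key, pkey)) {
      cache$pseudo_model <- cache$pseudo_prev
    } else {
      cache$pseudo_model <- build_rate_matrix(theta$kappa, 1, ctx$pi,
                                              "pseudogene", ctx$cs)
    }
    cache$pseudo_prev <- old
    cache$pseudo_prev_key <- old_key
    cache$pseudo_key <- pkey
    drop_keys("^p")
  }
  list(gene = cache$gene_model, pseudo = cache$pseudo_model,
       Pcache = cache$Pcache)
}

#' Log unnormalized posterior of a chain state
#'
#' Sum of the pruning sequence log-likelihood, the gene-tree prior under
#' the pseudogenization-duplication-loss process, and the parameter prior;
#' an invalid pseudogenization configuration gives \code{-Inf}.
#'
#' @param gs a \code{gene_tree_state}
#' @param theta a \code{model_params}
#' @param ctx a \code{model_context}
#' @param priors prior list as \code{\link{default_priors}}
#' @param use_likelihood,use_tree_prior include the respective factors
#'   (both TRUE for the posterior; turning them off yields reference
#'   targets used by sampler validation)
#' @param cache optional evaluation cache (internal reuse across calls)
#' @param check_validity validate the state first (skipped by the sampler,
#'   whose proposals are valid by construction)
#' @return List with \code{total}, \code{log_likelihood},
#'   \code{log_tree_prior}, \code{log_theta_prior}.
#' @export
log_unnormalized_posterior <- function(gs, theta, ctx,
                                       priors = default_priors(),
                                       use_likelihood = TRUE,
                                       use_tree_prior = TRUE,
                                       cache = new_eval_cache(),
                                       check_validity = TRUE) {
  if (check_validity && !validate_state(gs)$ok)
    return(list(total = -Inf, log_likelihood = NA_real_,
                log_tree_prior = NA_real_, log_theta_prior = NA_real_))
  lp_theta <- log_theta_prior(theta, priors)
  ll <- 0; lp_tree <- 0
  if (is.finite(lp_theta)) {
    if (use_likelihood) {
      m <- cache_models(cache, ctx, theta)
      ll <- sequence_log_likelihood(ctx$aln, gs, m$gene, m$pseudo,
                                    patterns = ctx$patterns,
                                    Pcache = m$Pcache)
    }
    if (use_tree_prior) {
      bd <- cache_bd(cache, ctx, theta)
      lp_tree <- gene_tree_log_prior(gs, theta, ctx$dsp, bd)
    }
  }
  list(total = ll + lp_tree + lp_theta, log_likelihood = ll,
       log_tree_prior = lp_tree, log_theta_prior = lp_theta)
}

# ---- truncated-normal random walk ---------------------------------------

rtruncnorm1 <- function(mean, sd, lower, upper) {
  qnorm(runif(1, pnorm(lower, mean, sd), pnorm(upper, mean, sd)), mean, sd)
}

log_dtruncnorm <- function(x, mean, sd, lower, upper) {
  dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
}

# ---- mutable tree edits --------------------------------------------------

gs_mutable <- function(gs) {
  e <- new.env(parent = emptyenv())
  e$parent <- gs$parent; e$elen <- gs$edge_length; e$is_psi <- gs$is_psi
  e$label <- gs$label; e$species <- gs$leaf_species; e$class <- gs$leaf_class
  e$alive <- rep(TRUE, gs$n)
  e
}

# remove a vertex with exactly one live child, concatenating edge lengths
splice_out <- function(m, u) {
  ch <- which(m$alive & !is.na(m$parent) & m$parent == u)
  stopifnot(length(ch) == 1L)
  m$elen[ch] <- m$elen[ch] + m$elen[u]
  m$parent[ch] <- m$parent[u]
  m$alive[u] <- FALSE
  invisible(ch)
}

# insert a vertex on the edge above v at fraction frac from the top
insert_on_edge <- function(m, v, frac, is_psi) {
  L <- m$elen[v]
  j <- length(m$parent) + 1L
  m$parent <- c(m$parent, m$parent[v])
  m$elen <- c(m$elen, frac * L)
  m$is_psi <- c(m$is_psi, is_psi)
  m$label <- c(m$label, NA_character_)
  m$species <- c(m$species, NA_character_)
  m$class <- c(m$class, NA_character_)
  m$alive <- c(m$alive, TRUE)
  m$parent[v] <- j
  m$elen[v] <- (1 - frac) * L
  j
}

gs_freeze <- function(m) {
  keep <- which(m$alive)
  new_id <- match(seq_along(m$alive), keep)
  parent <- m$parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, new_id[parent])
  n <- length(keep)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) if (!is.na(parent[i]))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  new_gene_tree_state(parent, children, m$elen[keep], m$is_psi[keep],
                      m$label[keep], m$species[keep], m$class[keep])
}

# per-vertex subtree summaries used by topology-move legality rules
subtree_flags <- function(gs) {
  has_gene <- logical(gs$n); uncovered <- logical(gs$n)
  for (u in gene_postorder(gs)) {
    if (gs$is_leaf[u]) {
      has_gene[u] <- gs$leaf_class[u] == "gene"
      uncovered[u] <- gs$leaf_class[u] == "pseudogene"
    } else {
      kids <- gs$children[[u]]
      has_gene[u] <- any(has_gene[kids])
      uncovered[u] <- if (gs$is_psi[u]) FALSE else any(uncovered[kids])
    }
  }
  has_psi <- logical(gs$n)
  for (u in gene_postorder(gs)) {
    kids <- gs$children[[u]]
    has_psi[u] <- gs$is_psi[u] || (length(kids) > 0 && any(has_psi[kids]))
  }
  list(has_gene = has_gene, has_psi = has_psi, uncovered = uncovered)
}

# ---- pseudogenization-vertex moves (up merges / down splits) -------------

psi_merge_candidates <- function(gs) {
  which(vapply(seq_len(gs$n), function(w) {
    kids <- gs$children[[w]]
    !gs$is_psi[w] && !is.na(gs$parent[w]) && length(kids) == 2L &&
      all(gs$is_psi[kids])
  }, TRUE))
}

psi_split_candidates <- function(gs) {
  which(vapply(seq_len(gs$n), function(u) {
    if (!gs$is_psi[u]) return(FALSE)
    w <- gs$children[[u]][1]
    length(gs$children[[w]]) == 2L
  }, TRUE))
}

propose_psi <- function(gs) {
  up <- runif(1) < 0.5
  if (up) {
    cands <- psi_merge_candidates(gs)
    if (length(cands) == 0L) return(NULL)
    w <- if (length(cands) == 1L) cands else sample(cands, 1L)
    u12 <- gs$children[[w]]
    L_pw <- gs$edge_length[w]
    m <- gs_mutable(gs)
    c1 <- splice_out(m, u12[1])
    c2 <- splice_out(m, u12[2])
    B1 <- m$elen[c1]; B2 <- m$elen[c2]
    insert_on_edge(m, w, runif(1), TRUE)
    prop <- gs_freeze(m)
    log_hr <- log(length(cands)) - log(length(psi_split_candidates(prop))) +
      log(L_pw) - log(B1) - log(B2)
  } else {
    cands <- psi_split_candidates(gs)
    if (length(cands) == 0L) return(NULL)
    u <- if (length(cands) == 1L) cands else sample(cands, 1L)
    w <- gs$children[[u]][1]
    c12 <- gs$children[[w]]
    A <- gs$edge_length[u] + gs$edge_length[w]
    L1 <- gs$edge_length[c12[1]]; L2 <- gs$edge_length[c12[2]]
    m <- gs_mutable(gs)
    splice_out(m, u)
    insert_on_edge(m, c12[1], runif(1), TRUE)
    insert_on_edge(m, c12[2], runif(1), TRUE)
    prop <- gs_freeze(m)
    log_hr <- log(length(cands)) - log(length(psi_merge_candidates(prop))) +
      log(L1) + log(L2) - log(A)
  }
  list(gs = prop, log_hr = log_hr)
}

# ---- topology moves ------------------------------------------------------

# skeleton parent: first non-psi ancestor
skeleton_parent <- function(gs, v) {
  p <- gs$parent[v]
  while (!is.na(p) && gs$is_psi[p]) p <- gs$parent[p]
  p
}

nni_candidates <- function(gs, fl = subtree_flags(gs)) {
  mb <- mode_below(gs)
  out <- list()
  for (B in seq_len(gs$n)) {
    if (gs$is_psi[B] || gs$is_leaf[B] || B == gs$root) next
    A <- skeleton_parent(gs, B)
    if (is.na(A) || A == gs$root || length(gs$children[[A]]) != 2L) next
    # child pointer of A on the chain towards B
    z <- B
    while (gs$parent[z] != A) z <- gs$parent[z]
    cC <- setdiff(gs$children[[A]], z)
    for (cD in gs$children[[B]]) {
      ok_C <- (!fl$has_gene[cC] || !mb[B]) && (!fl$has_psi[cC] || !mb[B]) &&
        (!fl$uncovered[cC] || mb[B])
      ok_D <- (!fl$has_gene[cD] || !mb[A]) && (!fl$has_psi[cD] || !mb[A]) &&
        (!fl$uncovered[cD] || mb[A])
      if (ok_C && ok_D)
        out[[length(out) + 1L]] <- c(A = A, B = B, cC = cC, cD = cD)
    }
  }
  out
}

apply_nni <- function(gs, mv) {
  m <- gs_mutable(gs)
  m$parent[mv[["cC"]]] <- mv[["B"]]
  m$parent[mv[["cD"]]] <- mv[["A"]]
  gs_freeze(m)
}

propose_nni <- function(gs) {
  cands <- nni_candidates(gs)
  if (length(cands) == 0L) return(NULL)
  mv <- cands[[sample.int(length(cands), 1L)]]
  prop <- apply_nni(gs, mv)
  list(gs = prop,
       log_hr = log(length(cands)) - log(length(nni_candidates(prop))))
}

# SPR: prune the subtree hanging from vertex v (whose parent must be an
# ordinary binary vertex, which gets spliced out) and regraft it onto the
# edge above a target vertex at a uniform position.
spr_pairs <- function(gs, fl = subtree_flags(gs)) {
  mb <- mode_below(gs)
  in_sub <- function(v) {
    inside <- logical(gs$n)
    walk <- function(x) {
      inside[x] <<- TRUE
      for (k in gs$children[[x]]) walk(k)
    }
    walk(v)
    inside
  }
  pairs <- list()
  for (v in seq_len(gs$n)) {
    p <- gs$parent[v]
    if (is.na(p) || gs$is_psi[p] || length(gs$children[[p]]) != 2L) next
    inside <- in_sub(v)
    for (t in seq_len(gs$n)) {
      if (t == v || t == p || inside[t] || is.na(gs$parent[t])) next
      # mode of the edge above t once p is spliced out
      pt <- gs$parent[t]
      tm <- if (pt == p) mb[gs$parent[p]] else mb[pt]
      ok <- (!fl$has_gene[v] || !tm) && (!fl$has_psi[v] || !tm) &&
        (!fl$uncovered[v] || tm)
      if (ok) pairs[[length(pairs) + 1L]] <- c(v = v, t = t)
    }
  }
  pairs
}

propose_spr <- function(gs) {
  pairs <- spr_pairs(gs)
  if (length(pairs) == 0L) return(NULL)
  mv <- pairs[[sample.int(length(pairs), 1L)]]
  v <- mv[["v"]]; t <- mv[["t"]]
  p <- gs$parent[v]
  m <- gs_mutable(gs)
  m$parent[v] <- NA_integer_        # detach (reattached below)
  s <- splice_out(m, p)
  A_det <- m$elen[s]                # merged edge length at the detach site
  L_tgt <- m$elen[t]
  j <- insert_on_edge(m, t, runif(1), FALSE)
  m$parent[v] <- j
  prop <- gs_freeze(m)
  log_hr <- log(length(pairs)) - log(length(spr_pairs(prop))) +
    log(L_tgt) - log(A_det)
  list(gs = prop, log_hr = log_hr)
}

# NNI and SPR are each their own reverse move family, so the uniform
# choice probabilities cancel in the Hastings ratio; an empty menu
# proposes the identity.
propose_topology <- function(gs, kinds = c("nni", "spr")) {
  kind <- if (length(kinds) == 1L) kinds else sample(kinds, 1L)
  if (kind == "nni") propose_nni(gs) else propose_spr(gs)
}

# ---- chain configuration and driver --------------------------------------

#' Chain configuration
#'
#' Defaults mirror the analysis protocol the model was designed for:
#' 5,000,000 iterations, burn-in 2,500,000, thinning 500.  Scale these
#' down for exploratory runs.
#'
#' @param iterations,burn_in,thinning MCMC run length controls
#' @param seed RNG seed (chains are deterministic given the seed)
#' @param fixed_tree optional \code{gene_tree_state}: start here and
#'   disable topology moves
#' @param move_weights weights of the move families
#' @param priors parameter priors (\code{\link{default_priors}})
#' @param tuning named proposal standard deviations
#' @param n_discretization interior discretization points per species-tree
#'   edge (NULL = duration-proportional default)
#' @param use_likelihood,use_tree_prior posterior factors to include
#'   (turning them off targets reference distributions for sampler checks)
#' @param sample_realizations sample a dated realization at every thinned
#'   iteration
#' @param auto_tune adapt proposal scales towards 20-40\% acceptance
#'   during burn-in only
#' @param stem_length stem edge length for the NJ initial tree
#' @param init_state optional \code{gene_tree_state} to start from with
#'   all moves enabled (unlike \code{fixed_tree})
#' @param topology_moves topology move kinds to use (subset of
#'   \code{c("nni", "spr")})
#' @return A list of class \code{chain_config}.
#' @export
chain_config <- function(iterations = 5e6, burn_in = 2.5e6, thinning = 500,
                         seed = NULL, fixed_tree = NULL,
                         move_weights = c(length = 0.3, theta = 0.2,
                                          psi = 0.2, topology = 0.3),
                         priors = default_priors(),
                         tuning = c(length = 0.2, delta = 0.2, mu = 0.2,
                                    psi = 0.2, rate_mean = 0.15,
                                    rate_cv = 0.2, kappa = 0.6,
                                    omega = 0.25),
                         n_discretization = NULL,
                         use_likelihood = TRUE, use_tree_prior = TRUE,
                         sample_realizations = FALSE,
                         auto_tune = TRUE, stem_length = 0.1,
                         init_state = NULL,
                         topology_moves = c("nni", "spr")) {
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning, seed = seed, fixed_tree = fixed_tree,
                 move_weights = move_weights, priors = priors,
                 tuning = tuning, n_discretization = n_discretization,
                 use_likelihood = use_likelihood,
                 use_tree_prior = use_tree_prior,
                 sample_realizations = sample_realizations,
                 auto_tune = auto_tune, stem_length = stem_length,
                 init_state = init_state,
                 topology_moves = topology_moves),
            class = "chain_config")
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples gene trees, edge lengths, pseudogenization configurations and
#' model parameters from their joint posterior given a codon alignment, a
#' leaf classification and a dated species tree.  The initial tree is
#' built by neighbor joining on codon-level distances with the minimal
#' valid pseudogenization placement (one vertex at the midpoint of the
#' parent edge of each maximal all-pseudogene clade) unless a fixed tree
#' is supplied, in which case topology moves are disabled and the
#' pseudogenization configuration, lengths and parameters are still
#' sampled.
#'
#' @param aln a \code{codon_alignment}
#' @param st a \code{dated_species_tree}
#' @param leaf_map data.frame (id, species, class) classifying the leaves;
#'   may be NULL when \code{config$fixed_tree} carries the classification
#' @param theta0 initial \code{model_params}
#' @param config a \code{chain_config}
#' @return Object of class \code{pdlrs_trace}: \code{samples} (data.frame
#'   of thinned scalar samples), \code{trees} (thinned
#'   \code{gene_tree_state}s), \code{realizations} (optional),
#'   \code{acceptance} (per move family), \code{map} (highest-posterior
#'   state seen), and the effective configuration.
#' @export
run_chain <- function(aln, st, leaf_map = NULL,
                      theta0 = model_params(0.5, 0.5, 0.5, 1, 0.5,
                                            kappa = 2, omega = 0.5),
                      config = chain_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ctx <- make_context(aln, st, config$n_discretization)
  gs <- if (!is.null(config$fixed_tree)) config$fixed_tree
        else if (!is.null(config$init_state)) config$init_state
        else nj_initial_tree(aln, leaf_map, stem_length = config$stem_length)
  chk <- validate_state(gs)
  if (!chk$ok) stop("invalid initial state: ",
                    paste(chk$violations, collapse = "; "))
  theta <- theta0
  w <- config$move_weights
  if (!is.null(config$fixed_tree)) w[["topology"]] <- 0
  if (!config$use_likelihood && !config$use_tree_prior)
    w <- c(length = 0, theta = 1, psi = 0, topology = 0)
  w <- w / sum(w)
  tune <- config$tuning
  priors <- config$priors
  cache <- new_eval_cache()
  use_ll <- config$use_likelihood
  use_tp <- config$use_tree_prior
  comp_ll <- function(gs, theta) {
    if (!use_ll) return(0)
    m <- cache_models(cache, ctx, theta)
    sequence_log_likelihood(ctx$aln, gs, m$gene, m$pseudo,
                            patterns = ctx$patterns, Pcache = m$Pcache)
  }
  comp_tree <- function(gs, theta) {
    if (!use_tp) return(0)
    bd <- cache_bd(cache, ctx, theta)
    gene_tree_log_prior(gs, theta, ctx$dsp, bd)
  }
  gs <- with_dp_cache(gs, ctx$dsp)
  cur <- list(log_likelihood = comp_ll(gs, theta),
              log_tree_prior = comp_tree(gs, theta),
              log_theta_prior = log_theta_prior(theta, priors))
  cur$total <- cur$log_likelihood + cur$log_tree_prior +
    cur$log_theta_prior
  if (!is.finite(cur$total)) stop("initial state has zero posterior")
  theta_names <- c("delta", "mu", "psi", "rate_mean", "rate_cv",
                   "kappa", "omega")
  n_thin <- max(0L, floor((config$iterations - config$burn_in) /
                            config$thinning))
  samples <- data.frame(iteration = integer(n_thin),
                        log_posterior = numeric(n_thin),
                        log_likelihood = numeric(n_thin),
                        log_tree_prior = numeric(n_thin),
                        log_theta_prior = numeric(n_thin),
                        delta = numeric(n_thin), mu = numeric(n_thin),
                        psi = numeric(n_thin),
                        rate_mean = numeric(n_thin),
                        rate_cv = numeric(n_thin),
                        kappa = numeric(n_thin), omega = numeric(n_thin),
                        n_psi = integer(n_thin),
                        newick = character(n_thin))
  trees <- vector("list", n_thin)
  realizations <- if (config$sample_realizations) vector("list", n_thin)
  acc <- prop_n <- setNames(numeric(4), c("length", "theta", "psi",
                                          "topology"))
  scalar_acc <- scalar_n <- setNames(numeric(length(theta_names) + 1L),
                                     c("length", theta_names))
  map <- list(log_posterior = cur$total, state = gs, theta = theta,
              iteration = 0L)
  row <- 0L
  for (it in seq_len(config$iterations)) {
    mv <- sample(names(w), 1L, prob = w)
    prop_n[mv] <- prop_n[mv] + 1
    accepted <- FALSE
    if (mv == "length") {
      edges <- which(!is.na(gs$edge_length))
      e <- if (length(edges) == 1L) edges else sample(edges, 1L)
      x <- gs$edge_length[e]
      s <- tune[["length"]]
      xp <- rtruncnorm1(x, s, 0, Inf)
      gs2 <- gs                     # keeps the cached topology arrays
      gs2$edge_length[e] <- xp
      lhr <- log_dtruncnorm(x, xp, s, 0, Inf) -
        log_dtruncnorm(xp, x, s, 0, Inf)
      new_ll <- comp_ll(gs2, theta)
      new_tree <- comp_tree(gs2, theta)
      scalar_n[["length"]] <- scalar_n[["length"]] + 1
      if (log(runif(1)) < new_ll + new_tree -
            cur$log_likelihood - cur$log_tree_prior + lhr) {
        gs <- gs2
        cur$log_likelihood <- new_ll
        cur$log_tree_prior <- new_tree
        accepted <- TRUE
        scalar_acc[["length"]] <- scalar_acc[["length"]] + 1
      }
    } else if (mv == "theta") {
      nm <- sample(theta_names, 1L)
      pr <- priors[[nm]]
      x <- theta[[nm]]
      s <- tune[[nm]]
      xp <- rtruncnorm1(x, s, pr$lower, pr$upper)
      theta2 <- theta
      theta2[[nm]] <- xp
      lhr <- log_dtruncnorm(x, xp, s, pr$lower, pr$upper) -
        log_dtruncnorm(xp, x, s, pr$lower, pr$upper)
      new_tp <- log_theta_prior(theta2, priors)
      # only the affected factor is recomputed: kappa/omega enter the
      # sequence likelihood, the remaining parameters the gene-tree prior
      seq_par <- nm %in% c("kappa", "omega")
      if (is.finite(new_tp)) {
        new_ll <- if (seq_par) comp_ll(gs, theta2) else cur$log_likelihood
        new_tree <- if (seq_par) cur$log_tree_prior
                    else comp_tree(gs, theta2)
        logr <- new_ll + new_tree + new_tp - cur$log_likelihood -
          cur$log_tree_prior - cur$log_theta_prior + lhr
      } else logr <- -Inf
      scalar_n[[nm]] <- scalar_n[[nm]] + 1
      if (log(runif(1)) < logr) {
        theta <- theta2
        cur$log_likelihood <- new_ll
        cur$log_tree_prior <- new_tree
        cur$log_theta_prior <- new_tp
        accepted <- TRUE
        scalar_acc[[nm]] <- scalar_acc[[nm]] + 1
      }
    } else {
      pr <- if (mv == "psi") propose_psi(gs)
            else propose_topology(gs, config$topology_moves)
      if (!is.null(pr)) {
        gs2 <- with_dp_cache(pr$gs, ctx$dsp)
        new_ll <- comp_ll(gs2, theta)
        new_tree <- comp_tree(gs2, theta)
        if (log(runif(1)) < new_ll + new_tree - cur$log_likelihood -
              cur$log_tree_prior + pr$log_hr) {
          gs <- gs2
          cur$log_likelihood <- new_ll
          cur$log_tree_prior <- new_tree
          accepted <- TRUE
        }
      }
    }
    cur$total <- cur$log_likelihood + cur$log_tree_prior +
      cur$log_theta_prior
    if (accepted) acc[mv] <- acc[mv] + 1
    if (cur$total > map$log_posterior) {
      map <- list(log_posterior = cur$total, state = gs, theta = theta,
                  iteration = it)
    }
    # burn-in-only adaptation of scalar proposal scales
    if (config$auto_tune && it <= config$burn_in && it %% 500 == 0) {
      for (nm in names(scalar_n)) {
        if (scalar_n[[nm]] >= 20) {
          r <- scalar_acc[[nm]] / scalar_n[[nm]]
          if (r < 0.2) tune[[nm]] <- tune[[nm]] * 0.8
          if (r > 0.4) tune[[nm]] <- tune[[nm]] * 1.25
          scalar_acc[[nm]] <- scalar_n[[nm]] <- 0
        }
      }
    }
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thinning == 0 && row < n_thin) {
      row <- row + 1L
      samples$iteration[row] <- it
      samples$log_posterior[row] <- cur$total
      samples$log_likelihood[row] <- cur$log_likelihood
      samples$log_tree_prior[row] <- cur$log_tree_prior
      samples$log_theta_prior[row] <- cur$log_theta_prior
      for (nm in theta_names) samples[[nm]][row] <- theta[[nm]]
      samples$n_psi[row] <- sum(gs$is_psi)
      samples$newick[row] <- write_gene_tree(gs)
      trees[[row]] <- gs
      if (config$sample_realizations) {
        bd <- cache_bd(cache, ctx, theta)
        dp <- gene_tree_log_prior(gs, theta, ctx$dsp, bd,
                                  return_tables = TRUE)
        realizations[[row]] <- sample_realization(gs, dp, ctx$dsp)
      }
    }
  }
  structure(list(samples = samples[seq_len(row), , drop = FALSE],
                 trees = trees[seq_len(row)],
                 realizations = if (config$sample_realizations)
                   realizations[seq_len(row)],
                 acceptance = data.frame(move = names(acc),
                                         proposed = as.numeric(prop_n),
                                         accepted = as.numeric(acc)),
                 map = map, config = config, tuning_final = tune),
            class = "pdlrs_trace")
}

#' Select the maximum a posteriori tree among candidate traces
#'
#' Returns the candidate whose trace attained the highest recorded log
#' unnormalized posterior; ties are broken by first-seen order.
#'
#' @param traces list of \code{pdlrs_trace} objects
#' @return List with \code{index}, \code{tree}, \code{theta},
#'   \code{log_posterior}.
#' @export
select_map_tree <- function(traces) {
  if (length(traces) == 0L) stop("no traces supplied")
  lps <- vapply(traces, function(tr) tr$map$log_posterior, 0)
  i <- which.max(lps)          # which.max returns the first maximum
  list(index = i, tree = traces[[i]]$map$state,
       theta = traces[[i]]$map$theta, log_posterior = lps[i])
}

# ---- initial tree --------------------------------------------------------

# pairwise fraction of differing codon sites (complete codons only)
codon_p_distance <- function(aln, cs = codon_space()) {
  idx <- matrix(match(aln$codons, cs$codons), nrow = nrow(aln$codons))
  n <- nrow(idx)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    D[i, j] <- D[j, i] <- if (any(ok))
      mean(idx[i, ok] != idx[j, ok]) else 0.5
  }
  D
}

#' Neighbor-joining initial state
#'
#' NJ on codon-level p-distances, midpoint-rooted, with short branches
#' floored and the minimal valid pseudogenization placement added.
#'
#' @param aln a \code{codon_alignment}
#' @param leaf_map data.frame (id, species, class)
#' @param stem_length stem edge length of the degree-one root
#' @return A valid \code{gene_tree_state}.
#' @export
nj_initial_tree <- function(aln, leaf_map, stem_length = 0.1) {
  if (is.null(leaf_map)) stop("leaf_map is required for the NJ initial tree")
  D <- codon_p_distance(aln)
  n <- nrow(D)
  if (n < 2L) stop("need at least two sequences")
  if (n == 2L) {
    txt <- sprintf("(%s:%.6f,%s:%.6f);", aln$ids[1], max(D[1, 2] / 2, 1e-3),
                   aln$ids[2], max(D[1, 2] / 2, 1e-3))
    gs <- read_gene_tree(txt, leaf_map, stem_length)
  } else {
    phy <- ape::nj(as.dist(D))
    phy$edge.length[phy$edge.length < 1e-3] <- 1e-3
    phy <- phangorn::midpoint(phy)
    phy$edge.length[phy$edge.length < 1e-3] <- 1e-3
    gs <- gene_tree_from_phylo(phy, leaf_map, stem_length)
  }
  minimal_psi_placement(gs)
}

#' Minimal valid pseudogenization placement
#'
#' Inserts one pseudogenization vertex at the midpoint of the parent edge
#' of every maximal all-pseudogene clade: the unique valid placement with
#' the fewest vertices.
#'
#' @param gs a \code{gene_tree_state} without pseudogenization vertices
#' @return The augmented \code{gene_tree_state}.
#' @export
minimal_psi_placement <- function(gs) {
  all_pseudo <- logical(gs$n)
  for (u in gene_postorder(gs)) {
    all_pseudo[u] <- if (gs$is_leaf[u]) gs$leaf_class[u] == "pseudogene"
      else all(all_pseudo[gs$children[[u]]])
  }
  targets <- which(vapply(seq_len(gs$n), function(v) {
    p <- gs$parent[v]
    all_pseudo[v] && !is.na(p) && (p == gs$root || !all_pseudo[p])
  }, TRUE))
  if (length(targets) == 0L) return(gs)
  m <- gs_mutable(gs)
  for (v in targets) insert_on_edge(m, v, 0.5, TRUE)
  gs_freeze(m)
}

# ---- convergence diagnostics ---------------------------------------------

#' Effective sample size of a scalar trace
#'
#' Initial-positive-sequence estimator on the autocorrelation function.
#' @param x numeric vector
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

#' Split-Rhat of a scalar trace
#' @param x numeric vector (one chain; split into halves)
#' @return Potential scale reduction factor.
#' @export
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  ch <- list(x[seq_len(n)], x[n + seq_len(n)])
  m <- vapply(ch, mean, 0)
  v <- vapply(ch, var, 0)
  W <- mean(v)
  B <- n * var(m)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
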