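#' Forward simulation of the gene/pseudogene birth-death process
#'
#' A single gene lineage enters the species tree at its degree-one root
#' and evolves towards the leaves: gene lineages duplicate, die and
#' convert to pseudogenes at rates \code{delta}, \code{mu}, \code{psi};
#' pseudogene lineages duplicate and die at the same \code{delta},
#' \code{mu} but cannot convert back; every lineage bifurcates
#' deterministically at speciation vertices.  Lineages without extant
#' descendants are pruned; pseudogenization events remain as degree-two
#' vertices of the pruned tree.
#'
#' @param st a \code{dated_species_tree}
#' @param rates a \code{bd_rates}
#' @param seed optional RNG seed
#' @return List with \code{extinct} (logical; TRUE when no lineage
#'   survives), and otherwise \code{state} (a \code{gene_tree_state} with
#'   NA edge lengths; see \code{\link{assign_lengths}}) and \code{time}
#'   (absolute event time per vertex).
#' @export
simulate_gene_tree <- function(st, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- list()   # each: list(type, time, species, mode, children)
  add <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  # lineage entering the edge above species vertex cv at `time`;
  # returns node id of the subtree root, or NA if it leaves no survivor
  evolve <- function(cv, time, pseudo) {
    repeat {
      rate <- rates$delta + rates$mu + if (pseudo) 0 else rates$psi
      tn <- if (rate > 0) time - rexp(1, rate) else -Inf
      if (tn <= st$time[cv]) {
        if (st$is_leaf[cv]) {
          return(add(list(type = "leaf", time = 0, species = cv,
                          mode = pseudo, children = integer(0))))
        }
        kids <- st$children[[cv]]
        a <- evolve(kids[1], st$time[cv], pseudo)
        b <- evolve(kids[2], st$time[cv], pseudo)
        if (is.na(a) && is.na(b)) return(NA_integer_)
        if (is.na(a)) return(b)
        if (is.na(b)) return(a)
        return(add(list(type = "spec", time = st$time[cv], species = cv,
                        mode = pseudo, children = c(a, b))))
      }
      e <- runif(1) * rate
      if (e < rates$delta) {
        a <- evolve(cv, tn, pseudo)
        b <- evolve(cv, tn, pseudo)
        if (is.na(a) && is.na(b)) return(NA_integer_)
        if (is.na(a)) return(b)
        if (is.na(b)) return(a)
        return(add(list(type = "dup", time = tn, species = cv,
                        mode = pseudo, children = c(a, b))))
      } else if (e < rates$delta + rates$mu) {
        return(NA_integer_)
      } else {
        # pseudogenization: degree-two vertex, then continue as pseudogene
        sub <- evolve(cv, tn, TRUE)
        if (is.na(sub)) return(NA_integer_)
        return(add(list(type = "psi", time = tn, species = cv,
                        mode = FALSE, children = sub)))
      }
    }
  }
  basal <- st$children[[st$root]][1]
  top <- evolve(basal, st$time[st$root], FALSE)
  if (is.na(top)) return(list(extinct = TRUE))
  root_id <- add(list(type = "root", time = st$time[st$root],
                      species = st$root, mode = FALSE, children = top))
  n <- length(nodes)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (k in nodes[[i]]$children) parent[k] <- i
  time <- vapply(nodes, function(x) x$time, 0)
  is_psi <- vapply(nodes, function(x) x$type == "psi", TRUE)
  is_leaf <- vapply(nodes, function(x) x$type == "leaf", TRUE)
  leaf_species <- rep(NA_character_, n)
  leaf_class <- rep(NA_character_, n)
  label <- rep(NA_character_, n)
  cnt <- setNames(integer(sum(st$is_leaf)), st$label[st$is_leaf])
  for (i in which(is_leaf)) {
    sp <- st$label[nodes[[i]]$species]
    cnt[sp] <- cnt[sp] + 1L
    leaf_species[i] <- sp
    leaf_class[i] <- if (nodes[[i]]$mode) "pseudogene" else "gene"
    label[i] <- paste0(sp, "_", cnt[sp],
                       if (nodes[[i]]$mode) "P" else "")
  }
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- as.integer(nodes[[i]]$children)
  gs <- new_gene_tree_state(parent, children, rep(NA_real_, n), is_psi,
                            label, leaf_species, leaf_class)
  list(extinct = FALSE, state = gs, time = time)
}

#' Assign relaxed-clock edge lengths
#'
#' Draws an independent gamma rate (given mean and coefficient of
#' variation) per edge and sets each edge length to rate times the edge's
#' time span; edges incident to pseudogenization vertices get their own
#' independent draws.
#'
#' @param sim result of \code{\link{simulate_gene_tree}} (non-extinct)
#' @param rate_mean,rate_cv gamma mean and coefficient of variation
#' @param seed optional RNG seed
#' @return The \code{gene_tree_state} with edge lengths filled in.
#' @export
assign_lengths <- function(sim, rate_mean, rate_cv, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gs <- sim$state
  shape <- 1 / rate_cv^2
  scale <- rate_mean * rate_cv^2
  for (v in seq_len(gs$n)) {
    p <- gs$parent[v]
    if (is.na(p)) next
    span <- sim$time[p] - sim$time[v]
    r <- rgamma(1, shape = shape, scale = scale)
    gs$edge_length[v] <- max(r * span, 1e-9)
  }
  gs
}

#' Simulate a codon alignment down a gene tree
#'
#' The root sequence is drawn from the gene-mode equilibrium; each edge
#' evolves its parent's sequence with the gene- or pseudogene-mode
#' transition matrix for its length, switching mode below
#' pseudogenization vertices.  Leaves are returned as a codon alignment.
#'
#' @param gs a valid \code{gene_tree_state} with edge lengths
#' @param gene_model,pseudo_model \code{codon_model}s sharing frequencies
#' @param n_codons number of codon sites
#' @param seed optional RNG seed
#' @return A \code{codon_alignment} over the leaves of \code{gs}.
#' @export
simulate_alignment <- function(gs, gene_model, pseudo_model, n_codons = 300,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- codon_space()
  em <- edge_mode_pseudo(gs)
  pr <- pi64(gene_model)
  seqs <- vector("list", gs$n)
  seqs[[gs$root]] <- sample.int(64, n_codons, replace = TRUE, prob = pr)
  walk <- function(v) {
    for (k in gs$children[[v]]) {
      P <- if (isTRUE(em[k])) transition_matrix(pseudo_model,
                                                gs$edge_length[k])
           else transition_matrix(gene_model, gs$edge_length[k],
                                  full64 = TRUE)
      P[P < 0] <- 0
      s <- seqs[[v]]
      out <- integer(n_codons)
      for (state in unique(s)) {
        sel <- s == state
        out[sel] <- sample.int(64, sum(sel), replace = TRUE,
                               prob = P[state, ])
      }
      seqs[[k]] <<- out
      walk(k)
    }
  }
  walk(gs$root)
  lv <- which(gs$is_leaf)
  strings <- vapply(lv, function(v)
    paste(cs$codons[seqs[[v]]], collapse = ""), "")
  codon_alignment(strings, gs$label[lv])
}

#' Nine-taxon vertebrate species tree (synthetic stand-in)
#'
#' A dated nine-species amniote tree with the root-to-leaf depth
#' normalized to 1.0 (one unit = 400 million years) and a stem of 0.1.
#' The topology and (approximate) divergence times follow the consensus
#' vertebrate phylogeny; this object is a synthetic stand-in constructed
#' for simulation studies, not a download of any published calibration.
#'
#' @return A \code{dated_species_tree} of depth 1.
#' @export
nine_taxon_species_tree <- function() {
  txt <- paste0(
    "(chicken:1.0,(opossum:0.4,((cow:0.2,dog:0.2):0.0375,",
    "((mouse:0.05,rat:0.05):0.175,(macaque:0.075,",
    "(human:0.015,chimp:0.015):0.06):0.15):0.0125):0.1625):0.6):0.1;")
  parse_dated_species_tree(txt)
}

#' Synthetic study: grid of simulated gene families
#'
#' Generates one family per cell of a dN/dS x transition/transversion
#' grid over the nine-taxon host tree of depth 1.0 (pseudogenization rate
#' 0.5, uniform codon equilibrium frequencies).  Families that go extinct
#' or contain no pseudogene leaf or fewer than two leaves are redrawn up
#' to an attempt cap.
#'
#' @param seed RNG seed
#' @param omega_grid,kappa_grid grid values (defaults: the 5 x 5 study
#'   design)
#' @param delta,mu duplication and loss rates (the study's
#'   duplication-loss regime; defaults 0.5 each)
#' @param psi pseudogenization rate (default 0.5)
#' @param rate_mean,rate_cv relaxed-clock parameters (defaults 1 and 0.5)
#' @param n_codons codon sites per family (default 300)
#' @param st host tree (default \code{\link{nine_taxon_species_tree}})
#' @param max_attempts redraw cap per family
#' @return List of families; each has \code{state} (true gene tree with
#'   lengths), \code{time} (true vertex times), \code{aln}, \code{omega},
#'   \code{kappa}, \code{psi_times} (true pseudogenization times),
#'   \code{attempts}.
#' @export
synthetic_study <- function(seed = 1,
                            omega_grid = c(0.3, 0.6, 0.8, 1.2, 1.8),
                            kappa_grid = c(0.2, 0.8, 1.2, 1.6, 2.0),
                            delta = 0.5, mu = 0.5, psi = 0.5,
                            rate_mean = 1, rate_cv = 0.5,
                            n_codons = 300,
                            st = nine_taxon_species_tree(),
                            max_attempts = 200) {
  set.seed(seed)
  cs <- codon_space()
  pi_u <- rep(1 / 64, 64)
  rates <- bd_rates(delta, mu, psi)
  fams <- list()
  for (om in omega_grid) for (ka in kappa_grid) {
    gene_model <- build_rate_matrix(ka, om, pi_u, "gene", cs)
    pseudo_model <- build_rate_matrix(ka, 1, pi_u, "pseudogene", cs)
    att <- 0L
    repeat {
      att <- att + 1L
      if (att > max_attempts)
        stop("could not generate a family with a pseudogene leaf")
      sim <- simulate_gene_tree(st, rates)
      if (sim$extinct) next
      nl <- sum(sim$state$is_leaf)
      npsg <- sum(sim$state$leaf_class[sim$state$is_leaf] == "pseudogene")
      if (nl >= 2 && npsg >= 1) break
    }
    gs <- assign_lengths(sim, rate_mean, rate_cv)
    aln <- simulate_alignment(gs, gene_model, pseudo_model, n_codons)
    fams[[length(fams) + 1L]] <-
      list(state = gs, time = sim$time, aln = aln, omega = om, kappa = ka,
           psi_times = sim$time[gs$is_psi], attempts = att)
  }
  fams
}
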