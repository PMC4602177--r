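# independent oracles used to pin the implementation

# ---- brute-force sequence likelihood -------------------------------------
# Sums over all 64-state assignments to every internal vertex, written as
# explicit nested sums over the tree structure (no reuse of the package's
# pruning code).  Transition matrices are taken mode-correctly per edge.
brute_force_loglik <- function(aln, gs, gene_model, pseudo_model) {
  cs <- codon_space()
  em <- pdlrs:::edge_mode_pseudo(gs)
  P <- vector("list", gs$n)
  for (v in seq_len(gs$n)) {
    if (is.na(gs$parent[v])) next
    P[[v]] <- if (isTRUE(em[v]))
      transition_matrix(pseudo_model, gs$edge_length[v])
    else transition_matrix(gene_model, gs$edge_length[v], full64 = TRUE)
  }
  pi_root <- pdlrs:::pi64(gene_model)
  obs <- matrix(match(aln$codons, cs$codons), nrow = nrow(aln$codons))
  rownames(obs) <- aln$ids
  # returns a 64-vector: f[s] = P(observed leaves below v | state at v = s)
  below <- function(v, site) {
    if (gs$is_leaf[v]) {
      o <- obs[gs$label[v], site]
      f <- rep(1, 64)
      if (!is.na(o)) f <- as.numeric(seq_len(64) == o)
      return(f)
    }
    f <- rep(1, 64)
    for (k in gs$children[[v]]) {
      fk <- below(k, site)
      # explicit sum over the child vertex state
      g <- vapply(1:64, function(s) sum(P[[k]][s, ] * fk), 0)
      f <- f * g
    }
    f
  }
  tot <- 0
  for (site in seq_len(aln$n_codons)) {
    tot <- tot + log(sum(pi_root * below(gs$root, site)))
  }
  tot
}

# ---- gene-only (no pseudogenization) reconciliation DP in plain R --------
# Independent transcription of the duplication-loss recursions with
# deSolve-integrated extinction and 1-to-1 factors; valid for states
# without pseudogenization vertices and psi = 0.
dlrs_prior_oracle <- function(gs, theta, dsp) {
  stopifnot(!any(gs$is_psi))
  requireNamespace("deSolve", quietly = TRUE)
  delta <- theta$delta; mu <- theta$mu
  npts <- dsp$n_points
  # extinction at each point and per-slice 1-to-1 factors, leaf to root
  eps <- rep(NA_real_, npts)
  arc <- rep(NA_real_, npts)       # extinction at parent through this point
  p11s <- rep(NA_real_, npts)
  ord <- order(dsp$pt_time)
  for (x in ord) {
    kids <- dsp$pt_children[[x]]
    if (length(kids) == 0L) { eps[x] <- 0; next }
    vals <- numeric(length(kids))
    for (i in seq_along(kids)) {
      z <- kids[i]
      dt <- dsp$pt_time[x] - dsp$pt_time[z]
      f <- function(t, y, parms) {
        list(c(mu - (delta + mu) * y[1] + delta * y[1]^2, y[1]))
      }
      sol <- deSolve::lsoda(c(E = eps[z], I = 0), c(0, dt), f,
                            rtol = 1e-12, atol = 1e-14)
      vals[i] <- sol[2, "E"]
      arc[z] <- sol[2, "E"]
      p11s[z] <- exp(2 * delta * sol[2, "I"] - (delta + mu) * dt)
    }
    eps[x] <- prod(vals)
  }
  shape <- 1 / theta$rate_cv^2
  scale <- theta$rate_mean * theta$rate_cv^2
  g <- function(l, t) dgamma(l / t, shape = shape, scale = scale) / t
  sig <- sigma(gs, dsp$st)
  kind <- dsp$dp_arrays$kind
  # s tables per vertex
  s <- vector("list", gs$n)
  Rsum <- vector("list", gs$n)
  Sside <- vector("list", gs$n)
  post <- setdiff(pdlrs:::gene_postorder(gs), gs$root)
  for (u in post) {
    M <- matrix(0, npts, npts)
    Ru <- rep(0, npts)
    S0 <- matrix(0, npts, 2)
    kids <- gs$children[[u]]
    for (y in seq_len(npts)) {
      d <- 0
      if (gs$is_leaf[u]) {
        if (y == dsp$vertex_point[sig[u]]) d <- 1
      } else if (kind[y] == 0L) {
        d <- 2 * delta * dsp$dp_arrays$wt[y] *
          Rsum[[kids[1]]][y] * Rsum[[kids[2]]][y]
      } else if (kind[y] == 1L && y == dsp$vertex_point[sig[u]]) {
        d <- Sside[[kids[1]]][y, 1] * Sside[[kids[2]]][y, 2] +
          Sside[[kids[1]]][y, 2] * Sside[[kids[2]]][y, 1]
      }
      if (d <= 0) next
      M[y, y] <- d
      base <- d
      z <- y
      x <- dsp$pt_parent[z]
      while (!is.na(x)) {
        base <- base * p11s[z]
        gl <- g(gs$edge_length[u], dsp$pt_time[x] - dsp$pt_time[y])
        if (kind[x] == 1L) {
          # the speciation case consumes the side sums without the
          # sibling-side extinction (the sibling side is occupied by the
          # other child); the factor applies only when continuing past x
          which_side <- match(z, dsp$pt_children[[x]])
          S0[x, which_side] <- S0[x, which_side] + base * gl
          sib <- setdiff(dsp$pt_children[[x]], z)
          base <- base * arc[sib]
        }
        val <- base * gl
        M[x, y] <- val
        Ru[x] <- Ru[x] + val
        z <- x
        x <- dsp$pt_parent[z]
      }
    }
    s[[u]] <- M
    Rsum[[u]] <- Ru
    Sside[[u]] <- S0
  }
  c0 <- gs$children[[gs$root]][1]
  log(Rsum[[c0]][dsp$vertex_point[dsp$st$root]])
}

# ---- BFS shortest path on the line graph (edge-distance oracle) ----------
edge_distance_bfs <- function(gst, e_a, e_b) {
  if (e_a == e_b) return(0L)
  edges <- which(!is.na(gst$parent))
  touch <- function(e) c(gst$parent[e], e)
  adj <- function(e) edges[vapply(edges, function(f)
    f != e && length(intersect(touch(e), touch(f))) > 0, TRUE)]
  dist <- setNames(rep(NA_integer_, gst$n), seq_len(gst$n))
  dist[e_a] <- 0L
  frontier <- e_a
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (e in frontier) for (f in adj(e)) {
      if (is.na(dist[f])) {
        dist[f] <- dist[e] + 1L
        nxt <- c(nxt, f)
      }
    }
    if (!is.na(dist[e_b])) return(as.integer(dist[e_b]))
    frontier <- nxt
  }
  stop("edges not connected")
}
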