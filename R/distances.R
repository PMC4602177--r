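#' Pseudogenization configurations and their comparison
#'
#' Two pseudogenization configurations of one gene family live on the same
#' suppressed tree G* (the gene tree with its degree-two pseudogenization
#' vertices removed).  Each configuration is the set of G* edges created
#' by the suppression, optionally with the time of each suppressed origin.
#' Comparisons decompose the union of the two edge sets into roof/shade
#' relations: an edge of one configuration lying above the corresponding
#' edges of the other is the roof, the covered edges its shade.
#'
#' @name distances
NULL

#' Extract a pseudogenization configuration from a gene-tree state
#'
#' @param gs a valid \code{gene_tree_state}
#' @param times optional numeric vector over the vertices of \code{gs}
#'   with absolute times (e.g. a realization); origin times of the
#'   configuration edges are read from it
#' @return Object of class \code{psi_configuration}: \code{tree} (the
#'   suppressed \code{gene_tree_state}), \code{edges} (child-endpoint
#'   vertex ids of the configuration edges), \code{signature} (clade
#'   signatures identifying the edges), \code{topology} (canonical string
#'   of G*), \code{times} (per configuration edge or NA).
#' @export
psi_configuration <- function(gs, times = NULL) {
  sup <- suppress(gs)
  edges <- which(!is.na(sup$origin))
  sig <- clade_signatures(sup$tree)
  tms <- rep(NA_real_, length(edges))
  if (!is.null(times)) tms <- times[sup$origin[edges]]
  structure(list(tree = sup$tree, edges = edges,
                 signature = sig[edges],
                 topology = canonical_topology(sup$tree),
                 times = tms),
            class = "psi_configuration")
}

# vertex depths (edges from the root)
vertex_depths <- function(gs) {
  d <- integer(gs$n)
  walk <- function(v, k) {
    d[v] <<- k
    for (ch in gs$children[[v]]) walk(ch, k + 1L)
  }
  walk(gs$root, 0L)
  d
}

#' Edge distance on the suppressed tree
#'
#' The number of internal vertices on the unique shortest path containing
#' both edges; zero when the edges coincide, one for adjacent edges.
#'
#' @param gst a \code{gene_tree_state} (the common suppressed tree)
#' @param e_a,e_b edges given by their child-endpoint vertex ids
#' @return Nonnegative integer.
#' @export
edge_distance <- function(gst, e_a, e_b) {
  if (e_a == e_b) return(0L)
  d <- vertex_depths(gst)
  vdist <- function(a, b) {
    k <- 0L
    while (a != b) {
      if (d[a] < d[b]) b <- gst$parent[b] else a <- gst$parent[a]
      k <- k + 1L
    }
    k
  }
  ends_a <- c(gst$parent[e_a], e_a)
  ends_b <- c(gst$parent[e_b], e_b)
  min(outer(ends_a, ends_b, Vectorize(vdist))) + 1L
}

# is edge a (child id) an ancestor-or-equal edge of edge b on the tree?
edge_above <- function(gst, a, b) {
  v <- b
  while (!is.na(v)) {
    if (v == a) return(TRUE)
    v <- gst$parent[v]
  }
  FALSE
}

#' Roof/shade decomposition of a configuration pair
#'
#' Pairs up the edges of two pseudogenization configurations on their
#' common suppressed tree: identical edges form self-relations; otherwise
#' an edge with the other configuration's corresponding edges strictly
#' below it is a roof and those edges are its shade.  Every edge of both
#' configurations belongs to exactly one relation.
#'
#' @param a,b \code{psi_configuration}s with identical suppressed topology
#' @return List of relations: \code{roof} (edge id on \code{a$tree}),
#'   \code{roof_set} (1 or 2), \code{shade} (edge ids), \code{roof_time},
#'   \code{shade_times}.
#' @export
roofs_and_shades <- function(a, b) {
  if (!identical(a$topology, b$topology))
    stop("configurations do not share a suppressed tree")
  gst <- a$tree
  # map b's edges into a's vertex numbering via clade signatures
  sig_a <- clade_signatures(gst)
  eb <- match(b$signature, sig_a)
  if (anyNA(eb)) stop("edge signatures do not map between configurations")
  ea <- a$edges
  rel <- list()
  used_b <- logical(length(eb))
  for (i in seq_along(ea)) {
    f <- ea[i]
    j_eq <- which(eb == f)
    if (length(j_eq) == 1L) {       # identical edge: roof shading itself
      used_b[j_eq] <- TRUE
      rel[[length(rel) + 1L]] <- list(roof = f, roof_set = 1L, shade = f,
                                      roof_time = a$times[i],
                                      shade_times = b$times[j_eq])
      next
    }
    above <- which(vapply(eb, function(e) edge_above(gst, e, f) && e != f,
                          TRUE))
    if (length(above) > 0L) next    # f belongs to that edge's shade
    below <- which(vapply(eb, function(e) edge_above(gst, f, e) && e != f,
                          TRUE))
    used_b[below] <- TRUE
    rel[[length(rel) + 1L]] <- list(roof = f, roof_set = 1L,
                                    shade = eb[below],
                                    roof_time = a$times[i],
                                    shade_times = b$times[below])
  }
  for (j in which(!used_b)) {
    e <- eb[j]
    below <- which(vapply(ea, function(f) edge_above(gst, e, f) && f != e,
                          TRUE))
    if (length(below) == 0L) next   # already covered via equality above
    rel[[length(rel) + 1L]] <- list(roof = e, roof_set = 2L,
                                    shade = ea[below],
                                    roof_time = b$times[j],
                                    shade_times = a$times[below])
  }
  rel
}

#' Topological distance between pseudogenization configurations
#'
#' Per roof, the mean and the maximum edge distance to its shade; the
#' average topological distance D_a is the mean of the per-roof means and
#' the maximum topological distance D_m the maximum of the per-roof
#' maxima.
#'
#' @param a,b \code{psi_configuration}s sharing a suppressed tree
#' @return Named numeric vector \code{c(D_a, D_m)}.
#' @export
topological_distance <- function(a, b) {
  rel <- roofs_and_shades(a, b)
  if (length(rel) == 0L) return(c(D_a = 0, D_m = 0))
  das <- dms <- numeric(length(rel))
  for (i in seq_along(rel)) {
    dd <- vapply(rel[[i]]$shade, function(e)
      as.numeric(edge_distance(a$tree, rel[[i]]$roof, e)), 0)
    das[i] <- mean(dd)
    dms[i] <- max(dd)
  }
  c(D_a = mean(das), D_m = max(dms))
}

#' Temporal distance between pseudogenization configurations
#'
#' Same aggregation as the topological distance with the absolute
#' difference between the roof's origin time and each shade origin time,
#' in species-tree time units.
#'
#' @param a,b \code{psi_configuration}s with origin times
#' @return Named numeric vector \code{c(T_a, T_m)}.
#' @export
temporal_distance <- function(a, b) {
  rel <- roofs_and_shades(a, b)
  if (length(rel) == 0L) return(c(T_a = 0, T_m = 0))
  tas <- tms <- numeric(length(rel))
  for (i in seq_along(rel)) {
    if (anyNA(c(rel[[i]]$roof_time, rel[[i]]$shade_times)))
      stop("origin times missing for temporal distance")
    dd <- abs(rel[[i]]$roof_time - rel[[i]]$shade_times)
    tas[i] <- mean(dd)
    tms[i] <- max(dd)
  }
  c(T_a = mean(tas), T_m = max(tms))
}

#' Posterior summaries of configuration distances
#'
#' Given the true configuration and posterior samples, computes the
#' expected (posterior-weighted mean) and maximum-over-support values of
#' the average and maximum topological distances, and their temporal
#' analogues when times are available.  Samples whose suppressed topology
#' differs from the truth cannot be compared edge-by-edge and are counted
#' separately.
#'
#' @param truth a \code{psi_configuration}
#' @param samples list of \code{psi_configuration}s (posterior draws)
#' @param weights optional weights (defaults to equal; normalized over
#'   the comparable support)
#' @param temporal also compute temporal summaries
#' @return List with \code{E_Da}, \code{M_Da}, \code{E_Dm}, \code{M_Dm},
#'   temporal analogues (\code{E_Ta}, \code{M_Ta}, \code{E_Tm},
#'   \code{M_Tm}) when requested, \code{n_used}, \code{n_excluded}.
#' @export
posterior_summaries <- function(truth, samples, weights = NULL,
                                temporal = FALSE) {
  if (is.null(weights)) weights <- rep(1, length(samples))
  keep <- vapply(samples, function(s) identical(s$topology, truth$topology),
                 TRUE)
  if (!any(keep)) stop("no comparable samples (no shared suppressed tree)")
  ww <- weights[keep] / sum(weights[keep])
  Da <- Dm <- Ta <- Tm <- numeric(sum(keep))
  i <- 0L
  for (s in samples[keep]) {
    i <- i + 1L
    d <- topological_distance(truth, s)
    Da[i] <- d[["D_a"]]; Dm[i] <- d[["D_m"]]
    if (temporal) {
      tt <- temporal_distance(truth, s)
      Ta[i] <- tt[["T_a"]]; Tm[i] <- tt[["T_m"]]
    }
  }
  out <- list(E_Da = sum(ww * Da), M_Da = max(Da),
              E_Dm = sum(ww * Dm), M_Dm = max(Dm),
              n_used = sum(keep), n_excluded = sum(!keep))
  if (temporal) {
    out$E_Ta <- sum(ww * Ta); out$M_Ta <- max(Ta)
    out$E_Tm <- sum(ww * Tm); out$M_Tm <- max(Tm)
  }
  out
}
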