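#' Dated species trees
#'
#' A dated species tree is a rooted binary ultrametric tree with absolute
#' times on its vertices (leaves at time 0, times increasing towards the
#' root) plus a degree-one root vertex above the basal speciation: the stem
#' over which the ancestral gene lineage enters the tree.
#'
#' @param newick_text Newick string with branch lengths interpretable as
#'   times.  A root edge (e.g. \code{"(...):0.5;"}) is used as the stem of
#'   the degree-one root; when absent, a stem of \code{stem_fraction} times
#'   the tree height is added.
#' @param stem_fraction Stem duration as a fraction of tree height when the
#'   input carries no root edge (default 0.1).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An object of class \code{dated_species_tree}: a list with
#'   integer \code{parent} (NA at the root), \code{children}, numeric
#'   absolute \code{time} per vertex, logical \code{is_leaf}, character
#'   \code{label}, and \code{root} (the degree-one root index).
#' @export
parse_dated_species_tree <- function(newick_text, stem_fraction = 0.1,
                                     tol = 1e-6) {
  phy <- ape::read.tree(text = newick_text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  dated_species_tree_from_phylo(phy, stem_fraction = stem_fraction, tol = tol)
}

#' Build a dated species tree from an ape \code{phylo} object
#'
#' @param phy rooted binary \code{phylo} with branch lengths (= durations);
#'   an optional \code{root.edge} becomes the stem of the degree-one root.
#' @inheritParams parse_dated_species_tree
#' @return A \code{dated_species_tree}.
#' @export
dated_species_tree_from_phylo <- function(phy, stem_fraction = 0.1,
                                          tol = 1e-6) {
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.binary(phy)) stop("species tree contains polytomies")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  depth <- numeric(nnode)            # time from phylo root down to vertex
  parent <- rep(NA_integer_, nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    depth[c] <- depth[p] + phy$edge.length[i]
  }
  height <- max(depth[seq_len(ntip)])
  leaf_depth <- depth[seq_len(ntip)]
  if (any(abs(leaf_depth - height) > tol * max(height, 1))) {
    rpt <- paste(sprintf("%s=%.8g", phy$tip.label, leaf_depth),
                 collapse = ", ")
    stop("species tree is not ultrametric (leaf depths: ", rpt, ")")
  }
  time <- height - depth
  time[seq_len(ntip)] <- 0           # snap leaves exactly to 0
  stem <- if (!is.null(phy$root.edge) && phy$root.edge > 0)
    phy$root.edge else stem_fraction * height
  if (stem <= 0) stop("stem duration must be positive")
  # append the degree-one root above the basal speciation
  root <- nnode + 1L
  parent <- c(parent, NA_integer_)
  parent[ntip + 1L] <- root
  time <- c(time, height + stem)
  is_leaf <- c(rep(TRUE, ntip), rep(FALSE, phy$Nnode + 1L))
  label <- c(phy$tip.label, rep(NA_character_, phy$Nnode + 1L))
  children <- vector("list", root)
  for (v in seq_len(root)) children[[v]] <- integer(0)
  for (v in seq_len(root)) if (!is.na(parent[v]))
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  st <- structure(list(parent = parent, children = children, time = time,
                       is_leaf = is_leaf, label = label, root = root,
                       n_vertices = root),
                  class = "dated_species_tree")
  validate_species_tree(st)
  st
}

validate_species_tree <- function(st) {
  stopifnot(length(st$children[[st$root]]) == 1L)
  for (v in seq_len(st$n_vertices)) {
    kids <- st$children[[v]]
    if (st$is_leaf[v] && length(kids) != 0L)
      stop("leaf with children")
    if (!st$is_leaf[v] && v != st$root && length(kids) != 2L)
      stop("non-binary internal vertex")
    for (k in kids) if (st$time[k] >= st$time[v])
      stop("node times must strictly decrease from root to leaves")
  }
  if (anyDuplicated(st$label[st$is_leaf]))
    stop("leaf names must be unique")
  invisible(st)
}

#' Tree height (root-to-leaf time, excluding the stem)
#' @param st a \code{dated_species_tree}
#' @export
species_tree_height <- function(st) {
  basal <- st$children[[st$root]][1]
  st$time[basal]
}

# postorder over species-tree vertices (children before parents)
species_postorder <- function(st) {
  ord <- integer(0)
  walk <- function(v) {
    for (k in st$children[[v]]) walk(k)
    ord[[length(ord) + 1L]] <<- v
  }
  walk(st$root)
  unlist(ord)
}

#' Discretize a dated species tree
#'
#' Augments every edge of the species tree with equidistant interior time
#' points; the resulting point grid is the support on which the gene-tree
#' prior's time integrals are approximated by sums.
#'
#' @param st a \code{dated_species_tree}.
#' @param n_points Either a single positive integer (interior points per
#'   edge) or \code{NULL} for the default density: per-edge counts
#'   proportional to edge duration with target slice width
#'   \code{height / 30} and a floor of \code{min_points}.
#' @param min_points Floor on interior points per edge for the
#'   proportional default.
#' @return An object of class \code{discretized_species_tree}; points are
#'   indexed \code{1..n_points_total}, species vertices are points too
#'   (\code{pt_vertex} maps them back), and \code{pt_parent}/\code{pt_time}
#'   give the point topology and times.
#' @export
discretize <- function(st, n_points = NULL, min_points = 3L) {
  height <- species_tree_height(st)
  per_edge <- function(duration) {
    if (!is.null(n_points)) {
      if (n_points < 1) stop("n_points must be >= 1")
      as.integer(n_points)
    } else {
      max(as.integer(min_points), as.integer(ceiling(duration / (height / 30))))
    }
  }
  nv <- st$n_vertices
  pt_time <- st$time                  # species vertices become points 1..nv
  pt_parent <- rep(NA_integer_, nv)
  pt_vertex <- seq_len(nv)
  pt_edge_child <- rep(NA_integer_, nv)  # species edge (by child vertex) a point lies on
  # interior points appended per edge, bottom to top
  for (v in seq_len(nv)) {
    p <- st$parent[v]
    if (is.na(p)) next
    k <- per_edge(st$time[p] - st$time[v])
    h <- (st$time[p] - st$time[v]) / (k + 1)
    below <- v                       # point id of the child endpoint
    for (j in seq_len(k)) {
      pt_time <- c(pt_time, st$time[v] + j * h)
      pt_parent <- c(pt_parent, NA_integer_)
      pt_vertex <- c(pt_vertex, NA_integer_)
      pt_edge_child <- c(pt_edge_child, v)
      id <- length(pt_time)
      pt_parent[below] <- id
      below <- id
    }
    pt_parent[below] <- p
  }
  npt <- length(pt_time)
  pt_children <- vector("list", npt)
  for (i in seq_len(npt)) pt_children[[i]] <- integer(0)
  for (i in seq_len(npt)) if (!is.na(pt_parent[i]))
    pt_children[[pt_parent[i]]] <- c(pt_children[[pt_parent[i]]], i)
  slice_dt <- ifelse(is.na(pt_parent), NA_real_, pt_time[pt_parent] - pt_time)
  dsp <- structure(list(st = st, n_points = npt, pt_time = pt_time,
                        pt_parent = pt_parent, pt_children = pt_children,
                        pt_vertex = pt_vertex,
                        pt_edge_child = pt_edge_child,
                        slice_dt = slice_dt,
                        vertex_point = seq_len(nv),
                        root_point = st$root),
                   class = "discretized_species_tree")
  dsp$dp_arrays <- dp_point_arrays(dsp)   # cached for the prior DP
  dsp
}

#' Time between two comparable discretization points
#'
#' @param dsp a \code{discretized_species_tree}
#' @param x,y point indices; \code{x} must be an ancestor of \code{y} or
#'   equal to it.
#' @return \code{time(x) - time(y)} (nonnegative).
#' @export
time_between <- function(dsp, x, y) {
  if (!point_is_ancestor(dsp, x, y))
    stop("x must be an ancestor of y (or equal)")
  dsp$pt_time[x] - dsp$pt_time[y]
}

# is x an ancestor of y (or equal) in the point topology?
point_is_ancestor <- function(dsp, x, y) {
  v <- y
  while (!is.na(v)) {
    if (v == x) return(TRUE)
    v <- dsp$pt_parent[v]
  }
  FALSE
}

# points in postorder (all descendants before each point)
point_postorder <- function(dsp) {
  order(dsp$pt_time, seq_len(dsp$n_points))
}
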