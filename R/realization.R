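#' Sample a dated realization of the gene tree
#'
#' Top-down stochastic backtrace through the DP tables: the root's single
#' child is placed at a point with probability proportional to its row in
#' the root table, and every other vertex conditionally on its parent's
#' placement (restricted, at speciation placements, to the species-tree
#' side its leaves map into).  Pseudogenization vertices then receive a
#' continuous time by linear interpolation between the realized times of
#' their endpoints, weighted by the two incident edge lengths.
#'
#' @param gs a valid \code{gene_tree_state}
#' @param dp result of \code{gene_tree_log_prior(..., return_tables = TRUE)}
#' @param dsp the \code{discretized_species_tree} used for \code{dp}
#' @return data.frame with one row per gene-tree vertex: \code{vertex},
#'   \code{point} (species-tree point id; NA for the gene-tree root and
#'   for pseudogenization vertices, which are dated by interpolation),
#'   \code{time}, \code{is_psi}.
#' @export
sample_realization <- function(gs, dp, dsp) {
  npts <- dsp$n_points
  rootpt <- dsp$vertex_point[dsp$st$root]
  point <- rep(NA_integer_, gs$n)
  time <- rep(NA_real_, gs$n)
  c0 <- gs$children[[gs$root]][1]
  pick <- function(w) {
    s <- sum(w)
    if (s <= 0) stop("zero-probability backtrace: inconsistent DP tables")
    sample.int(length(w), 1L, prob = w / s)
  }
  # proper-descendant mask of a point
  desc_mask <- function(x) {
    m <- logical(npts)
    for (y in seq_len(npts)) {
      z <- dsp$pt_parent[y]
      while (!is.na(z)) {
        if (z == x) { m[y] <- TRUE; break }
        z <- dsp$pt_parent[z]
      }
    }
    m
  }
  # side (first point child of x) through which y is reached from x
  arc_of <- function(x, y) {
    z <- y
    repeat {
      p <- dsp$pt_parent[z]
      if (is.na(p)) stop("not a descendant")
      if (p == x) return(z)
      z <- p
    }
  }
  assign_vertex <- function(u, y) {
    point[u] <<- y
    time[u] <<- dsp$pt_time[y]
    kids <- gs$children[[u]]
    if (length(kids) == 0L) return(invisible())
    dm <- desc_mask(y)
    is_spec <- !is.na(dsp$pt_vertex[y]) &&
      length(dsp$pt_children[[y]]) == 2L
    if (length(kids) == 2L && is_spec) {
      arcs <- dsp$pt_children[[y]]
      # each child must descend through a distinct arc
      w1 <- dp$tables[[kids[1]]][y, ]; w1[!dm] <- 0
      w2 <- dp$tables[[kids[2]]][y, ]; w2[!dm] <- 0
      a1 <- vapply(seq_len(npts), function(q)
        dm[q] && identical(arc_of(y, q), arcs[1]), TRUE)
      p11_ <- w1 * a1; p12 <- w1 * !a1
      p21 <- w2 * a1; p22 <- w2 * !a1
      if (sum(p11_) * sum(p22) >= sum(p12) * sum(p21)) {
        y1 <- pick(p11_); y2 <- pick(p22)
      } else {
        y1 <- pick(p12); y2 <- pick(p21)
      }
      assign_vertex(kids[1], y1)
      assign_vertex(kids[2], y2)
    } else {
      for (k in kids) {
        w <- dp$tables[[k]][y, ]
        w[!dm] <- 0
        assign_vertex(k, pick(w))
      }
    }
  }
  w0 <- dp$tables[[c0]][rootpt, ]
  w0[rootpt] <- 0
  assign_vertex(c0, pick(w0))
  point[gs$root] <- NA_integer_
  time[gs$root] <- dsp$pt_time[rootpt]
  # date pseudogenization vertices by length-weighted interpolation
  for (u in which(gs$is_psi)) {
    p <- gs$parent[u]; ch <- gs$children[[u]][1]
    tp <- time[p]; tc <- time[ch]
    l1 <- gs$edge_length[u]; l2 <- gs$edge_length[ch]
    time[u] <- tp - (tp - tc) * l1 / (l1 + l2)
    point[u] <- NA_integer_
  }
  data.frame(vertex = seq_len(gs$n), point = point, time = time,
             is_psi = gs$is_psi)
}
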