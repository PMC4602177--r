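#' Birth-death rates of the two-type process
#'
#' @param delta duplication rate (events per lineage per time unit)
#' @param mu loss rate
#' @param psi pseudogenization (gene-to-pseudogene conversion) rate
#' @return A list of class \code{bd_rates}.
#' @export
bd_rates <- function(delta, mu, psi) {
  if (any(c(delta, mu, psi) < 0)) stop("rates must be nonnegative")
  structure(list(delta = delta, mu = mu, psi = psi), class = "bd_rates")
}

#' Extinction and 1-to-1 tables of the two-type birth-death process
#'
#' Computes, for every point of the discretized species tree, the
#' probability that a gene (or pseudogene) lineage starting there leaves no
#' extant descendant, and per discretization slice the "1-to-1"
#' probability: the lineage reaches the lower end of the slice as a single
#' tracked copy of its type while every side lineage spawned by unobserved
#' duplications goes extinct.  Extinction probabilities solve the coupled
#' Riccati system (a pseudogene lineage duplicates and dies at the same
#' rates as a gene but cannot convert); both are integrated by fixed-step
#' RK4 within each slice, multiplying across the two child arcs at
#' speciation vertices.  1-to-1 slice factors are
#' \code{exp(2 delta int(eps) - rate_total * dt)} and compose
#' multiplicatively along paths.
#'
#' @param dsp a \code{discretized_species_tree}
#' @param rates a \code{bd_rates}
#' @param n_substeps RK4 substeps per slice (default 20)
#' @return Object of class \code{bd_tables} with per-point \code{eps_g},
#'   \code{eps_p}, per-point arc values \code{eps_arc_g}/\code{eps_arc_p}
#'   (extinction at the parent through this point's subtree, used as the
#'   off-path factor at speciations) and per-slice \code{p11_g},
#'   \code{p11_p}.
#' @export
extinction_tables <- function(dsp, rates, n_substeps = 20L) {
  ord <- point_postorder(dsp)
  out <- bd_tables_cpp(ifelse(is.na(dsp$pt_parent), -1L,
                              dsp$pt_parent - 1L),
                       dsp$pt_time, ord - 1L,
                       rates$delta, rates$mu, rates$psi,
                       as.integer(n_substeps))
  structure(c(out, list(rates = rates)), class = "bd_tables")
}

#' 1-to-1 probability between two comparable points
#'
#' Product of per-slice 1-to-1 factors along the path from \code{y} up to
#' \code{x} (no off-path speciation factors; those belong to the
#' reconciliation recursion).
#'
#' @param dsp a \code{discretized_species_tree}
#' @param bd a \code{bd_tables}
#' @param x,y point indices, \code{x} an ancestor of \code{y} or equal
#' @param mode \code{"gene"} or \code{"pseudogene"}
#' @return Probability in [0, 1].
#' @export
p11 <- function(dsp, bd, x, y, mode = c("gene", "pseudogene")) {
  mode <- match.arg(mode)
  tab <- if (mode == "gene") bd$p11_g else bd$p11_p
  out <- 1
  z <- y
  while (z != x) {
    if (is.na(dsp$pt_parent[z])) stop("x must be an ancestor of y (or equal)")
    out <- out * tab[z]
    z <- dsp$pt_parent[z]
  }
  out
}

#' Monte-Carlo oracle for the two-type process
#'
#' Forward-simulates the two-type duplication/loss/conversion process from
#' a point on the species tree and estimates (a) the extinction probability
#' and (b), optionally, the expected number of designatable "1-to-1"
#' lineages at a registration point lower on the same edge: lineages of the
#' requested type crossing the registration time whose complement of
#' crossing lineages leaves no extant descendant.
#'
#' @param st a \code{dated_species_tree}
#' @param rates a \code{bd_rates}
#' @param start list with \code{edge} (child species-vertex id identifying
#'   the edge) and \code{time} (absolute time on that edge)
#' @param n_reps number of replicates
#' @param start_type \code{"gene"} or \code{"pseudogene"}
#' @param target optional list with \code{time} (on the same edge, below
#'   \code{start$time}) and \code{type}
#' @param seed optional RNG seed
#' @return List with \code{extinction} (estimate, se) and, when a target
#'   is given, \code{one_to_one} (estimate, se).
#' @export
mc_oracle <- function(st, rates, start, n_reps, start_type = "gene",
                      target = NULL, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k1 <- k2 <- rep(-1L, st$n_vertices)
  for (v in seq_len(st$n_vertices)) {
    kids <- st$children[[v]]
    if (length(kids) == 2L) { k1[v] <- kids[1] - 1L; k2[v] <- kids[2] - 1L }
  }
  ht <- !is.null(target)
  res <- mc_twotype_cpp(k1, k2, st$time,
                        start$edge - 1L, start$time,
                        if (start_type == "gene") 0L else 1L,
                        rates$delta, rates$mu, rates$psi,
                        as.integer(n_reps),
                        ht,
                        if (ht) start$edge - 1L else -1L,
                        if (ht) target$time else 0,
                        if (ht && target$type == "pseudogene") 1L else 0L)
  ext <- mean(res$extinct)
  out <- list(extinction = c(estimate = ext,
                             se = sqrt(ext * (1 - ext) / n_reps)))
  if (ht) {
    m <- mean(res$one_to_one)
    out$one_to_one <- c(estimate = m,
                        se = sd(res$one_to_one) / sqrt(n_reps))
  }
  out
}
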