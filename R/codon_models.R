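#' Codon state space
#'
#' The 64 codons of a genetic code, partitioned into sense and stop codons,
#' with the pairwise single-nucleotide-change classification used by
#' GY94-style rate matrices.
#'
#' @param code named character vector mapping codon triplets to amino
#'   acids, \code{"*"} for stops (default: the standard code from
#'   \pkg{Biostrings}).
#' @return An object of class \code{codon_space}: codon triplets, stop
#'   indicator, sense indices, and a 64x64 integer classification matrix
#'   (0 = more than one position differs or identical; 1 = synonymous
#'   transversion; 2 = synonymous transition; 3 = nonsynonymous
#'   transversion; 4 = nonsynonymous transition).
#' @export
codon_space <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste(names(code), code, collapse = ";")
  hit <- .codon_space_cache[[key]]
  if (!is.null(hit)) return(hit)
  codons <- names(code)
  stopifnot(length(codons) == 64L)
  aa <- unname(code)
  is_stop <- aa == "*"
  mat <- matrix(0L, 64, 64, dimnames = list(codons, codons))
  purine <- c("A", "G")
  split3 <- strsplit(codons, "")
  for (i in 1:64) for (j in 1:64) {
    if (i == j) next
    diff <- which(split3[[i]] != split3[[j]])
    if (length(diff) != 1L) next
    a <- split3[[i]][diff]; b <- split3[[j]][diff]
    ts <- (a %in% purine) == (b %in% purine)
    syn <- aa[i] == aa[j]
    mat[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L else
      if (!syn && !ts) 3L else 4L
  }
  out <- structure(list(codons = codons, aa = aa, is_stop = is_stop,
                        sense = which(!is_stop), n_sense = sum(!is_stop),
                        class_matrix = mat),
                   class = "codon_space")
  .codon_space_cache[[key]] <- out
  out
}

.codon_space_cache <- new.env(parent = emptyenv())

#' Estimate equilibrium codon frequencies from an alignment
#'
#' Empirical codon counts over all sequences (genes and pseudogenes
#' jointly) with add-one pseudocounts over the 64 codons; codons containing
#' a gap or ambiguity at any of their three positions are skipped.
#'
#' @param aln a \code{codon_alignment} (see \code{\link{read_codon_alignment}})
#' @param cs a \code{codon_space}
#' @return Named numeric vector of 64 frequencies summing to 1.
#' @export
estimate_frequencies <- function(aln, cs = codon_space()) {
  counts <- setNames(rep(1, 64), cs$codons)   # add-one pseudocounts
  tab <- table(aln$codons[aln$codons %in% cs$codons])
  counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  counts / sum(counts)
}

#' Build a codon substitution rate matrix
#'
#' GY94-style generator: zero rate between codons differing at more than
#' one position, and otherwise rate \code{pi_j} times \code{kappa} for a
#' transition and times \code{omega} for a nonsynonymous change, scaled so
#' one unit of edge length is one expected substitution per codon site at
#' equilibrium.  In gene mode the state space is the sense codons (no rates
#' into or out of stops, frequencies renormalized over sense codons); in
#' pseudogene mode all 64 codons are states, \code{omega} is fixed at 1 and
#' single-position changes into and out of stop codons are allowed.
#'
#' @param kappa transition/transversion ratio (>= 0)
#' @param omega dN/dS ratio (>= 0); ignored (forced to 1) in pseudogene mode
#' @param pi equilibrium frequencies over all 64 codons
#' @param mode \code{"gene"} or \code{"pseudogene"}
#' @param cs a \code{codon_space}
#' @return A list of class \code{codon_model}: \code{Q} (generator over the
#'   mode's state space), \code{pi} (stationary distribution used),
#'   \code{states} (codon indices into the 64-codon space), \code{mode},
#'   and the spectral decomposition used by
#'   \code{\link{transition_matrix}}.
#' @export
build_rate_matrix <- function(kappa, omega, pi, mode = c("gene", "pseudogene"),
                              cs = codon_space()) {
  mode <- match.arg(mode)
  stopifnot(kappa >= 0, omega >= 0, length(pi) == 64L, all(pi >= 0))
  if (mode == "pseudogene") omega <- 1
  states <- if (mode == "gene") cs$sense else 1:64
  if (mode == "gene" && any(pi[cs$sense] == 0))
    stop("gene mode requires positive frequencies on all sense codons")
  p <- pi[states] / sum(pi[states])
  cl <- cs$class_matrix[states, states, drop = FALSE]
  mult <- matrix(0, length(states), length(states))
  mult[cl == 1L] <- 1
  mult[cl == 2L] <- kappa
  mult[cl == 3L] <- omega
  mult[cl == 4L] <- kappa * omega
  Q <- mult * rep(p, each = length(states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  norm <- -sum(p * diag(Q))
  if (norm <= 0) stop("degenerate rate matrix (no admissible substitutions)")
  Q <- Q / norm
  # spectral decomposition via the symmetrized generator (Q is reversible)
  sq <- sqrt(p)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(Q = Q, pi = p, states = states, mode = mode,
                 kappa = kappa, omega = omega,
                 eig_values = eig$values,
                 eig_right = eig$vectors / sq,        # D^{-1/2} U
                 eig_left = t(eig$vectors * sq)),     # U' D^{1/2}
            class = "codon_model")
}

#' Codon transition probabilities
#'
#' Matrix exponential \code{expm(Q * t)} of a \code{codon_model} via its
#' cached spectral decomposition.
#'
#' @param model a \code{codon_model}
#' @param branch_length expected substitutions per codon site (>= 0)
#' @param full64 if TRUE, embed a gene-mode matrix into the 64-codon space
#'   (identity on stop codons, which carry no probability mass in gene
#'   mode).
#' @return Row-stochastic transition matrix.
#' @export
transition_matrix <- function(model, branch_length, full64 = FALSE) {
  if (branch_length < 0) stop("branch length must be nonnegative")
  P <- (model$eig_right * rep(exp(model$eig_values * branch_length),
                              each = nrow(model$eig_right))) %*% model$eig_left
  if (full64 && length(model$states) < 64L) {
    P64 <- diag(64)
    P64[model$states, model$states] <- P
    P <- P64
  }
  P
}

# stationary distribution embedded in the 64-codon space
pi64 <- function(model) {
  out <- numeric(64)
  out[model$states] <- model$pi
  out
}
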