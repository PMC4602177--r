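#' Sequence log-likelihood with a pseudogenization switch
#'
#' Felsenstein pruning over the gene tree, including its degree-two
#' pseudogenization vertices: an edge whose parent vertex emits gene
#' lineages uses the gene-mode transition matrix for its full length, any
#' edge below a pseudogenization vertex uses the pseudogene-mode matrix,
#' and the root state distribution is the gene-mode equilibrium (the root
#' precedes all pseudogenizations by model construction).  All partial
#' likelihoods live in the 64-codon space; the gene matrix carries zero
#' rates touching stop codons.  Missing codons (gaps/ambiguities) give
#' all-one partials; per-node scaling guards against underflow.
#'
#' @param aln a \code{codon_alignment} whose ids match the gene-tree leaves
#' @param gs a valid \code{gene_tree_state}
#' @param gene_model,pseudo_model \code{codon_model}s sharing the same
#'   underlying 64-codon frequencies
#' @param patterns optional precompressed site patterns
#'   (\code{pdlrs:::compress_patterns}); computed when NULL
#' @param Pcache optional environment caching per-edge transition matrices
#'   across calls, keyed by mode and length
#' @return Log-likelihood (sum over compressed site patterns).
#' @export
sequence_log_likelihood <- function(aln, gs, gene_model, pseudo_model,
                                    patterns = NULL, Pcache = NULL) {
  cs <- codon_space()
  if (is.null(patterns)) patterns <- compress_patterns(aln, cs)
  leaf_row <- match(gs$label[gs$is_leaf], aln$ids)
  if (anyNA(leaf_row)) stop("alignment ids do not match gene-tree leaves")
  row_of <- rep(NA_integer_, gs$n)
  row_of[which(gs$is_leaf)] <- leaf_row
  npat <- length(patterns$weight)
  em <- attr(gs, "edge_mode")
  if (is.null(em)) em <- edge_mode_pseudo(gs)
  po <- attr(gs, "postorder")
  if (is.null(po)) po <- gene_postorder(gs)
  pi_root <- pi64(gene_model)
  getP <- function(v) {
    mode <- if (isTRUE(em[v])) "p" else "g"
    len <- gs$edge_length[v]
    if (!is.null(Pcache)) {
      key <- paste0(mode, v)       # entry validity checked on the length
      ent <- Pcache[[key]]
      if (!is.null(ent) && ent$len == len) return(ent$P)
    }
    P <- if (mode == "p") transition_matrix(pseudo_model, len)
         else transition_matrix(gene_model, len, full64 = TRUE)
    if (!is.null(Pcache)) Pcache[[key]] <- list(len = len, P = P)
    P
  }
  logscale <- 0
  partial <- vector("list", gs$n)
  for (u in po) {
    if (gs$is_leaf[u]) {
      L <- matrix(0, 64, npat)
      obs <- patterns$idx[row_of[u], ]
      miss <- is.na(obs)
      if (any(miss)) L[, miss] <- 1
      L[cbind(obs[!miss], which(!miss))] <- 1
    } else {
      L <- matrix(1, 64, npat)
      for (k in gs$children[[u]]) {
        L <- L * (getP(k) %*% partial[[k]])
        partial[k] <- list(NULL)     # release memory without shifting
      }
      # single-scalar rescaling guards against underflow (applied to every
      # site pattern, so it contributes weight-summed log units)
      mx <- max(L)
      if (mx <= 0) return(-Inf)
      L <- L / mx
      logscale <- logscale + log(mx) * sum(patterns$weight)
    }
    partial[[u]] <- L
  }
  site <- as.numeric(pi_root %*% partial[[gs$root]])
  if (any(site <= 0)) return(-Inf)
  sum(log(site) * patterns$weight) + logscale
}
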