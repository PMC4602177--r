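#' Codon alignments
#'
#' A codon alignment stores, per sequence, the vector of codon triplets
#' (entries not matching an unambiguous ACGT triplet are treated as
#' missing).
#'
#' @param path FASTA file of aligned nucleotide sequences; the alignment
#'   length must be divisible by 3.
#' @return Object of class \code{codon_alignment}: \code{ids},
#'   \code{codons} (sequences x sites character matrix), \code{n_codons}.
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  codon_alignment(as.character(seqs), names(seqs))
}

#' Construct a codon alignment from character sequences
#' @param sequences character vector of equal-length nucleotide strings
#' @param ids sequence identifiers
#' @return A \code{codon_alignment}.
#' @export
codon_alignment <- function(sequences, ids = names(sequences)) {
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("all rows must have equal length")
  if (len %% 3 != 0) stop("alignment length must be divisible by 3")
  n_codons <- len %/% 3
  starts <- 3 * seq_len(n_codons) - 2
  codons <- t(vapply(toupper(sequences),
                     function(s) substring(s, starts, starts + 2),
                     character(n_codons)))
  rownames(codons) <- ids
  structure(list(ids = ids, codons = codons, n_codons = n_codons),
            class = "codon_alignment")
}

#' Write a codon alignment as FASTA
#' @param aln a \code{codon_alignment}
#' @param path output path
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", seqs), path)
}

# site-pattern compression: integer codon indices (NA = missing) per
# sequence x site, unique columns and their weights
compress_patterns <- function(aln, cs = codon_space()) {
  idx <- matrix(match(aln$codons, cs$codons), nrow = nrow(aln$codons))
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  list(idx = idx[, match(uk, key), drop = FALSE],
       weight = as.numeric(table(key)[uk]))
}
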