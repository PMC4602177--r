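#' Gene-tree states
#'
#' A gene-tree state couples a rooted gene tree \code{G} (binary apart from
#' a degree-one root and degree-two pseudogenization vertices), per-edge
#' lengths in expected substitutions per codon site, the set \code{Psi} of
#' pseudogenization vertices, and the classification of every leaf as a
#' gene or a pseudogene of a named species.
#'
#' @name gene_tree_state
NULL

new_gene_tree_state <- function(parent, children, edge_length, is_psi,
                                label, leaf_species, leaf_class) {
  n <- length(parent)
  is_leaf <- vapply(children, length, 1L) == 0L
  root <- which(is.na(parent))
  stopifnot(length(root) == 1L)
  structure(list(n = n, parent = parent, children = children,
                 edge_length = edge_length, is_psi = is_psi,
                 is_leaf = is_leaf, label = label,
                 leaf_species = leaf_species, leaf_class = leaf_class,
                 root = root),
            class = "gene_tree_state")
}

# postorder traversal (children before parents)
gene_postorder <- function(gs) {
  ord <- integer(0)
  walk <- function(v) {
    for (k in gs$children[[v]]) walk(k)
    ord[[length(ord) + 1L]] <<- v
  }
  walk(gs$root)
  unlist(ord)
}

# mode of the lineage immediately below each vertex: TRUE = pseudogene
mode_below <- function(gs) {
  out <- logical(gs$n)
  walk <- function(v, pseudo) {
    pseudo <- pseudo || gs$is_psi[v]
    out[v] <<- pseudo
    for (k in gs$children[[v]]) walk(k, pseudo)
  }
  walk(gs$root, FALSE)
  out
}

# mode of the edge above each vertex (pseudogene iff parent emits pseudogene
# lineages); NA for the root
edge_mode_pseudo <- function(gs) {
  mb <- mode_below(gs)
  out <- rep(NA, gs$n)
  for (v in seq_len(gs$n)) if (!is.na(gs$parent[v]))
    out[v] <- mb[gs$parent[v]]
  out
}

#' Validate a gene-tree state
#'
#' Checks the structural invariants: degree-one root, binary internal
#' vertices apart from degree-two pseudogenization vertices, positive edge
#' lengths, the pseudogenization vertices forming an antichain (no two on
#' one root-to-leaf path), every pseudogene leaf having a pseudogenization
#' ancestor, and no gene leaf below a pseudogenization vertex.
#'
#' @param gs a \code{gene_tree_state}
#' @return A list with \code{ok} (logical) and \code{violations}
#'   (character vector describing each failed invariant).
#' @export
validate_state <- function(gs) {
  v <- character(0)
  deg <- vapply(gs$children, length, 1L)
  if (deg[gs$root] != 1L) v <- c(v, "root must have exactly one child")
  for (u in seq_len(gs$n)) {
    if (u == gs$root) next
    if (gs$is_psi[u] && deg[u] != 1L)
      v <- c(v, sprintf("pseudogenization vertex %d is not degree two", u))
    if (!gs$is_psi[u] && !gs$is_leaf[u] && deg[u] != 2L)
      v <- c(v, sprintf("internal vertex %d is not binary", u))
    if (!is.na(gs$edge_length[u]) && gs$edge_length[u] <= 0)
      v <- c(v, sprintf("edge above vertex %d has non-positive length", u))
  }
  if (any(gs$is_psi[gs$is_leaf]))
    v <- c(v, "a leaf cannot be a pseudogenization vertex")
  # antichain + class consistency via lineage modes
  mb <- mode_below(gs)
  for (u in seq_len(gs$n)) {
    if (gs$is_psi[u] && !is.na(gs$parent[u]) && mb[gs$parent[u]])
      v <- c(v, sprintf(
        "nested pseudogenization vertices on one root-to-leaf path (at %d)", u))
  }
  for (u in which(gs$is_leaf)) {
    cls <- gs$leaf_class[u]
    if (is.na(cls) || !cls %in% c("gene", "pseudogene")) {
      v <- c(v, sprintf("leaf %s lacks a gene/pseudogene class", gs$label[u]))
      next
    }
    if (cls == "pseudogene" && !mb[u])
      v <- c(v, sprintf("pseudogene leaf %s has no pseudogenization ancestor",
                        gs$label[u]))
    if (cls == "gene" && mb[u])
      v <- c(v, sprintf("gene leaf %s descends from a pseudogenization vertex",
                        gs$label[u]))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Suppress pseudogenization vertices
#'
#' Removes every degree-two pseudogenization vertex, joining its two
#' incident edges into one (lengths summed), and records which edge of the
#' suppressed tree each removed vertex maps to.
#'
#' @param gs a valid \code{gene_tree_state}
#' @return A list with \code{tree} (a \code{gene_tree_state} with empty
#'   \code{Psi}), \code{origin} (integer vector over vertices of the
#'   suppressed tree: the original-vertex id of the pseudogenization vertex
#'   suppressed onto the edge above that vertex, or NA), and
#'   \code{orig_id} mapping suppressed-tree vertices to original ids.
#' @export
suppress <- function(gs) {
  keep <- !gs$is_psi
  new_id <- cumsum(keep)
  n2 <- sum(keep)
  parent2 <- rep(NA_integer_, n2)
  len2 <- rep(NA_real_, n2)
  origin2 <- rep(NA_integer_, n2)
  for (u in which(keep)) {
    nu <- new_id[u]
    p <- gs$parent[u]
    len <- gs$edge_length[u]
    org <- NA_integer_
    while (!is.na(p) && gs$is_psi[p]) {
      org <- p
      len <- len + gs$edge_length[p]
      p <- gs$parent[p]
    }
    parent2[nu] <- if (is.na(p)) NA_integer_ else new_id[p]
    len2[nu] <- len
    origin2[nu] <- org
  }
  children2 <- vector("list", n2)
  for (i in seq_len(n2)) children2[[i]] <- integer(0)
  for (i in seq_len(n2)) if (!is.na(parent2[i]))
    children2[[parent2[i]]] <- c(children2[[parent2[i]]], i)
  tree <- new_gene_tree_state(parent2, children2, len2,
                              rep(FALSE, n2),
                              gs$label[keep], gs$leaf_species[keep],
                              gs$leaf_class[keep])
  list(tree = tree, origin = origin2, orig_id = which(keep))
}

#' Species map sigma
#'
#' Maps every gene-tree vertex to the species-tree vertex it minimally
#' belongs to: leaves to their species leaf, internal vertices to the most
#' recent common ancestor of the species of their leaf descendants.
#'
#' @param gs a \code{gene_tree_state}
#' @param st a \code{dated_species_tree}
#' @return Integer vector over gene-tree vertices with species-tree
#'   vertex indices.
#' @export
sigma <- function(gs, st) {
  leaf_idx <- setNames(which(st$is_leaf), st$label[st$is_leaf])
  # species-tree depth for MRCA walks
  depth <- integer(st$n_vertices)
  walkd <- function(v, d) {
    depth[v] <<- d
    for (k in st$children[[v]]) walkd(k, d + 1L)
  }
  walkd(st$root, 0L)
  mrca2 <- function(a, b) {
    while (a != b) {
      if (depth[a] < depth[b]) b <- st$parent[b] else a <- st$parent[a]
    }
    a
  }
  sig <- rep(NA_integer_, gs$n)
  for (u in gene_postorder(gs)) {
    if (gs$is_leaf[u]) {
      sp <- gs$leaf_species[u]
      if (is.na(sp) || !sp %in% names(leaf_idx))
        stop("unknown species label: ", sp)
      sig[u] <- leaf_idx[[sp]]
    } else {
      kids <- gs$children[[u]]
      s <- sig[kids[1]]
      for (k in kids[-1]) s <- mrca2(s, sig[k])
      sig[u] <- s
    }
  }
  sig
}

#' Write a gene-tree state as Newick
#'
#' Degree-two pseudogenization vertices are serialized as singleton nodes
#' labeled \code{PSG}; the stem edge of the degree-one root becomes the
#' root edge.
#'
#' @param gs a \code{gene_tree_state}
#' @param digits significant digits for edge lengths
#' @return A Newick string.
#' @export
write_gene_tree <- function(gs, digits = 10) {
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(v) {
    lab <- if (gs$is_leaf[v]) gs$label[v]
           else if (gs$is_psi[v]) "PSG" else ""
    inner <- if (gs$is_leaf[v]) lab else
      paste0("(", paste(vapply(gs$children[[v]], rec, ""), collapse = ","),
             ")", lab)
    if (is.na(gs$parent[v])) inner
    else paste0(inner, ":", fmt(gs$edge_length[v]))
  }
  c0 <- gs$children[[gs$root]][1]
  paste0(rec(c0), ";")
}

#' Read a gene-tree state from Newick plus a leaf map
#'
#' @param newick_text Newick with branch lengths; singleton nodes labeled
#'   \code{PSG} are interpreted as pseudogenization vertices; a root edge,
#'   when present, is used as the stem edge length (otherwise
#'   \code{stem_length}).
#' @param leaf_map data.frame with columns \code{id}, \code{species},
#'   \code{class} (\code{gene}/\code{pseudogene}), as read by
#'   \code{\link{read_leaf_map}}.
#' @param stem_length stem edge length when no root edge is given.
#' @return A \code{gene_tree_state}.
#' @export
read_gene_tree <- function(newick_text, leaf_map, stem_length = 0.1) {
  phy <- ape::read.tree(text = newick_text)
  if (is.null(phy)) stop("could not parse gene-tree Newick")
  gene_tree_from_phylo(phy, leaf_map, stem_length = stem_length)
}

gene_tree_from_phylo <- function(phy, leaf_map, stem_length = 0.1) {
  ntip <- length(phy$tip.label)
  n0 <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n0)
  elen <- rep(NA_real_, n0)
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
    elen[phy$edge[i, 2]] <- phy$edge.length[i]
  }
  is_psi <- rep(FALSE, n0)
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    is_psi[ntip + seq_along(nl)] <- !is.na(nl) & nl == "PSG"
  }
  # append degree-one root above the phylo root
  root <- n0 + 1L
  phylo_root <- ntip + 1L
  parent <- c(parent, NA_integer_)
  parent[phylo_root] <- root
  elen[phylo_root] <- if (!is.null(phy$root.edge) && phy$root.edge > 0)
    phy$root.edge else stem_length
  elen <- c(elen, NA_real_)
  is_psi <- c(is_psi, FALSE)
  label <- c(phy$tip.label, rep(NA_character_, phy$Nnode + 1L))
  leaf_species <- rep(NA_character_, root)
  leaf_class <- rep(NA_character_, root)
  m <- match(phy$tip.label, leaf_map$id)
  if (anyNA(m)) stop("leaf map is missing ids: ",
                     paste(phy$tip.label[is.na(m)], collapse = ", "))
  leaf_species[seq_len(ntip)] <- leaf_map$species[m]
  leaf_class[seq_len(ntip)] <- leaf_map$class[m]
  children <- vector("list", root)
  for (i in seq_len(root)) children[[i]] <- integer(0)
  for (i in seq_len(root)) if (!is.na(parent[i]))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  new_gene_tree_state(parent, children, elen, is_psi, label,
                      leaf_species, leaf_class)
}

#' Read a leaf classification map
#'
#' Three-column tab-separated file: sequence id, species name, and class
#' (\code{gene} or \code{pseudogene}).
#'
#' @param path file path
#' @return data.frame with columns \code{id}, \code{species}, \code{class}.
#' @export
read_leaf_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("id", "species", "class"),
                   stringsAsFactors = FALSE)
  if (!all(df$class %in% c("gene", "pseudogene")))
    stop("leaf classes must be 'gene' or 'pseudogene'")
  df
}

#' Write a leaf classification map
#' @param gs a \code{gene_tree_state}
#' @param path output path
#' @export
write_leaf_map <- function(gs, path) {
  lv <- which(gs$is_leaf)
  write.table(data.frame(id = gs$label[lv], species = gs$leaf_species[lv],
                         class = gs$leaf_class[lv]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

# canonical topology string of the tree with Psi suppressed: identifies the
# suppressed topology up to leaf-labeled isomorphism
canonical_topology <- function(gs) {
  sup <- if (any(gs$is_psi)) suppress(gs)$tree else gs
  rec <- function(v) {
    if (sup$is_leaf[v]) return(sup$label[v])
    kids <- sort(vapply(sup$children[[v]], rec, ""))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  rec(sup$children[[sup$root]][1])
}

# leaf set (sorted labels) below each vertex; used as stable edge identity
clade_signatures <- function(gs) {
  sig <- character(gs$n)
  for (u in gene_postorder(gs)) {
    sig[u] <- if (gs$is_leaf[u]) gs$label[u] else
      paste(sort(unlist(strsplit(
        vapply(gs$children[[u]], function(k) sig[k], ""), "\\|"))),
        collapse = "|")
  }
  sig
}
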