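# Species-map plumbing: leaf maps, the LCA species map, species-tree pruning,
# implied-node insertion and the per-species decomposition of the gene tree.
#
# Conventions: a "species branch" is the edge above species node s; a gene
# node assigned to s lives in that edge.  After add_implied_nodes() every
# gene branch spans exactly one species branch: for each branch (p, g) either
# M(p) == M(g) or M(p) is the species parent of M(g) and p is a bottom of
# M(p).

#' Read a gene-leaf to species-leaf map from two-column TSV text
#'
#' Each non-empty line is `gene_label<TAB>species_label`.  Labels are matched
#' exactly; the map need not be one-to-one nor onto.
#'
#' @param text a character scalar (TSV content) or a file path.
#' @return a named character vector: `names` are gene-leaf labels, values are
#'   species-leaf labels.
#' @export
read_leaf_map <- function(text) {
  if (length(text) == 1L && !grepl("[\t\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty leaf map")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed leaf-map line: ", lines[bad][1L])
  genes <- vapply(parts, `[[`, "", 1L)
  sps <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    conflict <- vapply(dup, function(g) length(unique(sps[genes == g])) > 1L,
                       TRUE)
    if (any(conflict))
      stop("gene label mapped to multiple species: ",
           paste(dup[conflict], collapse = ", "))
    keep <- !duplicated(genes)
    genes <- genes[keep]; sps <- sps[keep]
  }
  stats::setNames(sps, genes)
}

# validate the leaf map against a gene tree and a species tree;
# returns integer vector: gene leaf id -> species leaf id
pair_leaf_map <- function(G, S, leaf_map) {
  gl <- tree_leaves(G)
  sl <- tree_leaves(S)
  sp_of <- stats::setNames(sl, S$label[sl])
  missing_g <- setdiff(G$label[gl], names(leaf_map))
  if (length(missing_g))
    stop("leaf map omits gene leaves: ", paste(missing_g, collapse = ", "))
  used <- leaf_map[G$label[gl]]
  bad <- setdiff(unique(used), names(sp_of))
  if (length(bad))
    stop("leaf map targets unknown species leaves: ",
         paste(bad, collapse = ", "))
  out <- rep(NA_integer_, n_nodes(G))
  out[gl] <- as.integer(sp_of[leaf_map[G$label[gl]]])
  out
}

#' Compute the LCA species map
#'
#' Maps every gene-tree node to the lowest common ancestor in the species
#' tree of the species of its descendant leaves.  This is the unique optimal
#' species map under the DLC model.
#'
#' @param G gene tree (`dlc_tree`).
#' @param S species tree (`dlc_tree`).
#' @param leaf_map named character vector from [read_leaf_map()].
#' @return integer vector of length `n_nodes(G)`: gene node id -> species
#'   node id.
#' @export
lca_species_map <- function(G, S, leaf_map) {
  M <- pair_leaf_map(G, S, leaf_map)
  depths <- tree_depths(S)
  for (v in rev(tree_preorder(G))) {
    kids <- G$children[[v]]
    if (length(kids))
      M[v] <- tree_lca(S, M[kids], depths)
  }
  M
}

#' Prune the species tree to the subtree relevant to the gene family
#'
#' Restricts `S` to the subtree rooted at the species image of the gene-tree
#' root.  Species outside that subtree can host no part of any reconciliation.
#'
#' @inheritParams lca_species_map
#' @param M the LCA species map from [lca_species_map()].
#' @return list with `tree` (pruned species tree, pre-order ids) and
#'   `old2new` (id translation for remapping `M`).
#' @export
prune_to_root <- function(S, M, G) {
  new_root <- M[G$root]
  keep <- sort(which(vapply(seq_len(n_nodes(S)), function(v)
    is_ancestor(S, new_root, v), TRUE)))
  old2new <- rep(NA_integer_, n_nodes(S))
  old2new[keep] <- seq_along(keep)
  parent <- old2new[S$parent[keep]]
  parent[keep == new_root] <- NA_integer_
  children <- lapply(S$children[keep], function(k) old2new[k])
  pruned <- renumber_preorder(
    new_tree(parent, children, S$label[keep], old2new[new_root], "species"))
  old2new[keep] <- pruned$old2new[old2new[keep]]
  list(tree = pruned$tree, old2new = old2new)
}

#' Insert implied nodes so each gene branch spans one species branch
#'
#' For every gene branch whose endpoints map to different species, one
#' single-child node is inserted at each species boundary the branch crosses:
#' at every intermediate species on the path, and additionally at `M(p)`
#' itself when the parent node `p` sits strictly inside its species branch
#' (i.e. `p` has another child mapping to the same species), so that every
#' crossing branch starts at a bottom node of the upper species.
#'
#' @param G gene tree.
#' @param S (pruned) species tree.
#' @param M species map of `G` into `S`.
#' @return list with `tree` (gene tree with implied nodes, renumbered in
#'   pre-order), `M` (extended map) and `old2new` (gene id translation).
#' @export
add_implied_nodes <- function(G, S, M) {
  parent <- G$parent; children <- G$children; label <- G$label
  Mx <- M
  n0 <- n_nodes(G)
  # decided on the *original* topology: the parent stays strictly inside its
  # species branch iff another original child maps to the same species
  needs_boundary <- vapply(seq_len(n0), function(g) {
    p <- G$parent[g]
    if (is.na(p) || M[p] == M[g]) return(FALSE)
    any(M[setdiff(G$children[[p]], g)] == M[p])
  }, TRUE)
  for (g in seq_len(n0)) {
    p <- G$parent[g]
    if (is.na(p) || M[p] == M[g]) next
    # species path from M[g] (exclusive) up to M[p] (inclusive)
    path <- integer(0)
    v <- S$parent[M[g]]
    while (!is.na(v) && v != M[p]) { path <- c(path, v); v <- S$parent[v] }
    if (is.na(v))
      stop("species map is not hierarchical on branch ", p, "->", g)
    if (needs_boundary[g]) path <- c(path, M[p])
    # path is bottom-up; build chain top-down from p
    cur <- p
    for (sp in rev(path)) {
      new_id <- length(parent) + 1L
      parent[new_id] <- cur
      children[[new_id]] <- integer(0)
      label[new_id] <- NA_character_
      Mx[new_id] <- sp
      children[[cur]][children[[cur]] == g] <- new_id
      parent[g] <- new_id
      children[[new_id]] <- g
      cur <- new_id
    }
  }
  ren <- renumber_preorder(new_tree(parent, children, label, G$root, G$role))
  M2 <- integer(length(Mx))
  M2[ren$old2new] <- Mx
  list(tree = ren$tree, M = M2, old2new = ren$old2new[seq_len(n0)])
}

#' Decompose the gene tree by species branch
#'
#' Computes, for every species node `s`: `nodes(s)` (gene nodes mapped to
#' `s`), `bottoms(s)` (the subset that are leaves or whose children all map
#' below `s`), `tops(s)` (`bottoms` of the parent species, or the gene root
#' for the species root), and the width `k`.  All sequences are in canonical
#' order (pre-order id of the implied gene tree).
#'
#' @param G gene tree with implied nodes.
#' @param S pruned species tree.
#' @param M extended species map.
#' @return an object of class `dlc_decomposition`.
#' @export
decompose <- function(G, S, M) {
  ns <- n_nodes(S)
  nodes <- vector("list", ns); bottoms <- vector("list", ns)
  tops <- vector("list", ns)
  for (s in seq_len(ns)) nodes[[s]] <- integer(0)
  for (g in seq_len(n_nodes(G))) nodes[[M[g]]] <- c(nodes[[M[g]]], g)
  for (s in seq_len(ns)) {
    nodes[[s]] <- sort(nodes[[s]])
    bottoms[[s]] <- sort(Filter(function(g) {
      kids <- G$children[[g]]
      !length(kids) || !any(M[kids] == s)
    }, nodes[[s]]))
  }
  for (s in tree_preorder(S)) {
    tops[[s]] <- if (is.na(S$parent[s])) G$root else bottoms[[S$parent[s]]]
  }
  # sanity: each gene branch spans exactly one species branch
  for (g in seq_len(n_nodes(G))) {
    p <- G$parent[g]
    if (is.na(p)) next
    if (M[p] != M[g] && !(identical(S$parent[M[g]], M[p]) && p %in% bottoms[[M[p]]]))
      stop("internal error: branch ", p, "->", g,
           " spans more than one species branch")
  }
  k <- max(1L, vapply(seq_len(ns), function(s)
    max(length(tops[[s]]), length(bottoms[[s]])), 1L))
  # ancestor-or-equal lookup over the implied gene tree
  ng <- n_nodes(G)
  anc <- matrix(FALSE, ng, ng)
  for (g in tree_preorder(G)) {
    p <- G$parent[g]
    if (!is.na(p)) anc[, g] <- anc[, p]
    anc[g, g] <- TRUE
  }
  # flag-independent helpers: per-top children inside s, and the tops whose
  # lineage enters s at all
  top_kids <- vector("list", ns)
  entering <- vector("list", ns)
  for (s in seq_len(ns)) {
    tk <- lapply(tops[[s]], function(t) intersect(G$children[[t]], nodes[[s]]))
    top_kids[[s]] <- tk
    entering[[s]] <- tops[[s]][vapply(tk, length, 1L) > 0L]
  }
  structure(list(G = G, S = S, M = M, nodes = nodes, bottoms = bottoms,
                 tops = tops, k = k, anc = anc, top_kids = top_kids,
                 entering = entering),
            class = "dlc_decomposition")
}

#' @export
print.dlc_decomposition <- function(x, ...) {
  cat(sprintf("<dlc_decomposition: %d species, %d gene nodes, width k=%d>\n",
              n_nodes(x$S), n_nodes(x$G), x$k))
  invisible(x)
}

#' Prepare an instance end to end
#'
#' Convenience pipeline: LCA map, species-tree pruning, implied-node
#' insertion and decomposition.
#'
#' @inheritParams lca_species_map
#' @return a `dlc_decomposition` (fields `G`, `S`, `M` hold the implied gene
#'   tree, pruned species tree and extended map).
#' @export
prepare_instance <- function(G, S, leaf_map) {
  M <- lca_species_map(G, S, leaf_map)
  pr <- prune_to_root(S, M, G)
  M2 <- pr$old2new[M]
  im <- add_implied_nodes(G, pr$tree, M2)
  decompose(im$tree, pr$tree, im$M)
}

# display label for a species node
species_label <- function(S, s) {
  lab <- S$label[[s]]
  if (!is.na(lab)) lab else sprintf("s%d", s)
}
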