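# Rooted trees with parent/child links and stable pre-order node ids.
#
# Input trees must be binary; single-child ("implied") nodes are created only
# internally by add_implied_nodes() and are never written back out.  Node ids
# are pre-order indices (root = 1), which serve as the canonical ordering for
# tops/bottoms sequences and as the stable ids in event payloads.

#' Construct a dlc_tree from parent/child vectors
#'
#' @param parent integer vector, `NA` for the root.
#' @param children list of integer vectors (may be empty for leaves).
#' @param label character vector, `NA` for unlabeled internal nodes.
#' @param root index of the root node.
#' @param role `"gene"` or `"species"`.
#' @return an object of class `dlc_tree`.
#' @keywords internal
new_tree <- function(parent, children, label, root, role) {
  structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), root = as.integer(root), role = role),
    class = "dlc_tree")
}

#' Number of nodes of a dlc_tree
#' @param tree a `dlc_tree`.
#' @return integer count of nodes (leaves plus internal, including implied).
#' @export
n_nodes <- function(tree) length(tree$parent)

tree_is_leaf <- function(tree, v) length(tree$children[[v]]) == 0L

#' Leaf node ids of a dlc_tree
#' @param tree a `dlc_tree`.
#' @return integer vector of leaf node ids (pre-order numbering).
#' @export
tree_leaves <- function(tree) {
  which(vapply(tree$children, length, 1L) == 0L)
}

#' Pre-order traversal of a dlc_tree
#' @return integer vector of node ids in pre-order.
#' @keywords internal
tree_preorder <- function(tree) {
  out <- integer(n_nodes(tree))
  stack <- tree$root
  i <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[[i]] <- v
    kids <- tree$children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

# Renumber nodes so ids are pre-order indices; returns list(tree, old2new).
renumber_preorder <- function(tree) {
  ord <- tree_preorder(tree)
  old2new <- integer(n_nodes(tree))
  old2new[ord] <- seq_along(ord)
  parent <- tree$parent[ord]
  parent <- ifelse(is.na(parent), NA_integer_, old2new[parent])
  children <- lapply(tree$children[ord], function(k) old2new[k])
  list(tree = new_tree(parent, children, tree$label[ord], 1L, tree$role),
       old2new = old2new)
}

#' Read a rooted binary tree from a Newick string
#'
#' Parses a strict rooted binary Newick tree.  Every internal node must have
#' exactly two children and leaf labels must be unique.  A bare single leaf
#' (`"a;"`) is accepted as the degenerate one-node tree.
#'
#' @param text a Newick string.
#' @param role `"gene"` or `"species"`.
#' @return a `dlc_tree` with nodes numbered in pre-order.
#' @export
#' @examples
#' tr <- read_newick("((a,b),c);", role = "gene")
read_newick <- function(text, role = c("gene", "species")) {
  role <- match.arg(role)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (grepl("^[^();,:[:space:]]+;?$", text)) {
    lab <- sub(";$", "", text)
    return(new_tree(NA_integer_, list(integer(0)), lab, 1L, role))
  }
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph) || !inherits(ph, "phylo"))
    stop("failed to parse Newick string")
  ntip <- length(ph$tip.label)
  if (ntip < 2L) stop("tree must have at least one leaf")
  nn <- ntip + ph$Nnode
  parent <- rep(NA_integer_, nn)
  children <- vector("list", nn)
  for (i in seq_len(nn)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1L]; c <- ph$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must be rooted")
  deg <- vapply(children, length, 1L)
  if (any(deg != 0L & deg != 2L))
    stop("tree must be strictly binary (found a node with ",
         paste(unique(deg[deg != 0L & deg != 2L]), collapse = "/"),
         " children)")
  labs <- c(ph$tip.label, if (!is.null(ph$node.label)) ph$node.label else
    rep(NA_character_, ph$Nnode))
  labs[labs == ""] <- NA_character_
  tips <- labs[seq_len(ntip)]
  if (anyDuplicated(tips))
    stop("duplicate leaf labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  renumber_preorder(new_tree(parent, children, labs, root, role))$tree
}

#' Write a dlc_tree as a Newick string
#'
#' Unary (implied) nodes are suppressed: the tree is written as its binary
#' topology over original nodes.
#'
#' @param tree a `dlc_tree`.
#' @return a Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  emit <- function(v) {
    kids <- tree$children[[v]]
    while (length(kids) == 1L) { # skip implied nodes
      v <- kids
      kids <- tree$children[[v]]
    }
    if (!length(kids)) return(tree$label[[v]])
    inner <- paste(vapply(kids, emit, ""), collapse = ",")
    lab <- tree$label[[v]]
    paste0("(", inner, ")", if (!is.na(lab)) lab else "")
  }
  paste0(emit(tree$root), ";")
}

#' @export
print.dlc_tree <- function(x, ...) {
  cat(sprintf("<dlc_tree role=%s, %d nodes, %d leaves>\n  %s\n",
              x$role, n_nodes(x), length(tree_leaves(x)), write_newick(x)))
  invisible(x)
}

# depth of every node (root = 0)
tree_depths <- function(tree) {
  d <- integer(n_nodes(tree))
  for (v in tree_preorder(tree))
    d[v] <- if (is.na(tree$parent[v])) 0L else d[tree$parent[v]] + 1L
  d
}

# TRUE iff a is an ancestor of (or equal to) b
is_ancestor <- function(tree, a, b, strict = FALSE) {
  if (a == b) return(!strict)
  v <- b
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    if (v == a) return(TRUE)
  }
  FALSE
}

# lowest common ancestor of a set of node ids
tree_lca <- function(tree, ids, depths = tree_depths(tree)) {
  ids <- unique(as.integer(ids))
  v <- ids[[1L]]
  for (w in ids[-1L]) {
    while (depths[v] > depths[w]) v <- tree$parent[v]
    while (depths[w] > depths[v]) w <- tree$parent[w]
    while (v != w) { v <- tree$parent[v]; w <- tree$parent[w] }
  }
  v
}
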