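# Synthetic instance generator: species tree by random joins, gene tree by a
# forward birth-death simulation inside the species tree (duplications copy a
# lineage within its species branch, losses kill it, every surviving lineage
# is inherited by both daughter species at a speciation), plus optional
# random NNI perturbations of the finished gene tree to induce ILS-like
# incongruence.  With all knobs at zero the instance is congruent (width
# k = 1, one gene per species).

#' Describe a synthetic instance
#'
#' @param n_species number of extant species (>= 1).
#' @param genes_per_species expected number of genes sampled per extant
#'   species; values above 1 add terminal-branch duplications.
#' @param dup_rate expected duplications per gene lineage per species branch.
#' @param loss_rate probability that a gene lineage dies within a species
#'   branch.
#' @param ils_rate expected NNI perturbations per internal gene node,
#'   inducing incongruence that the DLC model explains by deep coalescence.
#' @param seed integer seed; identical specs generate identical instances.
#' @return an object of class `dlc_instance_spec`.
#' @export
instance_spec <- function(n_species = 4L, genes_per_species = 1,
                          dup_rate = 0, loss_rate = 0, ils_rate = 0,
                          seed = 1L) {
  stopifnot(n_species >= 1L, genes_per_species >= 1, dup_rate >= 0,
            loss_rate >= 0, loss_rate < 1, ils_rate >= 0)
  structure(list(n_species = as.integer(n_species),
                 genes_per_species = genes_per_species,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 ils_rate = ils_rate, seed = as.integer(seed)),
            class = "dlc_instance_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

species_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("S%02d", seq_len(n))
}

# random rooted binary species tree over n labeled leaves (uniform joins)
random_species_tree <- function(n) {
  labs <- species_labels(n)
  if (n == 1L) return(new_tree(NA_integer_, list(integer(0)), labs, 1L,
                               "species"))
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer(0)), n)
  label <- labs
  roots <- seq_len(n)
  while (length(roots) > 1L) {
    pick <- sample(length(roots), 2L)
    new_id <- length(parent) + 1L
    parent[new_id] <- NA_integer_
    children[[new_id]] <- roots[pick]
    label[new_id] <- NA_character_
    parent[roots[pick]] <- new_id
    roots <- c(roots[-pick], new_id)
  }
  renumber_preorder(new_tree(parent, children, label, roots, "species"))$tree
}

#' Generate a synthetic reconciliation instance
#'
#' @param spec an `dlc_instance_spec`.
#' @param max_lineages abort and resample if the simulation exceeds this
#'   many concurrent gene lineages.
#' @return list with `G` (gene tree), `S` (species tree), `leaf_map` and
#'   `spec`.
#' @export
generate_instance <- function(spec, max_lineages = 256L) {
  stopifnot(inherits(spec, "dlc_instance_spec"))
  with_seed(spec$seed, {
    S <- random_species_tree(spec$n_species)
    for (attempt in seq_len(64L)) {
      res <- simulate_gene_tree(S, spec, max_lineages)
      if (!is.null(res)) return(c(res, list(S = S, spec = spec)))
    }
    stop("failed to generate a non-empty gene tree in 64 attempts")
  })
}

simulate_gene_tree <- function(S, spec, max_lineages) {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0); env$children <- list()
  env$label <- character(0)
  new_node <- function(p) {
    id <- length(env$parent) + 1L
    env$parent[id] <- p
    env$children[[id]] <- integer(0)
    env$label[id] <- NA_character_
    if (!is.na(p)) env$children[[p]] <- c(env$children[[p]], id)
    id
  }
  root <- new_node(NA_integer_)
  alive_leaves <- character(0)
  overflow <- FALSE

  recurse <- function(s, entering) {
    # entering: gene node ids whose branch continues into species s
    lineages <- entering
    for (t in entering) {
      if (overflow) return(invisible())
      if (stats::runif(1) < spec$loss_rate) {
        lineages <- setdiff(lineages, t)
        next
      }
      extra <- if (length(S$children[[s]]) == 0L &&
                   spec$genes_per_species > 1)
        stats::rpois(1, spec$dup_rate) +
          stats::rpois(1, spec$genes_per_species - 1)
      else stats::rpois(1, spec$dup_rate)
      tip <- t
      for (k in seq_len(extra)) {
        a <- new_node(tip); b <- new_node(tip)  # split: continue + new copy
        lineages <- c(setdiff(lineages, tip), a, b)
        tip <- a
      }
    }
    if (length(lineages) > max_lineages) { overflow <<- TRUE; return(invisible()) }
    kids <- S$children[[s]]
    if (!length(kids)) {
      for (t in lineages) {
        env$label[t] <- sprintf("%s_%d", species_label(S, s), t)
        alive_leaves <<- c(alive_leaves, env$label[t])
      }
    } else {
      # each surviving lineage is inherited by both daughter species
      left <- integer(0); right <- integer(0)
      for (t in lineages) {
        a <- new_node(t); b <- new_node(t)
        left <- c(left, a); right <- c(right, b)
      }
      recurse(kids[[1L]], left)
      recurse(kids[[2L]], right)
    }
  }
  recurse(S$root, root)
  if (overflow || !length(alive_leaves)) return(NULL)

  G <- prune_dead(new_tree(env$parent, env$children, env$label, root, "gene"))
  if (is.null(G)) return(NULL)
  if (spec$ils_rate > 0) G <- perturb_nni(G, spec$ils_rate)
  leaves <- tree_leaves(G)
  lm <- stats::setNames(sub("_[0-9]+$", "", G$label[leaves]),
                        G$label[leaves])
  list(G = G, leaf_map = lm)
}

# keep only labeled leaves; drop dead subtrees and suppress unary nodes
prune_dead <- function(G) {
  n <- n_nodes(G)
  keep <- logical(n)
  post <- rev(tree_preorder(G))
  for (v in post) {
    kids <- G$children[[v]]
    keep[v] <- if (!length(kids)) !is.na(G$label[v]) else any(keep[kids])
  }
  if (!keep[G$root]) return(NULL)
  # rebuild with suppression of single-child nodes
  parent <- integer(0); children <- list(); label <- character(0)
  add <- function(p) {
    id <- length(parent) + 1L
    parent[id] <<- p; children[[id]] <<- integer(0)
    label[id] <<- NA_character_
    if (!is.na(p)) children[[p]] <<- c(children[[p]], id)
    id
  }
  build <- function(v, p) {
    kids <- G$children[[v]][keep[G$children[[v]]]]
    while (length(kids) == 1L) {
      v <- kids
      kids <- G$children[[v]][keep[G$children[[v]]]]
    }
    id <- add(p)
    if (!length(kids)) label[id] <<- G$label[v]
    else for (k in kids) build(k, id)
    id
  }
  build(G$root, NA_integer_)
  renumber_preorder(new_tree(parent, children, label, 1L, "gene"))$tree
}

# random NNI moves on internal edges
perturb_nni <- function(G, rate) {
  n_int <- sum(vapply(G$children, length, 1L) > 0L)
  moves <- stats::rpois(1, rate * n_int)
  for (m in seq_len(moves)) {
    internal_edges <- which(!is.na(G$parent) &
                              vapply(G$children, length, 1L) > 0L)
    if (!length(internal_edges)) break
    v <- if (length(internal_edges) == 1L) internal_edges else
      sample(internal_edges, 1L)
    p <- G$parent[v]
    sib <- setdiff(G$children[[p]], v)
    ck <- G$children[[v]]
    move_child <- if (length(ck) == 1L) ck else sample(ck, 1L)
    # swap move_child with sib
    G$children[[p]] <- c(setdiff(G$children[[p]], sib), move_child)
    G$children[[v]] <- c(setdiff(G$children[[v]], move_child), sib)
    G$parent[move_child] <- p
    G$parent[sib] <- v
  }
  renumber_preorder(G)$tree
}
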