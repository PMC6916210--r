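# Tile enumeration and the stitching dynamic program.
#
# A tile is one sub-locus map for a species branch together with its folded
# descriptor (a single Pareto-optimal event count: duplications and losses
# are order-independent, so only the coalescence-minimal sub-partial orders
# survive, and kappa counts them).  Tiles are keyed by their relative locus
# pair (t, b) -- the label-free encoding of loci at tops and bottoms -- plus
# the continuation profile chi: the subset of top loci that continue
# un-duplicated into the branch.  chi is what lets the stitch emit exact
# speciation events ("bottom locus of s continues into at least one child")
# with exact frequencies.
#
# Recurrences (per top pattern t, continuation profile chi):
#   leaf s:      F(t, chi) = oplus over realized b of C(t, b, chi)
#   internal s:  F(t, b, chi) =
#       oplus over child profiles (chi', chi'') of
#         F_left(b*, chi') (x) F_right(b*, chi'') (x) C(t, b, chi)
#           (x) { speciation events for b-loci continuing per chi' u chi'' }
#   F(t, chi) = oplus over b of F(t, b, chi)
# where b* is b re-indexed dense as the children's top pattern.  The final
# front is the oplus over chi of F at the species root.

# non-empty string key for a (possibly empty) integer pattern: R lists
# cannot be indexed by the empty-string name
pattern_key <- function(p) paste0("p", paste(p, collapse = ","))

# first-occurrence dense renumbering, e.g. c(2,2,5,2) -> c(1,1,2,1)
dense_pattern <- function(values) {
  if (!length(values)) return(integer(0))
  match(values, unique(values))
}

#' Relative locus pair of a sub-locus map
#'
#' Label-free encoding of the loci at tops and bottoms: the concatenated
#' tops-then-bottoms locus sequence is renumbered densely by first
#' occurrence.  Two sub-locus maps receive the same pair iff they are
#' identical up to locus renaming on tops and bottoms.
#'
#' @param slm a `dlc_slm`.
#' @param dec the matching `dlc_decomposition`.
#' @return list with integer vectors `t` and `b`.
#' @export
relative_pair <- function(slm, dec) {
  tv <- slm$locus[slm$tops]
  bv <- slm$locus[slm$bottoms]
  dense <- dense_pattern(c(tv, bv))
  list(t = dense[seq_along(tv)],
       b = dense[seq_along(bv) + length(tv)])
}

# descriptor for one sub-locus map: base events plus the fold over all
# sub-partial orders (coalescence-minimal ones survive; kappa counts them)
tile_descriptor <- function(slm, dec) {
  base <- count_events(slm, list(), dec)
  desc <- desc_new(base$v, 1,
                   stats::setNames(rep(1, length(base$events)), base$events))
  for (l in mother_loci(slm, dec)) {
    elems <- order_elements(slm, dec, l)
    exts <- linear_extensions(elems, order_prec_matrix(dec, elems))
    res <- lapply(exts, function(o) coal_at_dups(slm, dec, l, o))
    cc <- vapply(res, `[[`, 0L, "c")
    kept <- res[cc == min(cc)]
    ev <- unlist(lapply(kept, `[[`, "events"))
    evv <- if (is.null(ev)) numeric(0) else {
      u <- unique(ev)
      stats::setNames(as.numeric(tabulate(match(ev, u), length(u))), u)
    }
    desc <- add_descriptors(
      desc, desc_new(c(0L, 0L, min(cc)), length(kept), evv))
  }
  desc
}

#' Enumerate the tiles of a species branch for one top pattern
#'
#' Every subset of the gene branches inside `s` is flagged as duplications
#' (loci are inherited elsewhere); sub-locus maps violating bottom-locus
#' distinctness at extant species are discarded.  Each surviving sub-locus
#' map yields one tile: the map, its descriptor, its relative locus pair and
#' its continuation profile.
#'
#' @param s species node id.
#' @param top_pattern dense integer pattern over the canonical tops of `s`.
#' @param dec a `dlc_decomposition`.
#' @return list of tiles (each a list `slm`, `desc`, `t`, `b`, `chi`).
#' @export
enumerate_tiles <- function(s, top_pattern, dec) {
  G <- dec$G
  nodes <- dec$nodes[[s]]
  branch_children <- setdiff(nodes, G$root)
  is_leaf_sp <- length(dec$S$children[[s]]) == 0L
  nb <- length(branch_children)
  tiles <- list()
  for (mask in 0:(2^nb - 1L)) {
    flags <- branch_children[bitwAnd(mask, bitwShiftL(1L, seq_len(nb) - 1L)) > 0L]
    slm <- sublocus_map(dec, s, top_pattern, flags)
    if (is_leaf_sp && anyDuplicated(slm$locus[slm$bottoms])) next
    rp <- relative_pair(slm, dec)
    tiles[[length(tiles) + 1L]] <-
      list(slm = slm, desc = tile_descriptor(slm, dec),
           t = rp$t, b = rp$b, chi = continuation_profile(slm, dec))
  }
  tiles
}

#' Build the per-species tile tables
#'
#' Pre-order traversal: the reachable top patterns of each species are the
#' dense re-indexings of the realized bottom patterns of its parent.  For
#' each species and reachable top pattern, tiles are grouped by
#' (bottom pattern, continuation profile) and their descriptors folded with
#' the Pareto union.
#'
#' @param dec a `dlc_decomposition`.
#' @return an object of class `dlc_tiletable`: per species, a list keyed by
#'   top-pattern of entries `C` (keyed by `"b|chi"`) and `bpatterns`.
#' @export
build_tile_tables <- function(dec) {
  S <- dec$S
  ns <- n_nodes(S)
  patterns <- vector("list", ns)   # per species: named list tkey -> t
  tables <- vector("list", ns)
  root_t <- c(1L)
  patterns[[S$root]] <- stats::setNames(list(root_t), pattern_key(root_t))
  for (s in tree_preorder(S)) {
    tables[[s]] <- list()
    for (tkey in names(patterns[[s]])) {
      tpat <- patterns[[s]][[tkey]]
      tiles <- enumerate_tiles(s, tpat, dec)
      C <- list(); bpat <- list()
      for (tl in tiles) {
        bk <- pattern_key(tl$b); ck <- pattern_key(tl$chi)
        key <- paste(bk, ck, sep = "|")
        if (is.null(C[[key]]))
          C[[key]] <- list(b = tl$b, chi = tl$chi, descs = list(tl$desc))
        else
          C[[key]]$descs <- oplus(C[[key]]$descs, list(tl$desc))
        bpat[[bk]] <- tl$b
      }
      tables[[s]][[tkey]] <- list(C = C, bpatterns = bpat)
      for (child in S$children[[s]]) {
        for (bk in names(bpat)) {
          tb <- dense_pattern(bpat[[bk]])
          tbk <- pattern_key(tb)
          if (is.null(patterns[[child]][[tbk]])) {
            if (is.null(patterns[[child]]))
              patterns[[child]] <- stats::setNames(list(tb), tbk)
            else patterns[[child]][[tbk]] <- tb
          }
        }
      }
    }
  }
  structure(list(tables = tables, patterns = patterns, dec = dec),
            class = "dlc_tiletable")
}

# speciation-event descriptor for bottom loci of s that continue into a child
speciation_descriptor <- function(s, b, bottoms, cont_values) {
  if (!length(cont_values)) return(desc_new(c(0L, 0L, 0L), 1, numeric(0)))
  ids <- vapply(cont_values, function(v)
    sprintf("spec|%d|%s", s, join_ids(bottoms[b == v])), "")
  desc_new(c(0L, 0L, 0L), 1, stats::setNames(rep(1, length(ids)), ids))
}

#' Stitch tile tables into the global Pareto-optimal descriptor set
#'
#' Post-order dynamic program over the species tree combining children
#' solutions with the species' own tiles; speciation events for the bottom
#' loci of each internal species are materialized here from the children's
#' continuation profiles.
#'
#' @param tiletab a `dlc_tiletable` from [build_tile_tables()].
#' @param dec the matching `dlc_decomposition` (defaults to the one stored in
#'   `tiletab`).
#' @return list of Pareto-optimal descriptors for the full reconciliation.
#' @export
stitch <- function(tiletab, dec = tiletab$dec) {
  S <- dec$S
  memo <- new.env(parent = emptyenv())

  # F(s, t) is a named list keyed by continuation-profile: each entry holds
  # the profile vector `chi` and the Pareto descriptor set `descs`
  Fsub <- function(s, tkey) {
    mkey <- paste(s, tkey, sep = "#")
    if (!is.null(memo[[mkey]])) return(memo[[mkey]])
    entry <- tiletab$tables[[s]][[tkey]]
    out <- list()
    put <- function(chi, descs) {
      ck <- pattern_key(chi)
      if (is.null(out[[ck]]))
        out[[ck]] <<- list(chi = chi, descs = descs)
      else out[[ck]]$descs <<- oplus(out[[ck]]$descs, descs)
    }
    if (is.null(entry)) { memo[[mkey]] <- out; return(out) }
    kids <- S$children[[s]]
    if (!length(kids)) {
      for (key in names(entry$C))
        put(entry$C[[key]]$chi, entry$C[[key]]$descs)
    } else {
      bottoms <- dec$bottoms[[s]]
      for (key in names(entry$C)) {
        Ce <- entry$C[[key]]
        b <- Ce$b
        tb <- dense_pattern(b)
        F1 <- Fsub(kids[[1L]], pattern_key(tb))
        F2 <- Fsub(kids[[2L]], pattern_key(tb))
        if (!length(F1) || !length(F2)) next
        uvals <- unique(b)
        for (e1 in F1) for (e2 in F2) {
          chi_union <- sort(unique(c(e1$chi, e2$chi)))
          # child profiles are in the child's dense numbering, which maps
          # the i-th distinct value of b to i
          cont_values <- uvals[chi_union[chi_union <= length(uvals)]]
          sd <- speciation_descriptor(s, b, bottoms, cont_values)
          combo <- otimes(otimes(e1$descs, e2$descs), Ce$descs)
          combo <- otimes(combo, list(sd))
          put(Ce$chi, combo)
        }
      }
    }
    out <- Filter(function(e) length(e$descs), out)
    memo[[mkey]] <- out
    out
  }

  root_out <- Fsub(S$root, pattern_key(c(1L)))
  if (!length(root_out)) stop("stitch produced no feasible reconciliation")
  Reduce(oplus, lapply(root_out, `[[`, "descs"))
}

#' Compute the Pareto-optimal reconciliation front of an instance
#'
#' End-to-end pipeline: LCA species map, species-tree pruning, implied-node
#' insertion, decomposition, tile enumeration and stitching.
#'
#' @param G gene tree (`dlc_tree` or Newick string).
#' @param S species tree (`dlc_tree` or Newick string).
#' @param leaf_map named character vector (gene leaf -> species leaf) or TSV
#'   text accepted by [read_leaf_map()].
#' @param max_width refuse instances whose decomposition width `k` exceeds
#'   this bound (the algorithm is fixed-parameter tractable in `k`).
#' @return an object of class `dlc_front`: list with `front` (descriptors),
#'   `dec`, and `k`.
#' @export
#' @examples
#' fr <- reconcile_landscape("(a1,a2);", "A;", c(a1 = "A", a2 = "A"))
reconcile_landscape <- function(G, S, leaf_map, max_width = 8L) {
  if (is.character(G)) G <- read_newick(G, "gene")
  if (is.character(S)) S <- read_newick(S, "species")
  if (is.character(leaf_map) && any(grepl("\t", leaf_map)))
    leaf_map <- read_leaf_map(leaf_map)
  dec <- prepare_instance(G, S, leaf_map)
  if (dec$k > max_width)
    stop("instance width k=", dec$k, " exceeds max_width=", max_width,
         "; the tile enumeration is exponential in k")
  tiletab <- build_tile_tables(dec)
  front <- canonical_descriptors(stitch(tiletab, dec))
  structure(list(front = front, dec = dec, k = dec$k), class = "dlc_front")
}

# stable ordering of a descriptor list by event count
canonical_descriptors <- function(A) {
  ord <- order(vapply(A, function(a) a$v[1], 0L),
               vapply(A, function(a) a$v[2], 0L),
               vapply(A, function(a) a$v[3], 0L))
  lapply(A[ord], function(a) {
    if (length(a$events)) a$events <- a$events[order(names(a$events))]
    a
  })
}

#' @export
print.dlc_front <- function(x, ...) {
  cat(sprintf("Pareto-optimal reconciliation front (width k=%d):\n", x$k))
  for (a in x$front)
    cat(sprintf("  <d=%d, l=%d, c=%d>  kappa=%g  events=%d\n",
                a$v[1], a$v[2], a$v[3], a$kappa, length(a$events)))
  invisible(x)
}
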