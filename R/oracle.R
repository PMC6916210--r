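# Brute-force enumeration of all labeled coalescent trees (LCTs) on small
# instances.  This is the validation oracle: it shares only the tree
# plumbing (parsing, LCA map, implied nodes) with the main code path so that
# node ids are comparable, but derives tops/bottoms, locus maps, orderings
# and all event counts in independent straight-line code -- no tiles, no
# relative patterns, no descriptor algebra.

# all linear extensions of a set under a "must precede" matrix, by
# exhaustive permutation filtering (deliberately naive)
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  res <- perms(seq_len(n))
  .perm_cache[[key]] <- res
  res
}

oracle_linexts <- function(elems, prec) {
  n <- length(elems)
  if (n <= 1L) return(list(elems))
  keep <- list()
  for (p in all_permutations(n)) {
    ok <- TRUE
    for (i in seq_len(n - 1L))
      if (any(prec[p[(i + 1L):n], p[i]])) { ok <- FALSE; break }
    if (ok) keep[[length(keep) + 1L]] <- elems[p]
  }
  keep
}

#' Enumerate all LCTs of a small instance by brute force
#'
#' Every subset of gene-tree branches is flagged as duplications (one fresh
#' locus per flag, inheritance elsewhere); locus maps with two extant genes
#' of one species on the same locus are discarded; every combination of
#' linear extensions (one per species and mother locus with duplications) is
#' a distinct LCT.  Events and counts are derived directly from the
#' definitions.
#'
#' @param G gene tree (`dlc_tree` or Newick string).
#' @param S species tree (`dlc_tree` or Newick string).
#' @param leaf_map named character vector gene leaf -> species leaf.
#' @param max_gene_leaves,max_species_leaves refuse larger instances (the
#'   enumeration is exponential).
#' @return list with `lcts` (one entry per LCT: `v`, `events`) and counts.
#' @export
enumerate_all_lcts <- function(G, S, leaf_map, max_gene_leaves = 6L,
                               max_species_leaves = 4L) {
  if (is.character(G)) G <- read_newick(G, "gene")
  if (is.character(S)) S <- read_newick(S, "species")
  if (length(tree_leaves(G)) > max_gene_leaves)
    stop("gene tree too large for the oracle (", length(tree_leaves(G)),
         " leaves > ", max_gene_leaves, ")")
  if (length(tree_leaves(S)) > max_species_leaves)
    stop("species tree too large for the oracle")

  # shared plumbing: same implied tree / ids as the main path
  M0 <- lca_species_map(G, S, leaf_map)
  pr <- prune_to_root(S, M0, G)
  im <- add_implied_nodes(G, pr$tree, pr$old2new[M0])
  Gx <- im$tree; Sx <- pr$tree; M <- im$M

  ng <- n_nodes(Gx); ns <- n_nodes(Sx)
  gparent <- Gx$parent
  # independent derivation of per-species structure
  sp_nodes <- lapply(seq_len(ns), function(s) which(M == s))
  sp_bottoms <- lapply(seq_len(ns), function(s) {
    Filter(function(g) {
      kids <- Gx$children[[g]]
      length(kids) == 0L || all(M[kids] != s)
    }, sp_nodes[[s]])
  })
  sp_tops <- lapply(seq_len(ns), function(s) {
    if (is.na(Sx$parent[s])) Gx$root else sp_bottoms[[Sx$parent[s]]]
  })
  leaf_species <- which(vapply(Sx$children, length, 1L) == 0L)
  branches <- which(!is.na(gparent))          # flag candidates (child ids)
  nb <- length(branches)

  # ancestor-or-equal lookup, derived by climbing from every node
  anc <- matrix(FALSE, ng, ng)
  for (g in seq_len(ng)) {
    v <- g
    repeat {
      anc[v, g] <- TRUE
      v <- gparent[v]
      if (is.na(v)) break
    }
  }
  # tops whose lineage actually enters s (structural, flag-independent)
  sp_entering <- lapply(seq_len(ns), function(s) {
    tops <- sp_tops[[s]]
    if (!length(tops)) return(integer(0))
    tops[vapply(tops, function(t) any(M[Gx$children[[t]]] == s), TRUE)]
  })

  # vectorized over all flag subsets: loci as nearest flagged ancestor branch
  # (0 = root locus), then extant-species distinctness filter
  nmask <- 2^nb
  masks <- seq_len(nmask) - 1
  bit_of <- integer(ng)
  bit_of[branches] <- 2^(seq_len(nb) - 1)
  L <- matrix(0L, nrow = ng, ncol = nmask)
  for (g in tree_preorder(Gx)) {
    p <- gparent[g]
    if (is.na(p)) next
    fl <- bitwAnd(masks, bit_of[g]) > 0
    L[g, ] <- ifelse(fl, g, L[p, ])
  }
  valid <- rep(TRUE, nmask)
  for (s in leaf_species) {
    bots <- sp_bottoms[[s]]
    if (length(bots) < 2L) next
    for (i in seq_len(length(bots) - 1L))
      for (j in (i + 1L):length(bots))
        valid <- valid & (L[bots[[i]], ] != L[bots[[j]], ])
  }

  # All events, losses, coalescences and order families of one species
  # branch depend only on the locus pattern over the branch's own scope
  # (tops, nodes, and children of bottoms -- the latter carry the
  # continuation flags).  That pure function is memoized per species on the
  # dense pattern, which collapses the work across flag subsets.
  sp_scope <- lapply(seq_len(ns), function(s)
    unique(c(sp_tops[[s]], sp_nodes[[s]],
             unlist(Gx$children[sp_bottoms[[s]]]))))
  sp_cache <- lapply(seq_len(ns), function(s) new.env(parent = emptyenv()))
  # linear-extension sets depend only on the element set (precedence comes
  # from fixed gene-tree ancestry), so they are shared across locus maps
  ext_cache <- new.env(parent = emptyenv())
  linexts_of <- function(elems) {
    ekey <- paste(elems, collapse = ",")
    hit <- ext_cache[[ekey]]
    if (!is.null(hit)) return(hit)
    np <- length(elems)
    prec <- matrix(FALSE, np, np)
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (i == j) next
      a <- elems[i]; b <- elems[j]
      prec[i, j] <-
        if (a <= ng && b <= ng) a != b && anc[a, b]
        else if (a <= ng) anc[a, gparent[b - ng]]
        else if (b <= ng) anc[a - ng, b]
        else anc[a - ng, gparent[b - ng]]
    }
    res <- oracle_linexts(elems, prec)
    ext_cache[[ekey]] <- res
    res
  }

  species_eval <- function(s, locus, key) {
    hit <- sp_cache[[s]][[key]]
    if (!is.null(hit)) return(hit)

    tops <- sp_tops[[s]]; bots <- sp_bottoms[[s]]
    in_s <- sp_nodes[[s]]
    root_sp <- is.na(Sx$parent[s])
    events <- character(0)
    nloss <- 0L; cspec <- 0L
    # branches with a duplication: endpoints on different loci
    created <- in_s[vapply(in_s, function(g) {
      p <- gparent[g]
      !is.na(p) && locus[p] != locus[g]
    }, TRUE)]
    # losses: locus at top (all tops) or created in s, absent at bottom
    top_l <- unique(locus[tops])
    bot_l <- unique(locus[bots])
    # (tops/bottoms/nodes vectors are ascending, so id lists need no sort)
    for (l in top_l[!(top_l %in% bot_l)]) {
      nloss <- nloss + 1L
      events <- c(events, sprintf("loss|%d|T:%s", s,
                                  paste(tops[locus[tops] == l],
                                        collapse = ",")))
    }
    for (g in created[!(locus[created] %in% bot_l)]) {
      nloss <- nloss + 1L
      events <- c(events, sprintf("loss|%d|D:%d", s, g))
    }
    # coalescence at speciation: lineages entering s
    if (!root_sp) {
      entering <- sp_entering[[s]]
      for (l in unique(locus[entering])) {
        grp <- entering[locus[entering] == l]
        if (length(grp) >= 2L) {
          cspec <- cspec + length(grp) - 1L
          events <- c(events, sprintf("cspec|%d|%s", s,
                                      paste(grp, collapse = ",")))
        }
      }
    }
    # speciation events: bottom locus continuing un-duplicated into a child
    if (length(Sx$children[[s]]) > 0L) {
      for (l in bot_l) {
        carriers <- bots[locus[bots] == l]
        continues <- any(vapply(carriers, function(x)
          any(locus[Gx$children[[x]]] == locus[x]), TRUE))
        if (continues)
          events <- c(events, sprintf("spec|%d|%s", s,
                                      paste(carriers, collapse = ",")))
      }
    }
    # duplications: plain + merged identity
    for (g in created) {
      events <- c(events, sprintf("dup|%d|%d", s, g))
      bd <- paste(bots[locus[bots] == locus[g]], collapse = ",")
      bm <- paste(bots[locus[bots] == locus[gparent[g]]], collapse = ",")
      pq <- sort(c(bd, bm))
      events <- c(events, sprintf("mdup|%d|{%s}{%s}", s, pq[1], pq[2]))
    }

    # order families per mother locus with departing duplications
    groups <- list()
    if (length(created)) {
      for (l in unique(locus[gparent[created]])) {
        dl <- created[locus[gparent[created]] == l]
        nl <- in_s[locus[in_s] == l]
        # elements: gene nodes on l, duplications departing l (as ng + id)
        elems <- c(nl, dl + ng)
        exts <- linexts_of(elems)
        # lineage portions on l (order-independent): start/end elements
        se <- integer(0); ee <- integer(0); lid <- integer(0)
        for (g in in_s) {
          p <- gparent[g]
          if (is.na(p)) next
          fl <- locus[p] != locus[g]
          if (locus[p] == l) {
            se <- c(se, if (p %in% nl) p else NA_integer_)
            ee <- c(ee, if (fl) ng + g else g)
            lid <- c(lid, g)
          } else if (fl && locus[g] == l) {
            se <- c(se, NA_integer_); ee <- c(ee, g); lid <- c(lid, g)
          }
        }
        # per extension: coalescence-at-duplication contributions + events
        evald <- lapply(exts, function(ord) {
          st <- as.numeric(match(se, ord)); st[is.na(st)] <- -Inf
          en <- match(ee, ord)
          cc <- 0L; ev <- character(0)
          for (pd in which(ord > ng)) {
            open <- st < pd & en >= pd
            extra <- sum(open) - 1L
            if (extra > 0L) {
              cc <- cc + extra
              ev <- c(ev, sprintf("cdup|%d|%d|%s", s, ord[pd] - ng,
                                  paste(lid[open], collapse = ",")))
            }
          }
          list(c = cc, events = ev)
        })
        groups[[length(groups) + 1L]] <- evald
      }
    }
    # the only identity that can repeat within a species is a merged
    # duplication; dedupe once here (memoized) so LCT records need not
    res <- list(nloss = nloss, cspec = cspec, events = unique(events),
                groups = groups)
    sp_cache[[s]][[key]] <- res
    res
  }

  # memo keys for every species and valid mask at once: the locus pattern of
  # a species' scope, encoded by its pairwise-equality bits (two locus
  # vectors get the same key iff they are identical up to renaming)
  vidx <- which(valid)
  sp_keys <- vector("list", ns)
  for (s in seq_len(ns)) {
    scope <- sp_scope[[s]]
    nsc <- length(scope)
    if (nsc <= 1L || !length(vidx)) {
      sp_keys[[s]] <- rep("k", length(vidx))
      next
    }
    parts <- list(numeric(length(vidx)))
    bit <- 1
    for (i in seq_len(nsc - 1L)) for (j in (i + 1L):nsc) {
      if (bit > 2^50) {  # keep each accumulator exactly representable
        parts[[length(parts) + 1L]] <- numeric(length(vidx))
        bit <- 1
      }
      parts[[length(parts)]] <- parts[[length(parts)]] +
        bit * (L[scope[i], vidx] == L[scope[j], vidx])
      bit <- bit * 2
    }
    sp_keys[[s]] <- do.call(paste, c(list("k"), parts, sep = "_"))
  }

  popcount <- vapply(seq_len(nmask) - 1L, function(m)
    sum(bitwAnd(m, 2^(seq_len(max(nb, 1L)) - 1)) > 0), 0)

  # evaluate each distinct per-species pattern once, then index per mask
  sp_vals <- vector("list", ns)
  for (s in seq_len(ns)) {
    uk <- unique(sp_keys[[s]])
    vals <- lapply(uk, function(k)
      species_eval(s, L[, vidx[match(k, sp_keys[[s]])]], k))
    sp_vals[[s]] <- vals[match(sp_keys[[s]], uk)]
  }

  chunks <- vector("list", length(vidx))
  for (ci in seq_along(vidx)) {
    d <- as.integer(popcount[vidx[ci]])
    base_events <- character(0)
    nloss <- 0L; cspec <- 0L
    groups <- list()
    for (s in seq_len(ns)) {
      res <- sp_vals[[s]][[ci]]
      nloss <- nloss + res$nloss
      cspec <- cspec + res$cspec
      base_events <- c(base_events, res$events)
      groups <- c(groups, res$groups)
    }

    # cartesian product over groups = one LCT per order family; the base
    # event vector is shared by reference, only order-dependent events are
    # appended per family (fields: v; eb = base events; ex = extra events)
    combos <- list(list(v = c(d, nloss, cspec), eb = base_events,
                        ex = character(0)))
    for (grp in groups) {
      acc2 <- vector("list", length(combos) * length(grp))
      i2 <- 0L
      for (a in combos) for (g in grp) {
        i2 <- i2 + 1L
        acc2[[i2]] <- list(v = a$v + c(0L, 0L, g$c), eb = a$eb,
                           ex = c(a$ex, g$events))
      }
      combos <- acc2
    }
    chunks[[ci]] <- combos
  }
  lcts <- do.call(c, chunks)

  list(lcts = lcts, n_lcts = length(lcts), G = Gx, S = Sx, M = M)
}

#' Pareto front of an LCT enumeration
#'
#' Groups LCTs by event count, drops dominated counts, and assembles
#' descriptors: kappa = group size, event frequencies = number of group
#' members containing each event.
#'
#' @param enum result of [enumerate_all_lcts()].
#' @return list of descriptors (Pareto-optimal, canonically ordered).
#' @export
oracle_front <- function(enum) {
  lcts <- enum$lcts
  if (!length(lcts)) stop("no LCTs enumerated")
  vm <- matrix(unlist(lapply(lcts, `[[`, "v")), nrow = 3L)
  keys <- paste(vm[1, ], vm[2, ], vm[3, ], sep = ",")
  uk <- unique(keys)
  vs <- lapply(uk, function(k) vm[, match(k, keys)])
  dominated <- vapply(seq_along(uk), function(i)
    any(vapply(seq_along(uk), function(j)
      j != i && all(vs[[j]] <= vs[[i]]) && any(vs[[j]] < vs[[i]]), TRUE)),
    TRUE)
  out <- list()
  for (i in which(!dominated)) {
    grp <- lcts[keys == uk[i]]
    ev <- unlist(lapply(grp, lct_event_list))
    E <- if (is.null(ev)) numeric(0) else {
      u <- unique(ev)
      stats::setNames(as.numeric(tabulate(match(ev, u), length(u))), u)
    }
    out[[length(out) + 1L]] <- descriptor(vs[[i]], length(grp), E)
  }
  canonical_descriptors(out)
}

#' Event list of one enumerated LCT
#'
#' LCT records store the locus-map-level events (`eb`, shared across the
#' map's order families) separately from the order-dependent
#' coalescence-at-duplication events (`ex`); this composes them.
#'
#' @param x one element of the `lcts` list from [enumerate_all_lcts()].
#' @return character vector of canonical event ids.
#' @export
lct_event_list <- function(x) c(x$eb, x$ex)
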