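# Sub-locus maps, sub-partial orders and event counting within one species
# branch.
#
# A sub-locus map assigns a locus to every gene node in tops(s) u nodes(s);
# the only locus changes are on flagged (duplication) branches, each of which
# creates a locus new to the branch.  Event counting:
#   d      = number of flagged branches in s
#   losses = loci present at the top of s (over *all* tops: a locus at the
#            bottom of the parent branch is inherited by both children) or
#            created by a duplication in s, that are absent from the bottom
#   coal at speciation = per top locus, (number of lineages actually entering
#            s on that locus) - 1; a lineage enters s iff its top node has a
#            child in nodes(s)
#   coal at duplication = per duplication, (number of contemporaneous open
#            lineages on the mother locus) - 1, as determined by the
#            sub-partial order
# Event identities are label-free strings, invariant under locus renumbering.

#' Build a sub-locus map for one species branch
#'
#' Given locus values at the tops of `s` and a set of flagged (duplication)
#' branches, propagates loci through the gene forest inside `s`: a node
#' inherits its parent's locus unless its branch is flagged, in which case it
#' starts a fresh locus.  For the root species the gene root takes locus 1.
#'
#' @param dec a `dlc_decomposition`.
#' @param s species node id.
#' @param top_loci integer vector of locus values, parallel to the canonical
#'   tops sequence of `s` (for the species root: a single value for the gene
#'   root).
#' @param flags integer vector of gene node ids whose parent branch carries a
#'   duplication.
#' @return an object of class `dlc_slm`.
#' @export
sublocus_map <- function(dec, s, top_loci, flags = integer(0)) {
  G <- dec$G
  tops <- if (is.na(dec$S$parent[s])) G$root else dec$tops[[s]]
  nodes <- dec$nodes[[s]]
  stopifnot(length(top_loci) == length(tops))
  locus <- rep(NA_integer_, n_nodes(G))
  locus[tops] <- as.integer(top_loci)
  nxt <- if (length(top_loci)) max(top_loci) else 0L
  flags <- sort(as.integer(flags))
  for (g in nodes) {  # nodes are in pre-order, parents first
    if (!is.na(locus[g])) next  # gene root in the root species
    p <- G$parent[g]
    if (g %in% flags) {
      nxt <- nxt + 1L
      locus[g] <- nxt
    } else locus[g] <- locus[p]
  }
  structure(list(s = s, tops = tops, nodes = nodes,
                 bottoms = dec$bottoms[[s]], locus = locus, flags = flags,
                 root_species = is.na(dec$S$parent[s])),
            class = "dlc_slm")
}

#' Validate a sub-locus map
#'
#' Checks the LCT constraints: a branch is flagged iff its endpoints carry
#' different loci; every flagged branch introduces a locus new to the species
#' branch; and if `s` is an extant (leaf) species, all bottom loci are
#' pairwise distinct.
#'
#' @param slm a `dlc_slm`.
#' @param dec the matching `dlc_decomposition`.
#' @return logical scalar.
#' @export
validate_sublocus_map <- function(slm, dec) {
  G <- dec$G
  locus <- slm$locus
  for (g in slm$nodes) {
    p <- G$parent[g]
    if (is.na(p) || is.na(locus[p])) next
    if ((locus[p] != locus[g]) != (g %in% slm$flags)) return(FALSE)
  }
  new_loci <- locus[slm$flags]
  if (anyDuplicated(new_loci)) return(FALSE)
  if (any(new_loci %in% locus[slm$tops])) return(FALSE)
  if (length(dec$S$children[[slm$s]]) == 0L) {
    bl <- locus[slm$bottoms]
    if (anyDuplicated(bl)) return(FALSE)
  }
  TRUE
}

# ---- partial orders -------------------------------------------------------
#
# Order elements are integers: e <= ng is gene node e; e > ng is the
# duplication on the branch above node (e - ng), where ng = n_nodes(G).

order_elem_dup <- function(dec) n_nodes(dec$G)

# precedence matrix: prec[i, j] TRUE iff element i must precede element j.
# With L(e) = the node (or dup-branch child) of e and U(e) = e's node (or the
# dup-branch parent), e precedes f iff L(e) is an ancestor-or-equal of U(f).
order_prec_matrix <- function(dec, elems) {
  ng <- order_elem_dup(dec)
  isd <- elems > ng
  lo <- elems; lo[isd] <- elems[isd] - ng
  up <- elems; up[isd] <- dec$G$parent[elems[isd] - ng]
  prec <- dec$anc[lo, up, drop = FALSE]
  diag(prec) <- FALSE
  prec
}

# all linear extensions of elements under a precedence matrix
linear_extensions <- function(elems, prec) {
  n <- length(elems)
  if (n <= 1L) return(list(elems))
  res <- list()
  recurse <- function(placed, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- elems[placed]
      return(invisible())
    }
    for (i in remaining) {
      ok <- TRUE
      for (j in setdiff(remaining, i)) if (prec[j, i]) { ok <- FALSE; break }
      if (ok) recurse(c(placed, i), setdiff(remaining, i))
    }
  }
  recurse(integer(0), seq_len(n))
  res
}

# mother loci with at least one departing duplication
mother_loci <- function(slm, dec) {
  if (!length(slm$flags)) return(integer(0))
  sort(unique(slm$locus[dec$G$parent[slm$flags]]))
}

# relevant order elements for one mother locus: the nodes of s on that locus
# plus the duplications departing it (encoded as ng + branch-child id)
order_elements <- function(slm, dec, l) {
  ng <- order_elem_dup(dec)
  nodes_l <- slm$nodes[slm$locus[slm$nodes] == l]
  dups_l <- slm$flags[slm$locus[dec$G$parent[slm$flags]] == l]
  c(nodes_l, dups_l + ng)
}

#' Enumerate all valid sub-partial orders of a sub-locus map
#'
#' For each mother locus with at least one departing duplication, the
#' relevant elements are the gene nodes of `s` on that locus plus the
#' duplication events departing it; a valid sub-partial order picks one
#' linear extension of gene-tree ancestry per mother locus.  With no
#' duplications there is exactly one (empty) order.
#'
#' @param slm a `dlc_slm`.
#' @param dec the matching `dlc_decomposition`.
#' @return list of order families; each family is a named list mapping the
#'   mother locus (as character) to a character vector of ordered elements.
#' @export
enumerate_partial_orders <- function(slm, dec) {
  ml <- mother_loci(slm, dec)
  if (!length(ml)) return(list(list()))
  per_locus <- lapply(ml, function(l) {
    elems <- order_elements(slm, dec, l)
    linear_extensions(elems, order_prec_matrix(dec, elems))
  })
  idx <- expand.grid(lapply(per_locus, seq_along))
  lapply(seq_len(nrow(idx)), function(r) {
    fam <- lapply(seq_along(ml), function(j) per_locus[[j]][[idx[r, j]]])
    names(fam) <- as.character(ml)
    fam
  })
}

# ---- event counting -------------------------------------------------------

# canonical id join; callers pass ascending id vectors
join_ids <- function(ids) paste(ids, collapse = ",")

# coalescence-at-duplication contributions and events for one mother locus
# under one linear extension (integer element codes)
coal_at_dups <- function(slm, dec, l, ord) {
  G <- dec$G
  ng <- order_elem_dup(dec)
  # lineages on locus l: each is a branch portion with a start/end position
  starts <- numeric(0); ends <- numeric(0); ids <- integer(0)
  for (g in slm$nodes) {
    p <- G$parent[g]
    if (is.na(p) || is.na(slm$locus[p])) next
    flagged <- g %in% slm$flags
    if (slm$locus[p] == l) {          # upper portion departs on l
      st <- match(p, ord)
      if (is.na(st)) st <- -Inf      # starts at a top of s
      en <- if (flagged) match(ng + g, ord) else match(g, ord)
      starts <- c(starts, st); ends <- c(ends, en); ids <- c(ids, g)
    } else if (flagged && slm$locus[g] == l) {  # dup-created lower portion
      starts <- c(starts, -Inf); ends <- c(ends, match(g, ord))
      ids <- c(ids, g)
    }
  }
  total <- 0L; events <- character(0)
  for (pd in which(ord > ng)) {
    open <- starts < pd & ends >= pd
    contrib <- sum(open) - 1L
    if (contrib > 0L) {
      total <- total + contrib
      events <- c(events, sprintf("cdup|%d|%d|%s", slm$s, ord[pd] - ng,
                                  join_ids(ids[open])))
    }
  }
  list(c = as.integer(total), events = events)
}

#' Count the events induced by a sub-locus map and sub-partial order
#'
#' @param slm a valid `dlc_slm`.
#' @param spo one order family from [enumerate_partial_orders()].
#' @param dec the matching `dlc_decomposition`.
#' @return list with `v` (the event-count contribution `c(d, l, c)` of this
#'   species branch) and `events` (character vector of canonical event ids;
#'   coalescence events carry their multiplicity in the count, not by
#'   repetition).
#' @export
count_events <- function(slm, spo, dec) {
  G <- dec$G
  s <- slm$s
  locus <- slm$locus
  d <- length(slm$flags)
  events <- character(0)

  # duplications: plain identity and merged (mother/daughter bottom sets)
  for (g in slm$flags) {
    events <- c(events, sprintf("dup|%d|%d", s, g))
    lm <- locus[G$parent[g]]; ld <- locus[g]
    bd <- join_ids(slm$bottoms[locus[slm$bottoms] == ld])
    bm <- join_ids(slm$bottoms[locus[slm$bottoms] == lm])
    if (bd > bm) { tmp <- bd; bd <- bm; bm <- tmp }
    events <- c(events, sprintf("mdup|%d|{%s}{%s}", s, bd, bm))
  }

  # losses
  top_loci <- unique(locus[slm$tops])
  bot_loci <- unique(locus[slm$bottoms])
  nloss <- 0L
  for (l in setdiff(top_loci, bot_loci)) {
    nloss <- nloss + 1L
    events <- c(events, sprintf("loss|%d|T:%s", s,
                                join_ids(slm$tops[locus[slm$tops] == l])))
  }
  for (g in slm$flags[!(locus[slm$flags] %in% bot_loci)]) {
    nloss <- nloss + 1L
    events <- c(events, sprintf("loss|%d|D:%d", s, g))
  }

  # coalescence at speciation: lineages entering s (the root branch is
  # entered by the single lineage of the gene root)
  cs <- 0L
  entering <- if (slm$root_species) slm$tops else dec$entering[[s]]
  for (l in unique(locus[entering])) {
    grp <- entering[locus[entering] == l]
    if (length(grp) >= 2L) {
      cs <- cs + length(grp) - 1L
      events <- c(events, sprintf("cspec|%d|%s", s, join_ids(grp)))
    }
  }

  # coalescence at duplication, per the sub-partial order
  cd <- 0L
  for (l in names(spo)) {
    res <- coal_at_dups(slm, dec, as.integer(l), spo[[l]])
    cd <- cd + res$c
    events <- c(events, res$events)
  }

  list(v = c(d, nloss, cs + cd), events = unique(events))
}

# which top loci of s continue un-duplicated into s (the continuation
# profile used for exact speciation-event bookkeeping at the stitch)
continuation_profile <- function(slm, dec) {
  if (slm$root_species) return(integer(0))
  tl <- slm$locus[slm$tops]
  tk <- dec$top_kids[[slm$s]]
  ok <- logical(length(tk))
  for (i in seq_along(tk)) {
    kids <- tk[[i]]
    ok[i] <- length(kids) > 0L && any(!(kids %in% slm$flags))
  }
  sort.int(unique(tl[ok]))
}

#' Reconciliation cost of an event count
#'
#' @param v event count `c(d, l, c)`.
#' @param costs positive numeric vector `c(C_D, C_L, C_C)`.
#' @return `d*C_D + l*C_L + c*C_C`.
#' @export
reconciliation_cost <- function(v, costs) {
  stopifnot(length(costs) == 3L)
  if (any(costs <= 0)) stop("event costs must be positive")
  sum(v * costs)
}
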