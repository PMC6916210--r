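# Event-count descriptors and the Pareto-preserving merge operations used by
# the dynamic program.
#
# A descriptor is <v, kappa, E>: v = c(d, l, c) is an event count, kappa the
# number of reconciliations (LCTs) attaining v, and E the event set -- a
# named numeric vector mapping canonical event-identity strings to the number
# of those LCTs containing the event (so 1 <= k <= kappa throughout).
# Descriptor sets are plain lists of descriptors with pairwise-distinct event
# counts.

#' Construct an event-count descriptor
#'
#' @param v integer vector `c(d, l, c)` of duplication, loss and coalescence
#'   counts.
#' @param kappa number of LCTs with event count `v` (stored as double; LCT
#'   counts grow multiplicatively).
#' @param events named numeric vector: canonical event id -> number of LCTs
#'   containing the event.
#' @return an object of class `dlc_descriptor`.
#' @export
descriptor <- function(v, kappa = 1, events = numeric(0)) {
  structure(list(v = as.integer(v), kappa = as.numeric(kappa),
                 events = events), class = "dlc_descriptor")
}

# internal fast constructor: identical fields, no class attribute (the class
# only drives printing; the algebra below treats descriptors structurally)
desc_new <- function(v, kappa, events) {
  list(v = v, kappa = kappa, events = events)
}

#' @export
print.dlc_descriptor <- function(x, ...) {
  cat(sprintf("<d=%d, l=%d, c=%d>  kappa=%g  |E|=%d\n",
              x$v[1], x$v[2], x$v[3], x$kappa, length(x$events)))
  invisible(x)
}

#' Strict Pareto domination of event counts
#'
#' `v` is strictly better than `v2` iff every entry of `v` is `<=` the
#' corresponding entry of `v2` and the vectors differ.
#'
#' @param v,v2 event counts `c(d, l, c)`.
#' @return logical scalar.
#' @export
strictly_better <- function(v, v2) {
  all(v <= v2) && any(v < v2)
}

#' Pareto-optimal subset of a descriptor set
#'
#' Keeps the descriptors whose event count is not strictly bettered by any
#' other member.  Implemented as a sort-and-sweep over (d, l) with a running
#' staircase of minimal c.
#'
#' @param A list of descriptors with pairwise-distinct event counts.
#' @return the Pareto-optimal sublist.
#' @export
pareto_subset <- function(A) {
  n <- length(A)
  if (n <= 1L) return(A)
  d <- vapply(A, function(a) a$v[1], 0L)
  l <- vapply(A, function(a) a$v[2], 0L)
  c3 <- vapply(A, function(a) a$v[3], 0L)
  ord <- order(d, l, c3)
  keptL <- integer(0); keptC <- integer(0); keep <- logical(n)
  for (i in ord) {
    sel <- keptL <= l[i]
    if (!any(sel) || min(keptC[sel]) > c3[i]) {
      keep[i] <- TRUE
      keptL <- c(keptL, l[i]); keptC <- c(keptC, c3[i])
    }
  }
  A[keep]
}

#' Scale an event set
#'
#' Multiplies every event frequency by `x` (used when one of `x` equivalent
#' LCT choices elsewhere is combined with each LCT here).
#'
#' @param x positive integer factor.
#' @param E named numeric event vector.
#' @return scaled event vector.
#' @export
scale_eventset <- function(x, E) {
  if (!length(E)) return(E)
  E * x
}

#' Merge two event sets
#'
#' Union of the identities with frequencies of shared identities added.
#'
#' @param E,F2 named numeric event vectors.
#' @return merged event vector.
#' @export
merge_eventsets <- function(E, F2) {
  if (!length(E)) return(F2)
  if (!length(F2)) return(E)
  idx <- match(names(F2), names(E))
  hit <- !is.na(idx)
  if (any(hit)) E[idx[hit]] <- E[idx[hit]] + F2[hit]
  if (all(hit)) E else c(E, F2[!hit])
}

#' Combine two descriptors of independent subproblems
#'
#' `a + b = <v + v', kappa * kappa', kappa' * E  merged with  kappa * E'>`:
#' counts add, LCT counts multiply, and each event's frequency is inflated by
#' the number of partner LCTs it is combined with.
#'
#' @param a,b descriptors.
#' @return the combined descriptor.
#' @export
add_descriptors <- function(a, b) {
  ea <- if (b$kappa == 1 || !length(a$events)) a$events else a$events * b$kappa
  eb <- if (a$kappa == 1 || !length(b$events)) b$events else b$events * a$kappa
  desc_new(a$v + b$v, a$kappa * b$kappa, merge_eventsets(ea, eb))
}

# merge descriptors sharing an event count: kappa added, event sets merged
merge_same_counts <- function(A) {
  if (length(A) <= 1L) return(A)
  keys <- vapply(A, function(a) paste(a$v, collapse = ","), "")
  if (!anyDuplicated(keys)) return(A)
  out <- list()
  for (k in unique(keys)) {
    grp <- A[keys == k]
    acc <- grp[[1L]]
    for (g in grp[-1L])
      acc <- desc_new(acc$v, acc$kappa + g$kappa,
                      merge_eventsets(acc$events, g$events))
    out[[length(out) + 1L]] <- acc
  }
  out
}

#' Pareto union of two descriptor sets
#'
#' Descriptors with equal event counts are merged (LCT counts added, event
#' sets merged), then the result is Pareto-filtered.  This is the operation
#' describing the union of two alternative LCT sets.
#'
#' @param A,B lists of descriptors.
#' @return Pareto-optimal merged list.
#' @export
oplus <- function(A, B) {
  pareto_subset(merge_same_counts(c(A, B)))
}

#' Pareto product of two descriptor sets
#'
#' All pairwise descriptor combinations, with same-count results merged and
#' the result Pareto-filtered.  This is the operation describing the
#' Cartesian product of two independent LCT sets.
#'
#' @param A,B lists of descriptors.
#' @return Pareto-optimal combined list.
#' @export
otimes <- function(A, B) {
  if (!length(A) || !length(B)) return(list())
  R <- vector("list", length(A) * length(B))
  i <- 0L
  for (a in A) for (b in B) {
    i <- i + 1L
    R[[i]] <- add_descriptors(a, b)
  }
  pareto_subset(merge_same_counts(R))
}

# canonical form of a descriptor set, for comparisons and stable output
canonical_front <- function(A) {
  ord <- order(vapply(A, function(a) a$v[1], 0L),
               vapply(A, function(a) a$v[2], 0L),
               vapply(A, function(a) a$v[3], 0L))
  lapply(A[ord], function(a) {
    ev <- a$events
    ev <- ev[order(names(ev))]
    list(v = a$v, kappa = a$kappa, events = ev)
  })
}
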