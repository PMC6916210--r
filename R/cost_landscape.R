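# Partition of the (C_D, C_L) event-cost rectangle into equivalence regions,
# with exact rational arithmetic throughout.  The coalescence cost is
# normalized to 1, so the cost of an event count <d,l,c> at (x, y) is
# d*x + l*y + c.  The region of a Pareto-optimal count v is the subset of
# the box where v is cost-minimal: the intersection of the box with the
# half-planes (d-d')x + (l-l')y <= (c'-c) over all other counts v'.  All
# half-plane coefficients are integers and box bounds are rationals, so
# vertices are exact and zero-area (segment/point) regions are classified
# without tolerances.

# ---- rational scalars: c(num, den), den > 0, reduced ----------------------

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- rat_gcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  c(num, den)
}

# parse "p/q" strings or numerics (continued-fraction approximation for
# numerics like 0.2, exact for integers)
as_rational <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(rat(as.numeric(parts[1])))
    return(rat(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  if (x == round(x)) return(rat(x))
  # continued fractions, denominators up to 1e6
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > 1e6) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  rat(p1, q1)
}

rat_lcm <- function(a, b) a / rat_gcd(a, b) * b

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_sub <- function(a, b) rat(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) rat(a[1] * b[2], a[2] * b[1])
# sign of a - b
rat_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])
rat_str <- function(a) if (a[2] == 1) sprintf("%g", a[1]) else
  sprintf("%g/%g", a[1], a[2])

# ---- polygons: list of vertices, each vertex = list(x = rat, y = rat) -----

polygon_box <- function(box) {
  list(list(x = box$dmin, y = box$lmin), list(x = box$dmax, y = box$lmin),
       list(x = box$dmax, y = box$lmax), list(x = box$dmin, y = box$lmax))
}

# a x + b y - cc, exact sign (a, b, cc integers)
halfplane_side <- function(v, a, b, cc) {
  # value = a*xn/xd + b*yn/yd - cc; sign of (a*xn*yd + b*yn*xd - cc*xd*yd)
  sign(a * v$x[1] * v$y[2] + b * v$y[1] * v$x[2] - cc * v$x[2] * v$y[2])
}

# clip a convex polygon by {a x + b y <= cc} (Sutherland-Hodgman, exact)
clip_halfplane <- function(poly, a, b, cc) {
  n <- length(poly)
  if (!n) return(poly)
  sides <- vapply(poly, halfplane_side, 0, a = a, b = b, cc = cc)
  if (all(sides <= 0)) return(poly)
  if (all(sides > 0)) return(list())
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    P <- poly[[i]]; Q <- poly[[j]]
    sp <- sides[i]; sq <- sides[j]
    if (sp <= 0) out[[length(out) + 1L]] <- P
    if ((sp < 0 && sq > 0) || (sp > 0 && sq < 0)) {
      # intersection: P + t (Q - P), t = f(P) / (f(P) - f(Q))
      fP <- rat_sub(rat_add(rat_mul(rat(a), P$x), rat_mul(rat(b), P$y)),
                    rat(cc))
      fQ <- rat_sub(rat_add(rat_mul(rat(a), Q$x), rat_mul(rat(b), Q$y)),
                    rat(cc))
      t <- rat_div(fP, rat_sub(fP, fQ))
      x <- rat_add(P$x, rat_mul(t, rat_sub(Q$x, P$x)))
      y <- rat_add(P$y, rat_mul(t, rat_sub(Q$y, P$y)))
      out[[length(out) + 1L]] <- list(x = x, y = y)
    }
  }
  # drop consecutive duplicates
  if (length(out) > 1L) {
    keep <- vapply(seq_along(out), function(i) {
      j <- if (i == 1L) length(out) else i - 1L
      !(rat_cmp(out[[i]]$x, out[[j]]$x) == 0 &&
          rat_cmp(out[[i]]$y, out[[j]]$y) == 0)
    }, TRUE)
    if (!any(keep)) keep[1L] <- TRUE
    out <- out[keep]
  }
  out
}

# exact shoelace area (nonnegative)
polygon_area <- function(poly) {
  n <- length(poly)
  if (n < 3L) return(rat(0))
  acc <- rat(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    acc <- rat_add(acc, rat_sub(rat_mul(poly[[i]]$x, poly[[j]]$y),
                                rat_mul(poly[[j]]$x, poly[[i]]$y)))
  }
  acc <- rat_div(acc, rat(2))
  if (acc[1] < 0) acc <- rat(-acc[1], acc[2])
  acc
}

distinct_vertices <- function(poly) {
  out <- list()
  for (v in poly) {
    dupe <- any(vapply(out, function(w)
      rat_cmp(v$x, w$x) == 0 && rat_cmp(v$y, w$y) == 0, TRUE))
    if (!dupe) out[[length(out) + 1L]] <- v
  }
  out
}

#' Construct a duplication/loss cost box
#'
#' Bounds may be numerics or exact fraction strings (`"1/5"`); the
#' coalescence cost is fixed at 1.
#'
#' @param dmin,dmax duplication-cost range (positive).
#' @param lmin,lmax loss-cost range (positive).
#' @return an object of class `dlc_costbox`.
#' @export
cost_box <- function(dmin = "1/5", dmax = 5, lmin = "1/5", lmax = 5) {
  b <- list(dmin = as_rational(dmin), dmax = as_rational(dmax),
            lmin = as_rational(lmin), lmax = as_rational(lmax))
  if (b$dmin[1] <= 0 || b$lmin[1] <= 0)
    stop("cost bounds must be positive")
  if (rat_cmp(b$dmin, b$dmax) > 0 || rat_cmp(b$lmin, b$lmax) > 0)
    stop("empty cost range")
  structure(b, class = "dlc_costbox")
}

#' Reconciliation cost of an event count at a cost point
#'
#' @param v event count `c(d, l, c)`.
#' @param cd,cl duplication and loss costs (coalescence cost 1).
#' @return `d*cd + l*cl + c`.
#' @export
point_cost <- function(v, cd, cl) {
  v[1] * cd + v[2] * cl + v[3]
}

#' Partition the cost box into equivalence regions
#'
#' One region per Pareto-optimal event count that is cost-minimal somewhere
#' in the box; counts never minimal in the box are dropped.  Regions are
#' closed convex polygons (dimension 2), segments (1) or points (0); they
#' cover the box and their interiors are pairwise disjoint, but adjacent
#' regions share boundaries.
#'
#' @param front list of descriptors (or a `dlc_front`).
#' @param box a `dlc_costbox`.
#' @return list of regions: each has `v`, `descriptor`, `vertices`, `dim`,
#'   `area` (numeric) and `area_rat` (exact).
#' @export
compute_regions <- function(front, box = cost_box()) {
  if (inherits(front, "dlc_front")) front <- front$front
  if (!length(front)) stop("empty descriptor set")
  vs <- lapply(front, `[[`, "v")
  regions <- list()
  for (i in seq_along(front)) {
    poly <- polygon_box(box)
    for (j in seq_along(front)) {
      if (i == j) next
      a <- vs[[i]][1] - vs[[j]][1]
      b <- vs[[i]][2] - vs[[j]][2]
      cc <- vs[[j]][3] - vs[[i]][3]
      poly <- clip_halfplane(poly, a, b, cc)
      if (!length(poly)) break
    }
    if (!length(poly)) next
    dv <- distinct_vertices(poly)
    area <- polygon_area(poly)
    dim <- if (length(dv) >= 3L && area[1] > 0) 2L
    else if (length(dv) >= 2L) 1L else 0L
    regions[[length(regions) + 1L]] <-
      list(v = vs[[i]], descriptor = front[[i]], vertices = dv,
           dim = dim, area_rat = area, area = area[1] / area[2])
  }
  if (!length(regions)) stop("no region intersects the cost box")
  regions
}

#' Per-event support within a region
#'
#' The support of an event is the fraction `k / kappa` of the region's
#' optimal reconciliations containing it; events at or above the threshold
#' are returned.
#'
#' @param d a descriptor.
#' @param threshold inclusive support threshold in `[0, 1]`.
#' @param merge_dups if `TRUE`, duplications are identified by their
#'   mother/daughter lineage partition (symmetric placements merge);
#'   otherwise by their gene branch.
#' @return data frame with `event`, `support`.
#' @export
region_support <- function(d, threshold = 0, merge_dups = FALSE) {
  E <- select_dup_identities(d$events, merge_dups)
  sup <- if (length(E)) E / d$kappa else numeric(0)
  out <- data.frame(event = names(sup), support = unname(sup),
                    stringsAsFactors = FALSE)
  out[out$support >= threshold, , drop = FALSE]
}

#' Per-event consensus support across regions
#'
#' The consensus support of an event is the fraction of regions whose
#' optimal reconciliations contain it in at least one reconciliation
#' (regardless of frequency).  Degenerate regions count.
#'
#' @param regions list of regions from [compute_regions()].
#' @param threshold inclusive threshold in `[0, 1]`.
#' @inheritParams region_support
#' @return data frame with `event`, `support`.
#' @export
consensus_support <- function(regions, threshold = 0, merge_dups = FALSE) {
  if (!length(regions)) stop("need at least one region")
  sets <- lapply(regions, function(r)
    names(select_dup_identities(r$descriptor$events, merge_dups)))
  all_ev <- sort(unique(unlist(sets)))
  frac <- vapply(all_ev, function(e)
    mean(vapply(sets, function(s) e %in% s, TRUE)), 0)
  out <- data.frame(event = all_ev, support = unname(frac),
                    stringsAsFactors = FALSE)
  out[out$support >= threshold, , drop = FALSE]
}

# choose between plain ("dup|") and merged ("mdup|") duplication identities
select_dup_identities <- function(E, merge_dups) {
  if (!length(E)) return(E)
  if (merge_dups) E[!startsWith(names(E), "dup|")]
  else E[!startsWith(names(E), "mdup|")]
}

#' Verify a computed region partition exactly
#'
#' Two certificates, both in exact integer arithmetic: (1) the positive-area
#' region areas sum exactly to the box area (together with the construction
#' this implies pairwise-disjoint interiors up to measure zero); (2) at
#' `n_points` random interior points of every positive-area region, the
#' owning event count strictly minimizes the reconciliation cost among all
#' front counts (which also implies the point lies in no other region).
#' Interior points are integer-weight convex combinations of the region's
#' vertices over a common denominator, so every comparison is an exact
#' integer sign test.
#'
#' @param regions regions from [compute_regions()].
#' @param front the descriptor list the regions were computed from.
#' @param box the `dlc_costbox` used.
#' @param n_points interior points per positive-area region.
#' @return list with logicals `areas_sum_to_box` and `interiors_owned`.
#' @export
verify_landscape <- function(regions, front, box, n_points = 1000L) {
  if (inherits(front, "dlc_front")) front <- front$front
  total <- rat(0)
  for (r in regions) if (r$dim == 2L) total <- rat_add(total, r$area_rat)
  box_area <- rat_mul(rat_sub(box$dmax, box$dmin),
                      rat_sub(box$lmax, box$lmin))
  areas_ok <- rat_cmp(total, box_area) == 0
  vs <- lapply(front, `[[`, "v")
  owned <- TRUE
  for (r in regions) {
    if (r$dim != 2L) next
    nv <- length(r$vertices)
    dens <- unique(c(vapply(r$vertices, function(v) v$x[2], 0),
                     vapply(r$vertices, function(v) v$y[2], 0)))
    L <- Reduce(rat_lcm, dens)
    if (L > 1e7) stop("vertex denominators too large for exact point check")
    Nx <- vapply(r$vertices, function(v) v$x[1] * (L / v$x[2]), 0)
    Ny <- vapply(r$vertices, function(v) v$y[1] * (L / v$y[2]), 0)
    W <- matrix(sample.int(9L, n_points * nv, replace = TRUE), n_points, nv)
    xn <- as.vector(W %*% Nx)
    yn <- as.vector(W %*% Ny)
    wsum <- rowSums(W)
    for (v2 in vs) {
      dd <- r$v[1] - v2[1]; dl <- r$v[2] - v2[2]; dc <- r$v[3] - v2[3]
      if (dd == 0 && dl == 0 && dc == 0) next
      # cost(owner) - cost(v2), over the common positive denominator
      val <- dd * xn + dl * yn + dc * wsum * L
      if (any(val >= 0)) { owned <- FALSE; break }
    }
    if (!owned) break
  }
  list(areas_sum_to_box = areas_ok, interiors_owned = owned)
}

#' Replace duplication identities by their merged form
#'
#' Two duplications in a species branch that differ only in which lineage
#' set keeps the mother locus and which takes the daughter locus yield the
#' same sets of paralogs; this view identifies them.  Frequencies are exact
#' (tracked at emission), not summed post hoc.
#'
#' @param E a named numeric event vector.
#' @return the event vector with plain duplication ids removed and merged
#'   ids retained.
#' @export
merge_dup_identities <- function(E) {
  select_dup_identities(E, merge_dups = TRUE)
}
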