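# Shared fixtures: exhaustive topology enumeration, instance builders and a
# cached oracle/DP battery used by several test files.

# all rooted binary labeled topologies over a label set, as Newick strings
# (without the trailing ";"); grows as (2n-3)!!
all_topologies <- function(labels) {
  if (length(labels) == 1L) return(labels)
  prev <- all_topologies(labels[-length(labels)])
  x <- labels[length(labels)]
  out <- character(0)
  graft <- function(s) {
    res <- sprintf("(%s,%s)", s, x)
    if (startsWith(s, "(")) {
      depth <- 0L
      chars <- strsplit(s, "")[[1]]
      for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") depth <- depth - 1L
        if (chars[i] == "," && depth == 1L) {
          left <- substr(s, 2L, i - 1L)
          right <- substr(s, i + 1L, nchar(s) - 1L)
          res <- c(res, sprintf("(%s,%s)", graft(left), right),
                   sprintf("(%s,%s)", left, graft(right)))
          break
        }
      }
    }
    res
  }
  for (p in prev) out <- c(out, graft(p))
  out
}

# deterministic congruent instance of a given size
congruent_instance <- function(n, seed = 1L) {
  inst <- generate_instance(instance_spec(n_species = n, seed = seed))
  inst
}

# check one instance: DP front == oracle front (exact)
check_instance <- function(g, s, lm) {
  fr <- reconcile_landscape(g, s, lm)
  en <- enumerate_all_lcts(g, s, lm)
  list(fr = fr, of = oracle_front(en),
       cmp = dlcpareto:::compare_fronts(fr$front, oracle_front(en)))
}

# ---- cached batteries (shared across acceptance criteria) -----------------

.battery_env <- new.env(parent = emptyenv())

# exhaustive battery: all gene topologies (<= max_g leaves) x all species
# topologies (<= max_s leaves) x all leaf maps
exhaustive_battery <- function(max_g = 4L, max_s = 3L) {
  key <- sprintf("ex_%d_%d", max_g, max_s)
  if (!is.null(.battery_env[[key]])) return(.battery_env[[key]])
  out <- list()
  for (ng in seq_len(max_g)) {
    gts <- all_topologies(paste0("g", seq_len(ng)))
    gtrees <- lapply(gts, function(g) read_newick(paste0(g, ";"), "gene"))
    for (ms in seq_len(max_s)) {
      sts <- all_topologies(LETTERS[seq_len(ms)])
      strees <- lapply(sts, function(s)
        read_newick(paste0(s, ";"), "species"))
      maps <- as.matrix(expand.grid(rep(list(seq_len(ms)), ng)))
      for (gi in seq_along(gts)) for (si in seq_along(sts))
        for (r in seq_len(nrow(maps))) {
          lm <- stats::setNames(LETTERS[maps[r, ]], paste0("g", seq_len(ng)))
          fr <- reconcile_landscape(gtrees[[gi]], strees[[si]], lm)
          en <- enumerate_all_lcts(gtrees[[gi]], strees[[si]], lm)
          out[[length(out) + 1L]] <-
            list(g = gts[[gi]], s = sts[[si]], lm = lm, front = fr$front,
                 oracle = oracle_front(en))
        }
    }
  }
  .battery_env[[key]] <- out
  out
}

# random generated battery within the oracle limits
random_battery <- function(n = 200L, seed = 20240901L) {
  key <- sprintf("rnd_%d_%d", n, seed)
  if (!is.null(.battery_env[[key]])) return(.battery_env[[key]])
  out <- list()
  i <- 0L
  while (length(out) < n) {
    i <- i + 1L
    sp <- instance_spec(
      n_species = 2L + (i %% 3L),               # 2..4 species
      genes_per_species = 1 + (i %% 2L) * 0.4,
      dup_rate = c(0, 0.2, 0.4)[1L + (i %% 3L)],
      loss_rate = c(0, 0.15)[1L + (i %% 2L)],
      ils_rate = c(0, 0.15, 0.3)[1L + ((i %/% 2L) %% 3L)],
      seed = seed + i)
    inst <- generate_instance(sp)
    if (length(tree_leaves(inst$G)) > 5L) next
    fr <- tryCatch(reconcile_landscape(inst$G, inst$S, inst$leaf_map),
                   error = function(e) NULL)
    if (is.null(fr)) next
    en <- enumerate_all_lcts(inst$G, inst$S, inst$leaf_map)
    out[[length(out) + 1L]] <-
      list(inst = inst, front = fr$front, oracle = oracle_front(en))
  }
  .battery_env[[key]] <- out
  out
}

# random descriptor generator for algebra property tests
random_descriptor_set <- function(n_max = 4L, ev_pool = paste0("e", 1:6)) {
  n <- sample.int(n_max, 1L)
  seen <- character(0)
  out <- list()
  for (i in seq_len(n)) {
    v <- sample.int(4L, 3L, replace = TRUE) - 1L
    key <- paste(v, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    kappa <- sample.int(4L, 1L)
    nev <- sample.int(4L, 1L) - 1L
    ev <- if (nev > 0L) {
      ids <- sample(ev_pool, nev)
      stats::setNames(sample.int(kappa, nev, replace = TRUE), ids)
    } else numeric(0)
    out[[length(out) + 1L]] <- descriptor(v, kappa, ev)
  }
  out
}

expect_front_equal <- function(A, B) {
  expect_true(isTRUE(dlcpareto:::compare_fronts(A, B)))
}
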