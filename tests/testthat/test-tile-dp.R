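# Tile enumeration, relative locus pairs and the stitching DP.

test_that("relative locus pairs are dense and renaming-invariant", {
  dec <- prepare_instance(read_newick("((a1,b1),(a2,b2));", "gene"),
                          read_newick("(A,B);", "species"),
                          c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  sA <- which(dec$S$label == "A")
  # two tops sharing a locus, bottoms inherit: t=(1,1), b=(1,1)
  slm <- sublocus_map(dec, sA, c(1L, 1L), integer(0))
  rp <- relative_pair(slm, dec)
  expect_equal(rp$t, c(1L, 1L)); expect_equal(rp$b, c(1L, 1L))
  # one bottom dup-created: numbering continues after the top loci
  leafA <- intersect(dec$nodes[[sA]], tree_leaves(dec$G))
  slm2 <- sublocus_map(dec, sA, c(1L, 1L), flags = leafA[1])
  rp2 <- relative_pair(slm2, dec)
  expect_equal(rp2$t, c(1L, 1L)); expect_equal(rp2$b, c(2L, 1L))
  # renaming top loci leaves the pair unchanged
  slm3 <- sublocus_map(dec, sA, c(7L, 7L), flags = leafA[1])
  slm3$locus <- slm2$locus + 10L
  expect_equal(relative_pair(slm3, dec), rp2)
})

test_that("tiles enumerate duplication placements under extant distinctness", {
  # empty species branch: one trivial tile
  dec <- prepare_instance(read_newick("(a,c);", "gene"),
                          read_newick("((A,B),C);", "species"),
                          c(a = "A", c = "C"))
  sB <- which(dec$S$label == "B")
  tiles <- enumerate_tiles(sB, 1L, dec)
  expect_length(tiles, 1L)
  expect_equal(tiles[[1]]$desc$v, c(0L, 1L, 0L))  # inherited locus is lost

  # species leaf holding the gene root and two genes: the single-dup
  # placements are optimal tiles with one coalescence-minimal order each;
  # the double-dup map is also a valid tile (dominated later, at the fold)
  dec2 <- prepare_instance(read_newick("(a1,a2);", "gene"),
                           read_newick("A;", "species"),
                           c(a1 = "A", a2 = "A"))
  tiles2 <- enumerate_tiles(1L, 1L, dec2)
  expect_length(tiles2, 3L)
  one_dup <- Filter(function(tl) tl$desc$v[1] == 1L, tiles2)
  expect_length(one_dup, 2L)
  for (tl in one_dup) {
    expect_equal(tl$desc$v, c(1L, 0L, 0L))
    expect_equal(tl$desc$kappa, 1)
  }

  # truly empty branch (no tops, no nodes)
  dec3 <- prepare_instance(read_newick("(a,b);", "gene"),
                           read_newick("((A,B),C);", "species"),
                           c(a = "A", b = "B"))
  # pruned to the (A,B) clade; fabricate an empty-species check via a
  # species with no nodes in the pruned tree is not present here, so check
  # the trivial pattern directly on a C-less decomposition
  expect_equal(length(tree_leaves(dec3$S)), 2L)
})

test_that("the stitched front matches hand-derived micro-instances", {
  # congruent instances: single zero descriptor, kappa 1, n-1 speciations
  for (nwk in list(c("((a,b),c);", "((A,B),C);"),
                   c("((a,b),(c,d));", "((A,B),(C,D));"))) {
    lm <- stats::setNames(toupper(letters[1:(nchar(gsub("[^a-z]", "", nwk[1])))]),
                          letters[1:(nchar(gsub("[^a-z]", "", nwk[1])))])
    fr <- reconcile_landscape(nwk[1], nwk[2], lm)
    expect_length(fr$front, 1L)
    expect_equal(fr$front[[1]]$v, c(0L, 0L, 0L))
    expect_equal(fr$front[[1]]$kappa, 1)
    n <- length(lm)
    expect_equal(sum(startsWith(names(fr$front[[1]]$events), "spec|")), n - 1L)
  }

  # one species, two genes
  fr2 <- reconcile_landscape("(a1,a2);", "A;", c(a1 = "A", a2 = "A"))
  expect_length(fr2$front, 1L)
  expect_equal(fr2$front[[1]]$v, c(1L, 0L, 0L))
  expect_equal(fr2$front[[1]]$kappa, 2)
  dups <- fr2$front[[1]]$events[startsWith(names(fr2$front[[1]]$events), "dup|")]
  expect_length(dups, 2L)
  expect_equal(unname(dups), c(1, 1))

  # single gene leaf
  fr3 <- reconcile_landscape("a1;", "(A,B);", c(a1 = "A"))
  expect_length(fr3$front, 1L)
  expect_equal(fr3$front[[1]]$v, c(0L, 0L, 0L))
})

test_that("stitching equals the oracle on targeted incongruent instances", {
  cases <- list(
    list(g = "((a1,b1),b2);", s = "(A,B);",
         lm = c(a1 = "A", b1 = "B", b2 = "B")),
    list(g = "((a1,b1),(a2,b2));", s = "(A,B);",
         lm = c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")),
    list(g = "((a1,c1),b1);", s = "((A,B),C);",
         lm = c(a1 = "A", c1 = "C", b1 = "B")),
    list(g = "(((a1,b1),c1),c2);", s = "((A,B),C);",
         lm = c(a1 = "A", b1 = "B", c1 = "C", c2 = "C")))
  for (cs in cases) {
    chk <- check_instance(cs$g, cs$s, cs$lm)
    expect_true(isTRUE(chk$cmp))
  }
})

test_that("swapping species children leaves the front unchanged", {
  lm <- c(a1 = "A", b1 = "B", b2 = "B", c1 = "C")
  fr1 <- reconcile_landscape("(((a1,b1),b2),c1);", "((A,B),C);", lm)
  fr2 <- reconcile_landscape("(((a1,b1),b2),c1);", "((B,A),C);", lm)
  fr3 <- reconcile_landscape("(((a1,b1),b2),c1);", "(C,(A,B));", lm)
  key <- function(fr) vapply(fr$front, function(a)
    sprintf("%s#%g", paste(a$v, collapse = ","), a$kappa), "")
  expect_setequal(key(fr1), key(fr2))
  expect_setequal(key(fr1), key(fr3))
})

test_that("two runs are deterministic and pruning dead clades is a no-op", {
  lm <- c(a1 = "A", b1 = "B", b2 = "B")
  f1 <- reconcile_landscape("((a1,b1),b2);", "(A,B);", lm)
  f2 <- reconcile_landscape("((a1,b1),b2);", "(A,B);", lm)
  expect_identical(f1$front, f2$front)
  # adding an unused outgroup species outside the pruned root changes nothing
  f3 <- reconcile_landscape("((a1,b1),b2);", "((A,B),Z);", lm)
  expect_identical(vapply(f1$front, function(a) paste(a$v, collapse = ","), ""),
                   vapply(f3$front, function(a) paste(a$v, collapse = ","), ""))
  expect_equal(vapply(f1$front, `[[`, 0, "kappa"),
               vapply(f3$front, `[[`, 0, "kappa"))
})

test_that("the width guard refuses high-k instances", {
  # many genes of one family in two species force a wide decomposition
  g <- "((((((a1,b1),a2),b2),a3),b3),((((a4,b4),a5),b5),a6));"
  lm <- stats::setNames(rep(c("A", "B"), 6)[1:11],
                        c("a1","b1","a2","b2","a3","b3","a4","b4","a5","b5","a6"))
  expect_error(reconcile_landscape(g, "(A,B);", lm, max_width = 2L),
               "max_width")
})

test_that("top-pattern counts respect the Bell-number width bound", {
  bell <- c(1, 2, 5, 15, 52)
  cases <- list(
    list(g = "((a1,b1),(a2,b2));", s = "(A,B);",
         lm = c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")),
    list(g = "(((a1,b1),b2),c1);", s = "((A,B),C);",
         lm = c(a1 = "A", b1 = "B", b2 = "B", c1 = "C")))
  for (cs in cases) {
    dec <- prepare_instance(read_newick(cs$g, "gene"),
                            read_newick(cs$s, "species"), cs$lm)
    tt <- build_tile_tables(dec)
    for (s in seq_along(tt$patterns)) {
      npat <- length(tt$patterns[[s]])
      width <- max(1L, length(dec$tops[[s]]))
      expect_lte(npat, bell[width])
    }
  }
})
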