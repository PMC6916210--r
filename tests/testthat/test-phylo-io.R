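# Tree parsing, LCA species map, pruning, implied nodes and decomposition.

test_that("Newick parsing accepts strict rooted binary trees and rejects the rest", {
  tr <- read_newick("((a,b),c);", role = "gene")
  expect_s3_class(tr, "dlc_tree")
  expect_equal(length(tree_leaves(tr)), 3L)
  expect_equal(sort(tr$label[tree_leaves(tr)]), c("a", "b", "c"))
  # root is node 1 in pre-order and has two children
  expect_equal(tr$root, 1L)
  expect_equal(length(tr$children[[tr$root]]), 2L)

  bal <- read_newick("((a,b),(c,d));", "gene")
  expect_equal(length(tree_leaves(bal)), 4L)

  expect_error(read_newick("(a);", "gene"))              # unary root
  expect_error(read_newick("(a,b,c);", "gene"))          # multifurcation
  expect_error(read_newick("((a,b),a);", "gene"), "duplicate")
  expect_error(read_newick("((a,b", "gene"))

  single <- read_newick("a1;", "gene")
  expect_equal(length(tree_leaves(single)), 1L)
  expect_equal(single$label[[1]], "a1")
})

test_that("Newick writing round-trips topology and labels", {
  for (nwk in c("((a,b),c);", "((a,b),(c,d));", "(((x1,x2),y),z);")) {
    tr <- read_newick(nwk, "gene")
    tr2 <- read_newick(write_newick(tr), "gene")
    expect_equal(write_newick(tr2), write_newick(tr))
    expect_equal(sort(tr2$label[tree_leaves(tr2)]),
                 sort(tr$label[tree_leaves(tr)]))
  }
})

test_that("leaf maps parse from TSV, tolerate many-to-one, and enforce totality", {
  lm <- read_leaf_map("a1\tA\nb1\tB")
  expect_equal(lm, c(a1 = "A", b1 = "B"))
  # not one-to-one: two genes in the same species is valid
  lm2 <- read_leaf_map("a1\tA\na2\tA")
  expect_equal(unname(lm2), c("A", "A"))
  expect_error(read_leaf_map("a1 A"), "malformed")
  expect_error(read_leaf_map("a1\tA\na1\tB"), "multiple")

  G <- read_newick("(a1,a2);", "gene")
  S <- read_newick("(A,B);", "species")
  expect_error(lca_species_map(G, S, c(a1 = "A")), "omits")
  expect_error(lca_species_map(G, S, c(a1 = "A", a2 = "Z")), "unknown")
})

test_that("the LCA species map maps internal nodes to leaf-image LCAs", {
  G <- read_newick("((a,b),c);", "gene")
  S <- read_newick("((A,B),C);", "species")
  M <- lca_species_map(G, S, c(a = "A", b = "B", c = "C"))
  # pre-order: root=1, (a,b)=2, a=3, b=4, c=5 in G; root=1, AB=2 in S
  expect_equal(M[G$root], S$root)
  expect_equal(M[2], 2L)

  # incongruent clade maps to the species root
  G2 <- read_newick("((a1,c1),b1);", "gene")
  M2 <- lca_species_map(G2, S, c(a1 = "A", c1 = "C", b1 = "B"))
  expect_equal(M2[2], S$root)

  # single-leaf gene tree
  G3 <- read_newick("a1;", "gene")
  M3 <- lca_species_map(G3, S, c(a1 = "A"))
  expect_equal(S$label[M3[1]], "A")
})

test_that("pruning restricts the species tree to the gene-root image", {
  S <- read_newick("((A,B),C);", "species")
  # all genes in A: pruned tree is the single leaf A
  G <- read_newick("(a1,a2);", "gene")
  M <- lca_species_map(G, S, c(a1 = "A", a2 = "A"))
  pr <- prune_to_root(S, M, G)
  expect_equal(length(tree_leaves(pr$tree)), 1L)
  expect_equal(pr$tree$label[[1]], "A")
  # genes spanning A and C: whole tree kept
  M2 <- lca_species_map(G, S, c(a1 = "A", a2 = "C"))
  expect_equal(length(tree_leaves(prune_to_root(S, M2, G)$tree)), 3L)
  # genes spanning A and B: the (A,B) clade
  M3 <- lca_species_map(G, S, c(a1 = "A", a2 = "B"))
  pr3 <- prune_to_root(S, M3, G)
  expect_equal(sort(pr3$tree$label[tree_leaves(pr3$tree)]), c("A", "B"))
})

test_that("implied nodes make every gene branch span one species branch", {
  S <- read_newick("((A,B),C);", "species")
  # branch root->a crosses the (A,B) ancestor: one implied node
  G <- read_newick("(a,c);", "gene")
  M <- lca_species_map(G, S, c(a = "A", c = "C"))
  im <- add_implied_nodes(G, S, M)
  expect_equal(n_nodes(im$tree), n_nodes(G) + 1L)
  unary <- which(vapply(im$tree$children, length, 1L) == 1L)
  expect_equal(length(unary), 1L)
  expect_equal(im$M[unary], 2L)  # the (A,B) ancestor in pre-order

  # congruent trees need no implied nodes
  Gc <- read_newick("((a,b),c);", "gene")
  Mc <- lca_species_map(Gc, S, c(a = "A", b = "B", c = "C"))
  expect_equal(n_nodes(add_implied_nodes(Gc, S, Mc)$tree), n_nodes(Gc))

  # mixed node: parent keeps a child in its own species, so a boundary node
  # is inserted even though the species are adjacent
  S2 <- read_newick("(A,B);", "species")
  G2 <- read_newick("((a1,b1),b2);", "gene")
  M2 <- lca_species_map(G2, S2, c(a1 = "A", b1 = "B", b2 = "B"))
  im2 <- add_implied_nodes(G2, S2, M2)
  expect_equal(n_nodes(im2$tree), n_nodes(G2) + 1L)
  dec2 <- decompose(im2$tree, S2, im2$M)
  # both lineages crossing into B appear as bottoms of the root species
  expect_equal(length(dec2$bottoms[[1]]), 2L)
})

test_that("branch-locality holds after implied-node insertion", {
  insts <- list(
    list(g = "((a,c),(b,c2));", s = "((A,B),C);",
         lm = c(a = "A", c = "C", b = "B", c2 = "C")),
    list(g = "(((a1,b1),c1),a2);", s = "((A,B),C);",
         lm = c(a1 = "A", b1 = "B", c1 = "C", a2 = "A")))
  for (it in insts) {
    dec <- prepare_instance(read_newick(it$g, "gene"),
                            read_newick(it$s, "species"), it$lm)
    G <- dec$G; S <- dec$S; M <- dec$M
    for (g in seq_len(length(G$parent))) {
      p <- G$parent[g]
      if (is.na(p)) next
      expect_true(M[p] == M[g] || identical(S$parent[M[g]], M[p]))
    }
  }
})

test_that("LCA map is unchanged on original nodes after implied insertion", {
  S <- read_newick("((A,B),C);", "species")
  G <- read_newick("((a,c),b);", "gene")
  lm <- c(a = "A", c = "C", b = "B")
  M <- lca_species_map(G, S, lm)
  im <- add_implied_nodes(G, S, M)
  M_re <- lca_species_map_check <- local({
    # recompute the LCA map on the implied tree; original images unchanged
    dec <- decompose(im$tree, S, im$M)
    im$M
  })
  expect_equal(M_re[im$old2new], M)
})

test_that("decomposition partitions gene nodes and sets tops from parents", {
  dec <- prepare_instance(read_newick("((a,b),c);", "gene"),
                          read_newick("((A,B),C);", "species"),
                          c(a = "A", b = "B", c = "C"))
  ns <- length(dec$nodes)
  expect_equal(sum(vapply(dec$nodes, length, 1L)),
               length(dec$G$parent))
  expect_equal(dec$tops[[dec$S$root]], dec$G$root)
  for (s in seq_len(ns)) {
    p <- dec$S$parent[s]
    if (!is.na(p)) expect_equal(dec$tops[[s]], dec$bottoms[[p]])
  }
  expect_equal(dec$k, 1L)  # congruent: width one

  # species entered by no lineage still lists its parent bottoms as tops
  dec2 <- prepare_instance(read_newick("(a,c);", "gene"),
                           read_newick("((A,B),C);", "species"),
                           c(a = "A", c = "C"))
  bspecies <- which(dec2$S$label == "B")
  expect_equal(length(dec2$nodes[[bspecies]]), 0L)
  expect_gt(length(dec2$tops[[bspecies]]), 0L)
})
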