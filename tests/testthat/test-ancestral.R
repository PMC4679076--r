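# Dollo parsimony reconstruction and ancestral count matrices.

test_that("newick parsing validates the binary rooted contract", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)
  expect_equal(sort(tr$node.label), c("N1", "N2", "N3"))

  expect_error(parse_newick("((A,B,C),D);"), "not-binary")
  expect_error(parse_newick("((A,B),(A,D));"), "duplicate leaf")

  # labels are deterministic postorder ids, stable across reparses
  tr2 <- parse_newick("((A,B),(C,D));")
  expect_identical(tr$node.label, tr2$node.label)
  # existing unique internal labels are kept
  tr3 <- parse_newick("((A,B)ab,(C,D)cd)root;")
  expect_equal(sort(tr3$node.label), c("ab", "cd", "root"))
})

test_that("a fully resolved binary tree has one fewer internal node than leaves", {
  for (n in c(5L, 23L)) {
    phy <- validate_phylogeny(ape::rphylo(n, birth = 1, death = 0))
    expect_equal(phy$Nnode, n - 1L)
  }
})

test_that("dollo presence is the spanning subtree of the possessing leaves", {
  tr <- parse_newick("((A,B),(C,D));")
  # all leaves: present everywhere, gained at the root, no losses
  all_nodes <- sort(c(tr$tip.label, tr$node.label))
  expect_equal(dollo_presence(tr, c("A", "B", "C", "D")), all_nodes)
  ev <- dollo_events(tr, c("A", "B", "C", "D"))
  expect_equal(ev$losses, character(0))

  # disjoint leaves: both internal ancestors and the root, two losses
  expect_equal(dollo_presence(tr, c("A", "C")),
               sort(c("A", "C", "N1", "N2", "N3")))
  ev2 <- dollo_events(tr, c("A", "C"))
  expect_equal(ev2$losses, c("B", "D"))

  # single leaf: gained at the leaf itself
  expect_equal(dollo_presence(tr, "A"), "A")
  expect_equal(dollo_events(tr, "A")$gain, "A")
  expect_equal(dollo_events(tr, "A")$losses, character(0))

  expect_error(dollo_presence(tr, character(0)), "non-empty")
  expect_error(dollo_presence(tr, "Z"), "unknown leaf")
})

test_that("dollo reconstruction matches the exhaustive single-gain oracle", {
  # every unlabeled shape with 2..5 leaves x every presence pattern
  for (n in 2:5) {
    for (nwk in all_tree_shapes(n)) {
      tr <- parse_newick(nwk)
      tips <- tr$tip.label
      for (mask in seq_len(2^n - 1L)) {
        leaves <- tips[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
        fast <- dollo_presence(tr, leaves)
        ev <- dollo_events(tr, leaves)
        oracle <- brute_force_dollo(tr, leaves)
        expect_equal(length(oracle$solutions), 1L)
        expect_equal(fast, oracle$solutions[[1L]])
        expect_equal(length(ev$losses), oracle$losses)
      }
    }
  }
})

test_that("random larger trees agree with the oracle too", {
  set.seed(88)
  for (rep in 1:25) {
    tr <- validate_phylogeny(ape::rtree(7L))
    leaves <- sample(tr$tip.label, sample(1:7, 1L))
    oracle <- brute_force_dollo(tr, leaves)
    expect_equal(dollo_presence(tr, leaves), oracle$solutions[[1L]])
  }
  expect_error(brute_force_dollo(validate_phylogeny(ape::rtree(9L)), "t1"),
               "capped")
})

test_that("ancestral counts follow the per-architecture reconstructions", {
  tr <- parse_newick("((A,B),(C,D));")
  tab <- rbind(assignments_df("A,B", genome_id = "A"),
               assignments_df("A,B", genome_id = "C"),
               assignments_df("Z", genome_id = "B"),
               assignments_df("Z", genome_id = "D"))
  m <- ancestral_count_matrix(tab, tr)
  # "A,B" spans A and C: present at every internal node
  expect_equal(unname(m["A", c("N1", "N2", "N3")]), c(1L, 1L, 1L))
  expect_equal(unname(m["B", c("N1", "N2", "N3")]), c(1L, 1L, 1L))
  expect_equal(attr(m, "genome_type"), "ancestral")

  # an architecture confined to one leaf contributes to no internal node
  tab2 <- rbind(tab, assignments_df("Q,Q", genome_id = "A"))
  tab2$protein_id <- sprintf("p%03d", seq_len(nrow(tab2)))
  m2 <- ancestral_count_matrix(tab2, tr)
  expect_false("Q" %in% rownames(m2)[rowSums(m2) > 0])

  # two identical leaf repertoires under the root of a 2-leaf tree
  tr2 <- parse_newick("(X,Y);")
  tab3 <- rbind(assignments_df("A,B", "C", genome_id = "X"),
                assignments_df("A,B", "C", genome_id = "Y"))
  tab3$protein_id <- sprintf("p%03d", seq_len(nrow(tab3)))
  m3 <- ancestral_count_matrix(tab3, tr2)
  extant <- build_arch_count_matrix(tab3)
  expect_equal(unname(m3[, 1L]), unname(extant[rownames(m3), "X"]))

  expect_error(ancestral_count_matrix(tab[tab$genome_id != "B", ], tr),
               "leaf genome.*B")
})

test_that("reconstructed presence is contained in the simulated truth", {
  set.seed(314)
  phy <- validate_phylogeny(ape::rphylo(12L, birth = 1, death = 0))
  archs <- build_genome_from_counts(
    sample_superfamily_diversity(60L, 2), "ROOT")$architecture
  evo <- evolve_architectures_on_tree(phy, archs, loss_prob = 0.35)
  labs <- colnames(evo$presence)
  tips <- phy$tip.label
  checked <- 0L
  for (a in rownames(evo$presence)) {
    surviving <- tips[evo$presence[a, tips]]
    if (length(surviving) == 0L) next
    recon <- dollo_presence(phy, surviving)
    true_set <- labs[evo$presence[a, ]]
    expect_true(all(recon %in% true_set))
    # equality whenever every true-present node kept a surviving leaf below
    # AND the gain node is recoverable as the MRCA of the survivors (no
    # unrecoverable spine above the MRCA)
    desc_ok <- all(vapply(true_set, function(v) {
      any(descendant_tips(phy, v) %in% surviving)
    }, logical(1L)))
    if (desc_ok && evo$gain[[a]] %in% recon) expect_setequal(recon, true_set)
    checked <- checked + 1L
  }
  expect_gt(checked, 30L)
})
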