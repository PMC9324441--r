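test_that("quartet score matches direct enumeration on worked cases", {
  taxa <- LETTERS[1:5]
  loci <- loci_from_splits(list(c("A", "B")), taxa)
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  expect_equal(quartet_score(t1, loci), 3)
  expect_equal(quartet_score(t2, loci), 1)
  expect_equal(brute_force_score(t1, loci), 3)
  expect_equal(brute_force_score(t2, loci), 1)
  empty <- structure(list(), taxa = taxa, class = "ri_loci")
  expect_equal(quartet_score(t1, empty), 0)
  # locus taxon absent from the species tree errors
  t_small <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(quartet_score(t_small, loci), "absent")
})

test_that("weighted scores scale with weights and drop zero-weight edges", {
  set.seed(11)
  inst <- random_instance(6, 12)
  tr <- random_unrooted(inst$taxa)
  loci100 <- inst$loci # bp_loci default weight 100
  expect_equal(quartet_score(tr, loci100, weighted = TRUE),
               100 * quartet_score(tr, loci100, weighted = FALSE))
  loci0 <- bp_loci(to_bipartitions(ri_matrix(inst$states), 2L), weight = 0)
  expect_equal(quartet_score(tr, loci0, weighted = TRUE), 0)
})

test_that("score is invariant under consistent taxon relabeling", {
  set.seed(5)
  inst <- random_instance(7, 10)
  tr <- random_unrooted(inst$taxa)
  sc <- quartet_score(tr, inst$loci)
  # relabel t1..t7 -> u7..u1 everywhere
  map <- setNames(paste0("u", 7:1), inst$taxa)
  states2 <- inst$states
  rownames(states2) <- unname(map[rownames(states2)])
  tr2 <- tr
  tr2$tip.label <- unname(map[tr$tip.label])
  loci2 <- bp_loci(to_bipartitions(ri_matrix(states2), 2L))
  expect_equal(quartet_score(tr2, loci2), sc)
})

test_that("branch tallies count induced quartets around a branch", {
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  taxa4 <- LETTERS[1:4]
  bt <- branch_tally(t4, loci_from_splits(list(c("A", "B")), taxa4),
                     c("A", "B"))
  expect_equal(unname(bt$n), c(1, 0, 0))
  expect_equal(bt$EN, 1L)

  conflict <- loci_from_splits(list(c("A", "B"), c("A", "C"), c("A", "D")),
                               taxa4)
  bt3 <- branch_tally(t4, conflict, c("A", "B"))
  expect_equal(unname(bt3$n), c(1, 1, 1))
  expect_equal(bt3$EN, 3L)

  # clusters of sizes 2,1,1,1: locus {a1,a2,b}|{c,d} contributes 2 to n1
  t5 <- ape::read.tree(text = "((a1,a2),(b,(c,d)));")
  taxa5 <- c("a1", "a2", "b", "c", "d")
  l5 <- loci_from_splits(list(c("a1", "a2", "b")), taxa5)
  bt5 <- branch_tally(t5, l5, c("a1", "a2", "b"))
  expect_equal(unname(bt5$n), c(2, 0, 0))

  term_edge <- which(t4$edge[, 2L] <= 4L)[1L]
  expect_error(branch_tally(t4, conflict, term_edge), "erminal")
})

test_that("per-branch n1 of a locus never exceeds the cluster product", {
  set.seed(23)
  for (rep in 1:20) {
    inst <- random_instance(7, 8)
    tr <- random_unrooted(inst$taxa)
    tls <- branch_tallies(tr, inst$loci)
    for (tl in tls) {
      cap <- prod(lengths(tl$clusters))
      expect_true(all(rowSums(tl$per_locus) <= cap))
      expect_equal(sum(tl$n), tl$m)
      expect_true(tl$EN <= length(inst$loci))
    }
  }
})

test_that("gene-tree loci read edge supports and collapse below threshold", {
  # 5-taxon unrooted tree: two nontrivial splits, {A,B} and {C,D}
  tr <- ape::read.tree(text = "((A,B)95,((C,D)3,E)80);")
  taxa <- LETTERS[1:5]
  loci <- gene_tree_loci(list(tr), taxa, weight_mode = "support")
  expect_length(loci[[1L]]$sides, 2L)
  expect_true(3 %in% loci[[1L]]$weights)

  collapsed <- collapse_low_support(loci, threshold = 5)
  expect_length(collapsed[[1L]]$sides, 1L)
  expect_false(3 %in% collapsed[[1L]]$weights)

  # direct read with collapse argument agrees
  loci2 <- gene_tree_loci(list(tr), taxa, weight_mode = "support",
                          collapse = 5)
  expect_length(loci2[[1L]]$sides, 1L)

  # all supports below threshold -> star tree, zero quartets anywhere
  star <- collapse_low_support(loci, threshold = 100)
  expect_length(star[[1L]]$sides, 0L)
  expect_equal(quartet_score(tr, star), 0)

  # phylo method contracts the edge but keeps all leaves
  ctr <- collapse_low_support(tr, 5)
  expect_setequal(ctr$tip.label, taxa)
  expect_length(tree_splits(ctr, sort(taxa)), 1L)
  # fully supported tree unchanged topologically at threshold 5
  keep <- collapse_low_support(ape::read.tree(text = "((A,B)100,((C,D)90,E)80);"), 5)
  expect_length(tree_splits(keep, sort(taxa)), 2L)
})

test_that("multi-edge gene trees score once per 4-subset with min-support weights", {
  taxa <- LETTERS[1:5]
  gt <- ape::read.tree(text = "((A,B)60,(C,(D,E)40)90);")
  loci <- gene_tree_loci(list(gt), taxa, weight_mode = "support")
  ref <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  # unweighted: every resolved 4-subset of the gene tree agrees: C(5,4)=5
  expect_equal(quartet_score(ref, loci), 5)
  expect_equal(brute_force_score(ref, loci), 5)
  # weighted: min support along the central path of each quartet
  expect_equal(quartet_score(ref, loci, weighted = TRUE),
               brute_force_score(ref, loci, weighted = TRUE))
})
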