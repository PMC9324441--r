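test_that("exhaustive search recovers clean data, majorities, and flags ties", {
  # perfect data: the splits of one 6-taxon tree
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  loci <- bp_loci(to_bipartitions(clean_matrix_from_tree(tr), 2L))
  res <- exhaustive_search(loci)
  expect_false(res$tie)
  expect_equal(res$score, brute_force_score(res$tree, loci))
  expect_true(same_topology(res$tree, tr))

  # majority: {2 x AB|CD, 1 x AC|BD} -> AB|CD, score 2
  taxa4 <- LETTERS[1:4]
  maj <- loci_from_splits(list(c("A", "B"), c("A", "B"), c("A", "C")), taxa4)
  rmaj <- exhaustive_search(maj)
  expect_equal(rmaj$score, 2)
  expect_false(rmaj$tie)
  expect_true(displays_clade(rmaj$tree, c("A", "B"), taxa4))

  # tie: {1 x AB|CD, 1 x AC|BD} -> canonical tree with tie flag
  tie <- loci_from_splits(list(c("A", "B"), c("A", "C")), taxa4)
  rtie <- exhaustive_search(tie)
  expect_true(rtie$tie)
  expect_equal(rtie$score, 1)
  expect_length(rtie$ties, 2L)
  expect_equal(ape::write.tree(rtie$tree),
               ape::write.tree(ape::read.tree(text = sort(rtie$ties)[1L])))

  expect_error(exhaustive_search(maj, max_taxa = 3L), "capped")
})

test_that("hill climbing never beats the exhaustive optimum and almost always matches it", {
  set.seed(101)
  hits <- 0L
  n_rep <- 40L
  for (rep in seq_len(n_rep)) {
    inst <- random_instance(6, 10)
    ex <- exhaustive_search(inst$loci)
    hc <- hillclimb_search(inst$loci, restarts = 10L, seed = rep)
    expect_lte(hc$score, ex$score + 1e-9)
    if (abs(hc$score - ex$score) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("hill climbing is deterministic given a seed and recovers perfect data", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  loci <- bp_loci(to_bipartitions(clean_matrix_from_tree(tr, copies = 2L), 2L))
  r1 <- hillclimb_search(loci, restarts = 5L, seed = 99L)
  r2 <- hillclimb_search(loci, restarts = 5L, seed = 99L)
  expect_identical(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  expect_identical(r1$score, r2$score)
  # perfect data on 8 taxa: the generating topology is recovered
  expect_equal(r1$score, quartet_score(tr, loci))
  expect_true(same_topology(r1$tree, tr))
})

test_that("anti-constraint searches exclude the clade and score no higher", {
  taxa4 <- LETTERS[1:4]
  l3 <- loci_from_splits(rep(list(c("A", "B")), 3L), taxa4)
  ra <- anticonstraint_search(l3, forbidden_clade = c("A", "B"))
  expect_equal(ra$score, 0)
  expect_true(ra$tie)
  sp <- tree_splits(ra$tree, taxa4)
  expect_false(has_clade <- any(vapply(sp, function(s)
    identical(s$side, c(1L, 2L)) || identical(s$side, c(3L, 4L)), logical(1))))

  # forbidden clade absent from the optimum anyway: same score
  set.seed(3)
  inst <- random_instance(6, 12)
  opt <- exhaustive_search(inst$loci)
  keys <- vapply(tree_splits(opt$tree, inst$taxa), function(s)
    paste(s$side, collapse = ","), "")
  full <- seq_along(inst$taxa)
  absent <- NULL
  for (p in utils::combn(full, 2L, simplify = FALSE)) {
    k1 <- paste(p, collapse = ",")
    k2 <- paste(setdiff(full, p), collapse = ",")
    if (!(k1 %in% keys) && !(k2 %in% keys)) {
      absent <- inst$taxa[p]
      break
    }
  }
  ra2 <- anticonstraint_search(inst$loci, forbidden_clade = absent,
                               method = "exhaustive")
  expect_equal(ra2$score, opt$score)

  # forbidding the true clade of clean data strictly lowers the score
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  loci <- bp_loci(to_bipartitions(clean_matrix_from_tree(tr, 2L), 2L))
  unc <- exhaustive_search(loci)
  con <- anticonstraint_search(loci, forbidden_clade = c("C", "D"),
                               method = "exhaustive")
  expect_lt(con$score, unc$score)
  expect_error(anticonstraint_search(loci, forbidden_clade = "A"), "between")
})

test_that("SDP quartet parsimony builds MRP rows and recovers clean trees", {
  taxa4 <- LETTERS[1:4]
  m2 <- ri_matrix(matrix(rep(c(1L, 1L, 0L, 0L), 2L), 4, 2,
                         dimnames = list(taxa4, NULL)))
  r <- sdp_quartets(m2)
  expect_equal(ncol(r$mrp), 1L) # single subset, single optimal topology
  expect_equal(unname(r$mrp[, 1L]), c(1L, 1L, 0L, 0L))
  expect_equal(r$treelength, 1)  # the MRP row fits in one step
  expect_true(displays_clade(r$tree, c("A", "B"), taxa4))

  # tie in a subset encodes both optimal topologies
  mt <- ri_matrix(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)),
                  taxa = taxa4)
  rt <- sdp_quartets(mt)
  expect_equal(ncol(rt$mrp), 2L)

  # clean 5-taxon matrix: supertree = generating tree, treelength = rows
  tr5 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  m5 <- clean_matrix_from_tree(tr5, copies = 2L)
  r5 <- sdp_quartets(m5)
  expect_true(same_topology(r5$tree, tr5))
  expect_equal(r5$treelength, ncol(r5$mrp))
})

test_that("SDP and quartet hill climbing agree on clean simulated matrices", {
  set.seed(77)
  tr <- ape::rtree(15, rooted = FALSE)
  tr$edge.length <- NULL
  m <- clean_matrix_from_tree(tr, copies = 2L)
  loci <- bp_loci(to_bipartitions(m, 2L))
  hc <- hillclimb_search(loci, restarts = 4L, seed = 5L,
                         candidate_pool = list(tr))
  sdp <- sdp_quartets(m, restarts = 4L, seed = 5L)
  expect_true(same_topology(hc$tree, tr))
  expect_true(same_topology(sdp$tree, hc$tree))
})

test_that("backbone constraints restrict the MRP search", {
  tr5 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  m5 <- clean_matrix_from_tree(tr5, copies = 2L)
  # force a backbone conflicting with the data: (A,C) together
  bb <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  rb <- sdp_quartets(m5, backbone = bb)
  expect_true(displays_clade(rb$tree, c("A", "C"), sort(tr5$tip.label)))
  # constrained search can only do worse (longer MRP length)
  r5 <- sdp_quartets(m5)
  expect_gte(rb$treelength, r5$treelength)
})
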