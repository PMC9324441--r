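test_that("PCS worked example: per-locus shares sum to the coalescence support", {
  taxa <- LETTERS[1:5]
  loci <- loci_from_splits(list(c("A", "B")), taxa)
  opt <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  tab <- pcs(loci, opt, clade = c("A", "B"), method = "exhaustive")
  expect_equal(tab$pcs, 2) # locus agrees 3 with the optimum, 1 with the anti tree
  expect_equal(attr(tab, "coalescence_support"), 2)
  expect_equal(sum(tab$pcs), attr(tab, "coalescence_support"))
  expect_error(pcs(loci, opt, clade = c("A", "C")), "not in the optimal")
})

test_that("PCS conservation holds exactly on random instances", {
  set.seed(55)
  for (rep in 1:10) {
    inst <- random_instance(6, 10)
    opt <- exhaustive_search(inst$loci)
    sp <- tree_splits(opt$tree, inst$taxa)
    clade <- inst$taxa[sp[[sample.int(length(sp), 1L)]]$side]
    tab <- pcs(inst$loci, opt, clade, method = "exhaustive")
    expect_equal(sum(tab$pcs), attr(tab, "coalescence_support"))
    expect_equal(attr(tab, "coalescence_support"),
                 opt$score - attr(tab, "anti")$score)
    expect_gte(attr(tab, "coalescence_support"), 0)
  }
})

# Fixture where exactly two loci prop up the {A,B} clade: removing both is
# needed before the optimum swings to the conflicting A+C attachment.
house_of_cards <- function() {
  taxa <- LETTERS[1:6]
  loci_from_splits(
    c(rep(list(c("A", "B")), 2L),             # the two key AB loci
      list(c("A", "C")),                      # conflicting, C,D-subset only
      rep(list(c("C", "D")), 3L),
      rep(list(c("E", "F")), 3L),
      rep(list(c("A", "B", "C", "D")), 2L)),
    taxa,
    excluded = c(list(NULL, NULL), list(c("E", "F")),
                 rep(list(NULL), 8L)))
}

test_that("removal index: two jointly supporting loci give index 2", {
  loci <- house_of_cards()
  ri <- removal_index(loci, clade = c("A", "B"), restarts = 6L, seed = 2L,
                      method = "exhaustive")
  expect_false(ri$unbounded)
  expect_equal(ri$index, 2L)
  expect_setequal(ri$removed, c("1", "2")) # the two AB loci
  # invariant: the collapse-witnessing tree lacks the clade
  expect_false(displays_clade(ri$final$tree, c("A", "B"), attr(loci, "taxa")))
})

test_that("removal index flags massive uniform support as unbounded at the cap", {
  taxa <- LETTERS[1:5]
  loci <- loci_from_splits(rep(list(c("A", "B")), 6L), taxa)
  ri <- removal_index(loci, clade = c("A", "B"), restarts = 4L, seed = 8L,
                      method = "exhaustive", max_steps = 3L)
  expect_true(is.na(ri$index))
  expect_true(ri$unbounded)
  expect_length(ri$removed, 3L)
})

test_that("removal index is at least 1 whenever coalescence support is positive", {
  set.seed(12)
  for (rep in 1:5) {
    inst <- random_instance(5, 8)
    opt <- exhaustive_search(inst$loci)
    sp <- tree_splits(opt$tree, inst$taxa)
    clade <- inst$taxa[sp[[1L]]$side]
    tab <- pcs(inst$loci, opt, clade, method = "exhaustive")
    if (attr(tab, "coalescence_support") <= 0) next
    ri <- removal_index(inst$loci, clade, restarts = 5L, seed = rep,
                        method = "exhaustive", max_steps = 6L)
    expect_true(ri$unbounded || ri$index >= 1L)
  }
})

test_that("bootstrap: perfect data gives 100% everywhere and seeds reproduce", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  loci <- bp_loci(to_bipartitions(clean_matrix_from_tree(tr, 4L), 2L))
  bs <- bootstrap_support(loci, tr, N = 15L, seed = 5L, restarts = 2L)
  expect_true(all(bs$table$percent == 100))

  b1 <- bootstrap_support(loci, tr, N = 3L, seed = 77L, restarts = 2L)
  b2 <- bootstrap_support(loci, tr, N = 3L, seed = 77L, restarts = 2L)
  expect_identical(b1$table, b2$table)
})

test_that("bootstrap support rises with the number of clean supporting loci", {
  taxa <- LETTERS[1:5]
  background <- c(rep(list(c("C", "D")), 4L),
                  list(c("A", "C"), c("A", "B")))
  few <- loci_from_splits(background, taxa)
  many <- loci_from_splits(c(background, rep(list(c("A", "B")), 4L)), taxa)
  b_few <- bootstrap_support(few, ape::read.tree(text = "(((A,B),E),(C,D));"),
                             N = 15L, seed = 31L, restarts = 3L)
  b_many <- bootstrap_support(many, ape::read.tree(text = "(((A,B),E),(C,D));"),
                              N = 15L, seed = 31L, restarts = 3L)
  ab_few <- b_few$table$percent[b_few$table$clade == "A,B"]
  ab_many <- b_many$table$percent[b_many$table$clade == "A,B"]
  expect_gte(ab_many, ab_few)
  expect_gt(ab_many, 50)
})

test_that("linked support: independent cherries lose only the target clade", {
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  loci <- bp_loci(to_bipartitions(clean_matrix_from_tree(tr, 2L), 2L))
  rep_ <- linked_support_report(loci, tr, clades = list(c("C", "D")),
                                method = "exhaustive")
  a <- rep_$anti_constraint[["C,D"]]
  expect_true("C,D" %in% a$lost)
  expect_length(a$linked, 0L)
  # empty clade list -> empty report
  rep0 <- linked_support_report(loci, tr, clades = list())
  expect_length(rep0$anti_constraint, 0L)
})

test_that("linked support: joint removal collapses interdependent clades together", {
  loci <- house_of_cards()
  taxa <- attr(loci, "taxa")
  opt <- exhaustive_search(loci)
  expect_true(displays_clade(opt$tree, c("A", "B"), taxa))
  rep_ <- linked_support_report(loci, opt, clades = list(c("A", "B")),
                                removal_sets = list(c("1", "2")),
                                method = "exhaustive",
                                seed = 4L, restarts = 6L)
  jr <- rep_$joint_removal[[1L]]
  expect_true("A,B" %in% jr$collapsed)
})
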