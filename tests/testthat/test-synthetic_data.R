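test_that("simulation is deterministic given the config seed", {
  tr <- six_taxon_tree(0.2)
  cfg <- sim_config(tr, n_characters = 40L, seed = 123L,
                    missing_probs = 0.2)
  s1 <- simulate_ri_matrix(cfg)
  s2 <- simulate_ri_matrix(cfg)
  expect_identical(s1$matrix$states, s2$matrix$states)
  expect_identical(s1$truth$insertion_clade, s2$truth$insertion_clade)
  g1 <- simulate_msc_gene_tree(cfg)
  g2 <- simulate_msc_gene_tree(cfg)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
})

test_that("config validation rejects bad trees and reticulations", {
  tr <- six_taxon_tree(0.2)
  bad <- tr
  bad$edge.length <- NULL
  expect_error(sim_config(bad), "branch lengths")
  nonult <- tr
  nonult$edge.length[1L] <- nonult$edge.length[1L] + 1
  expect_error(sim_config(nonult), "ultrametric")
  expect_error(sim_config(tr, reticulation = list(donor = "A", recipient = "B",
                                                  time = 0.5, gamma = 1.5)),
               "gamma")
  expect_error(sim_config(tr, reticulation = list(donor = "A", recipient = "B",
                                                  time = 50, gamma = 0.5)),
               "inside")
  expect_error(sim_config(tr, missing_probs = 1.2), "missing probabilities")
})

test_that("informative-only four-taxon characters are 2v2 splits", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.3,(C:1,D:1):0.3);")
  cfg <- sim_config(tr, n_characters = 120L, seed = 5L,
                    informative_only = TRUE)
  sim <- simulate_ri_matrix(cfg)
  cs <- colSums(sim$matrix$states)
  expect_true(all(cs == 2L))
  # truth clades match the coded presence sets
  for (j in seq_len(20L)) {
    expect_equal(sim$truth$insertion_clade[[j]],
                 sort(rownames(sim$matrix$states)[sim$matrix$states[, j] == 1L]))
  }
})

test_that("genealogies are valid coalescent trees on the species taxa", {
  tr <- six_taxon_tree(0.3)
  cfg <- sim_config(tr, seed = 9L)
  g <- simulate_msc_gene_tree(cfg)
  expect_s3_class(g, "phylo")
  expect_setequal(g$tip.label, tr$tip.label)
  expect_true(ape::is.binary(g))
  expect_true(ape::is.ultrametric(g, tol = 1e-6))
  # genealogy root is at least as old as the species root
  depth <- max(ape::node.depth.edgelength(g))
  sp_depth <- max(ape::node.depth.edgelength(tr))
  expect_gte(depth, sp_depth - 1e-9)
})

test_that("missing masking hits the configured per-taxon rates", {
  tr <- six_taxon_tree(0.5)
  rates <- c(0.28, 0.28, 0.05, 0.05, 0.5, 0)
  cfg <- sim_config(tr, n_characters = 2000L, seed = 77L,
                    missing_probs = rates)
  sim <- simulate_ri_matrix(cfg)
  frac <- rowMeans(is.na(sim$matrix$states))
  # per-taxon fractions within 3 binomial SEs of their targets
  se <- sqrt(rates * (1 - rates) / 2000)
  expect_true(all(abs(frac - rates) <= 3 * se + 1e-12))
  expect_equal(unname(frac[6L]), 0)
})

test_that("three-taxon pairing frequency matches the MSC closed form", {
  # quick single-t calibration; the full grid runs in the acceptance suite
  t <- 0.5
  tr <- ape::read.tree(text = sprintf("((A:1,B:1):%g,C:%g);", t, 1 + t))
  cfg <- sim_config(tr, seed = 2024L)
  n <- 4000L
  hits <- 0L
  set.seed(2024L)
  for (i in seq_len(n)) {
    g <- retroquartet:::sim_genealogy_compact(cfg)
    # the cherry of the 3-taxon genealogy: the first coalescence
    first <- which.min(g$age[4:5]) + 3L
    pair <- which(g$parent[1:3] == first)
    if (identical(sort(pair), c(1L, 2L))) hits <- hits + 1L
  }
  p <- 1 - (2 / 3) * exp(-t)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("gamma = 1 reroutes every recipient lineage through the donor", {
  # species tree ((A,B),(C,D)); recipient C jumps into the B branch, so
  # the unrooted genealogy quartet is almost always BC|AD
  tr <- ape::read.tree(text = "((A:1,B:1):0.4,(C:1,D:1):0.4);")
  cfg <- sim_config(tr, seed = 31L,
                    reticulation = list(donor = "B", recipient = "C",
                                        time = 0.5, gamma = 1))
  set.seed(31L)
  bc <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    g <- retroquartet:::sim_genealogy_compact(cfg)
    phy <- retroquartet:::compact_to_phylo(g, tr$tip.label)
    sp <- tree_splits(phy, sort(tr$tip.label))
    code <- retroquartet:::induced_quartet_code(
      lapply(sp, `[[`, "side"), 1:4)
    if (code == 3L) bc <- bc + 1L # {A,D} | {B,C}
  }
  # under gamma = 1, B and C share a branch from time 0.5 onward and BC|AD
  # becomes the clear majority; without the reticulation it would be a
  # minor topology at roughly (1/3)exp(-0.8) ~ 0.15
  expect_gt(bc / n, 0.45)
})

test_that("support-labeled gene trees mark perturbed edges with low labels", {
  tr <- six_taxon_tree(0.4)
  cfg <- sim_config(tr, seed = 88L)
  gts <- simulate_support_gene_trees(cfg, n_trees = 10L, error_rate = 0)
  expect_length(gts, 10L)
  labs <- suppressWarnings(as.numeric(unlist(lapply(gts, `[[`, "node.label"))))
  labs <- labs[!is.na(labs)]
  expect_true(all(labs >= 70))
  # error_rate 0: every gene tree is a plain MSC genealogy topology
  expect_setequal(gts[[1L]]$tip.label, tr$tip.label)

  gts2 <- simulate_support_gene_trees(cfg, n_trees = 30L, error_rate = 0.9)
  labs2 <- suppressWarnings(as.numeric(unlist(lapply(gts2, `[[`, "node.label"))))
  labs2 <- labs2[!is.na(labs2)]
  expect_true(any(labs2 <= 49))
  expect_length(simulate_support_gene_trees(cfg, 0L, 0.1), 0L)
})

test_that("collapse-at-50 weighting beats equal weighting under heavy gene-tree error", {
  # short internodes + high NNI error: weighting by support (collapsing
  # sub-50 labels) should recover the generating tree at least as often
  tr <- ape::read.tree(text = paste0(
    "(((A:1,B:1):0.15,(C:1.05,D:1.05):0.1):1,(E:1,F:1):1.15);"))
  taxa <- sort(tr$tip.label)
  wins_w <- 0L
  wins_e <- 0L
  for (rep in 1:8) {
    cfg <- sim_config(tr, seed = 500L + rep)
    gts <- simulate_support_gene_trees(cfg, n_trees = 60L, error_rate = 0.35)
    loci_eq <- gene_tree_loci(gts, taxa, weight_mode = "equal")
    loci_w <- gene_tree_loci(gts, taxa, weight_mode = "support",
                             collapse = 49)
    r_eq <- hillclimb_search(loci_eq, restarts = 3L, seed = rep)
    r_w <- hillclimb_search(loci_w, restarts = 3L, seed = rep,
                            weighted = TRUE)
    if (same_topology(r_eq$tree, tr))
      wins_e <- wins_e + 1L
    if (same_topology(r_w$tree, tr))
      wins_w <- wins_w + 1L
  }
  expect_gte(wins_w, wins_e)
  expect_gt(wins_w, 0L)
})
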