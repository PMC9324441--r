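test_that("complete-character filtering removes any missing entry in the subset", {
  taxa <- c("w", "x", "y", "z")
  states <- cbind(c(1L, 1L, NA, 0L), c(1L, 0L, 1L, 0L), c(0L, 0L, 1L, 1L))
  rownames(states) <- taxa
  m <- ri_matrix(states)
  f <- complete_character_filter(m, taxa)
  expect_equal(ncol(f$states), 2L)
  expect_equal(attr(f, "n_removed"), 1L)
  f3 <- complete_character_filter(m, c("w", "x", "z"))
  expect_equal(ncol(f3$states), 3L)
  expect_warning(
    complete_character_filter(
      ri_matrix(matrix(c(NA, 1L, 1L, 1L), 4, 1,
                       dimnames = list(taxa, NULL))), taxa),
    "complete")
  expect_error(complete_character_filter(m, c("w", "nope", "z")), "unknown")
})

test_that("two-tailed binomial p doubles the smaller exact tail and is exchangeable", {
  # perfect symmetry
  expect_equal(retroquartet:::binomial_two_tailed(10, 10), 1)
  # one-sided extreme: 2 * (1/2)^5
  expect_equal(retroquartet:::binomial_two_tailed(5, 0), 0.0625)
  expect_equal(retroquartet:::binomial_two_tailed(0, 5), 0.0625)
  set.seed(14)
  for (i in 1:25) {
    a <- sample(0:40, 1L)
    b <- sample(0:40, 1L)
    if (a + b == 0) next
    expect_equal(retroquartet:::binomial_two_tailed(a, b),
                 retroquartet:::binomial_two_tailed(b, a))
    expect_lte(retroquartet:::binomial_two_tailed(a, b), 1)
  }
})

test_that("quartet asymmetry classifies 2v2 patterns against the species tree", {
  taxa <- c("p", "q", "r", "s")
  # 6 characters for pq|rs, 3 for pr|qs, 1 for ps|qr, plus uninformative
  cols <- cbind(matrix(rep(c(1L, 1L, 0L, 0L), 6L), 4),
                matrix(rep(c(1L, 0L, 1L, 0L), 3L), 4),
                matrix(c(1L, 0L, 0L, 1L), 4),
                matrix(c(1L, 1L, 1L, 0L), 4),   # 3v1, ignored
                matrix(c(1L, NA, 0L, 0L), 4))   # incomplete, filtered
  rownames(cols) <- taxa
  m <- ri_matrix(cols)
  tr <- ape::read.tree(text = "((p,q),(r,s));")
  qa <- quartet_asymmetry(m, taxa, tr)
  expect_equal(qa$majority$count, 6L)
  expect_setequal(qa$majority$pairing, c("p", "q"))
  expect_equal(qa$minor[[1L]]$count, 3L)
  expect_equal(qa$minor[[2L]]$count, 1L)
  expect_equal(qa$n_complete, 11L)     # the ?-bearing character is dropped
  expect_equal(qa$n_informative, 10L)  # 6+3+1 characters split 2v2
  expect_equal(qa$p_value, retroquartet:::binomial_two_tailed(3, 1))

  # a species tree favoring pr|qs flips the majority
  qa2 <- quartet_asymmetry(m, taxa, ape::read.tree(text = "((p,r),(q,s));"))
  expect_equal(qa2$majority$count, 3L)
  expect_equal(qa2$minor[[1L]]$count, 6L)

  # no minority data: p undefined but flagged
  m0 <- ri_matrix(matrix(rep(c(1L, 1L, 0L, 0L), 2L), 4,
                         dimnames = list(taxa, NULL)))
  qa0 <- quartet_asymmetry(m0, taxa, tr)
  expect_true(is.na(qa0$p_value))
})

test_that("all 4-subsets are tested and adjusted p is no smaller than raw", {
  set.seed(21)
  taxa <- paste0("s", 1:5)
  states <- matrix(sample(c(0L, 1L), 5 * 60, replace = TRUE), 5, 60,
                   dimnames = list(taxa, NULL))
  m <- ri_matrix(states)
  tr <- ape::read.tree(text = "((s1,s2),(s3,(s4,s5)));")
  res <- all_quartet_asymmetry(m, taxa, tr, correction = "bonferroni")
  expect_equal(nrow(res), 5L) # C(5,4)
  ok <- !is.na(res$p)
  expect_true(all(res$p_adj[ok] >= res$p[ok]))
  res4 <- all_quartet_asymmetry(m, taxa[1:4], tr)
  expect_equal(nrow(res4), 1L)
})

test_that("triplet counts tabulate the three two-of-three presence patterns", {
  taxa <- c("a", "b", "c")
  cols <- cbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L),
                c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 0L, 0L), c(NA, 1L, 0L))
  rownames(cols) <- taxa
  tc <- triplet_counts(ri_matrix(cols), taxa)
  expect_equal(unname(tc$n), c(2L, 1L, 1L))
  expect_equal(tc$n_complete, 7L)
})

test_that("triplet LRT: uniform, tree-like, and skewed counts behave as nested models", {
  r0 <- triplet_lrt(c(10, 10, 10))
  expect_equal(r0$t_hat, 0)
  expect_equal(r0$gamma_hat, 0)
  expect_equal(r0$LR_tree_vs_polytomy, 0)
  expect_equal(r0$LR_hyb_vs_tree, 0)
  expect_equal(r0$p_tree_vs_polytomy, 1)

  r1 <- triplet_lrt(c(100, 10, 10))
  expect_lt(r1$gamma_hat, 0.02)
  expect_gt(r1$LR_tree_vs_polytomy, 50)
  expect_lt(r1$p_tree_vs_polytomy, 1e-10)

  r2 <- triplet_lrt(c(100, 50, 10))
  expect_gt(r2$gamma_hat, 0)
  expect_gt(r2$LR_hyb_vs_tree, 0)
  expect_lt(r2$p_hyb_vs_tree, 0.05)
})

test_that("triplet MLEs agree with a grid-search oracle and respect nesting", {
  cases <- list(c(100, 50, 10), c(80, 40, 30), c(60, 5, 3), c(7, 6, 2),
                c(200, 100, 100), c(30, 30, 5))
  for (n in cases) {
    r <- triplet_lrt(n)
    major <- which.max(n)
    minors <- setdiff(1:3, major)
    alt <- minors[which.max(n[minors])]
    oracle <- triplet_grid_loglik(n, major, alt)
    expect_gte(r$logL_hyb, oracle - 1e-3)
    expect_gte(r$logL_hyb, r$logL_tree - 1e-9)
    expect_gte(r$logL_tree, r$logL_poly - 1e-9)
  }
  set.seed(9)
  for (i in 1:20) {
    n <- as.numeric(sample(0:60, 3L, replace = TRUE))
    if (sum(n) == 0) n[1] <- 1
    r <- triplet_lrt(n)
    expect_gte(r$logL_hyb, r$logL_tree - 1e-9)
    expect_gte(r$logL_tree, r$logL_poly - 1e-9)
  }
})
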