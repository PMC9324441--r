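# Deviations from multispecies-coalescent symmetry in RI data.
#
# Under the MSC (no gene flow) the two minority resolutions of any species
# quartet are equally probable, and the three two-of-three presence
# patterns for a species triple follow multinomial frequencies
# (1 - (2/3) e^{-t}, (1/3) e^{-t}, (1/3) e^{-t}).  Skew beyond sampling
# error implies introgression (or another MSC violation).  Two tests are
# provided: an exact two-tailed binomial test on the minority counts of a
# quartet, and a triplet likelihood-ratio test comparing polytomy, tree
# and hybridization (mixture) models with an admixture estimate.

#' Restrict to characters complete for a taxon subset
#'
#' Characters with any missing entry among the given taxa are removed
#' (triplet and quartet pattern tests do not permit missing data).
#'
#' @param m an [ri_matrix()].
#' @param taxa_subset 3 or 4 taxon labels.
#' @return An [ri_matrix()] on the subset taxa; the number of characters
#'   removed is attached as attribute `n_removed`.
#' @export
complete_character_filter <- function(m, taxa_subset) {
  stopifnot(inherits(m, "ri_matrix"))
  idx <- taxon_ids(taxa_subset, m$taxa)
  sub <- m$states[idx, , drop = FALSE]
  ok <- colSums(is.na(sub)) == 0L
  if (!any(ok)) warning("no character is complete for the subset")
  out <- ri_matrix(sub[, ok, drop = FALSE], taxa = taxa_subset,
                   locus_ids = m$locus_ids[ok])
  attr(out, "n_removed") <- sum(!ok)
  out
}

#' Quartet asymmetry test
#'
#' Classifies the complete characters that split a species quartet 2-vs-2,
#' takes the resolution matching the species tree as the majority, and
#' tests the two minority counts for symmetry with an exact two-tailed
#' binomial test (expectation 0.5; p is the doubled smaller tail
#' probability, capped at 1).
#'
#' @param m an [ri_matrix()].
#' @param four_taxa four taxon labels.
#' @param species_tree `phylo` resolving the four taxa (defines the
#'   majority resolution).
#' @return A `quartet_asymmetry` object: the four taxa, `majority`
#'   (pairing and count), `minor` (two pairings with counts, larger
#'   first), `p_value`, `n_complete` (complete characters examined) and
#'   `n_informative` (2-vs-2 characters).
#' @export
quartet_asymmetry <- function(m, four_taxa, species_tree) {
  stopifnot(length(four_taxa) == 4L)
  sub <- complete_character_filter(m, four_taxa)
  st <- sub$states
  code <- 8L * st[1L, ] + 4L * st[2L, ] + 2L * st[3L, ] + st[4L, ]
  counts <- c(sum(code == 12L | code == 3L),   # t1t2|t3t4
              sum(code == 10L | code == 5L),   # t1t3|t2t4
              sum(code == 9L | code == 6L))    # t1t4|t2t3
  pairings <- list(four_taxa[c(1L, 2L)], four_taxa[c(1L, 3L)],
                   four_taxa[c(1L, 4L)])
  sp <- tree_splits(species_tree, sort(species_tree$tip.label))
  code_sp <- induced_quartet_code(
    split_sides(sp),
    taxon_ids(four_taxa, sort(species_tree$tip.label)))
  # induced_quartet_code works on the sorted 4-subset; translate back to
  # the caller's taxon order
  sorted <- sort(four_taxa)
  maj_pair <- switch(code_sp + 1L, NULL, sorted[c(1L, 2L)],
                     sorted[c(1L, 3L)], sorted[c(1L, 4L)])
  if (is.null(maj_pair)) {
    stop("species tree does not resolve the four taxa")
  }
  maj <- which(vapply(pairings, function(p)
    setequal(p, maj_pair) ||
      setequal(setdiff(four_taxa, p), maj_pair), logical(1)))
  minors <- setdiff(1:3, maj)
  o <- minors[order(-counts[minors])]
  c2 <- counts[o[1L]]
  c3 <- counts[o[2L]]
  p <- binomial_two_tailed(c2, c3)
  structure(list(taxa = four_taxa,
                 majority = list(pairing = pairings[[maj]],
                                 count = counts[maj]),
                 minor = list(
                   list(pairing = pairings[[o[1L]]], count = c2),
                   list(pairing = pairings[[o[2L]]], count = c3)),
                 p_value = p,
                 n_complete = ncol(st),
                 n_informative = sum(counts)),
            class = "quartet_asymmetry")
}

# exact two-tailed binomial p for (c2, c3): doubled smaller tail under
# Binomial(c2 + c3, 1/2), capped at 1; NA (flagged) when no minority data
binomial_two_tailed <- function(c2, c3) {
  n <- c2 + c3
  if (n == 0L) return(NA_real_)
  lo <- min(c2, c3)
  min(1, 2 * stats::pbinom(lo, n, 0.5))
}

#' @export
print.quartet_asymmetry <- function(x, ...) {
  cat("Quartet asymmetry:", paste(x$taxa, collapse = ", "), "\n")
  cat("  majority", paste(x$majority$pairing, collapse = "+"), "=",
      x$majority$count, "\n")
  cat("  minority", x$minor[[1L]]$count, "vs", x$minor[[2L]]$count,
      " two-tailed p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Quartet asymmetry over all 4-subsets
#'
#' @param m an [ri_matrix()].
#' @param taxa_list at least four taxon labels; every 4-subset is tested.
#' @param species_tree `phylo` defining majorities.
#' @param correction `"none"`, `"bonferroni"` or `"BH"`; the raw p is
#'   always reported, the adjusted p in an extra column.
#' @return Data frame with one row per 4-subset: taxa, the three counts,
#'   raw `p`, and `p_adj`.
#' @export
all_quartet_asymmetry <- function(m, taxa_list, species_tree,
                                  correction = c("none", "bonferroni", "BH")) {
  correction <- match.arg(correction)
  stopifnot(length(taxa_list) >= 4L)
  subs <- utils::combn(taxa_list, 4L, simplify = FALSE)
  rows <- lapply(subs, function(ft) {
    qa <- quartet_asymmetry(m, ft, species_tree)
    data.frame(taxa = paste(ft, collapse = ","),
               majority = qa$majority$count,
               minor1 = qa$minor[[1L]]$count,
               minor2 = qa$minor[[2L]]$count,
               n_informative = qa$n_informative,
               p = qa$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "none") out$p else
    stats::p.adjust(out$p, method = ifelse(correction == "BH", "BH",
                                           "bonferroni"))
  out
}

#' Triplet pattern counts
#'
#' Counts of the three informative presence patterns for an ordered
#' species triple: 110 (present in the first two, absent in the third),
#' 101 and 011, over characters with no missing entry among the three.
#'
#' @param m an [ri_matrix()].
#' @param triple three taxon labels.
#' @return A `triplet_counts` object: `taxa`, `n` (named 3-vector),
#'   `n_complete`.
#' @export
triplet_counts <- function(m, triple) {
  stopifnot(length(triple) == 3L)
  sub <- complete_character_filter(m, triple)
  st <- sub$states
  code <- 4L * st[1L, ] + 2L * st[2L, ] + st[3L, ]
  n <- c(`110` = sum(code == 6L), `101` = sum(code == 5L),
         `011` = sum(code == 3L))
  structure(list(taxa = triple, n = n, n_complete = ncol(st)),
            class = "triplet_counts")
}

# pattern probabilities for a triple under a resolved triplet tree with
# internal length t whose cherry is pattern `which` (1..3)
triplet_probs <- function(t, which) {
  p <- 1 - (2 / 3) * exp(-t)
  q <- (1 / 3) * exp(-t)
  out <- rep(q, 3L)
  out[which] <- p
  out
}

triplet_loglik <- function(n, probs) {
  ok <- n > 0
  sum(n[ok] * log(probs[ok]))
}

#' Triplet likelihood-ratio test for hybridization
#'
#' Fits three nested multinomial models to the triplet pattern counts:
#' a polytomy (uniform 1/3), a species tree (internal length `t >= 0`,
#' symmetric minor patterns), and a hybridization model mixing the tree
#' with the better-supported alternative pairing with weight
#' `gamma in [0, 1]`.  Likelihood-ratio statistics are assessed against
#' the boundary-corrected null `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' Because the direction of introgression is not identifiable from
#' unrooted triplet counts, `gamma_hat` is reported as the contribution of
#' the alternative pairing.
#'
#' @param counts a `triplet_counts` object or a named/unnamed 3-vector of
#'   pattern counts (110, 101, 011).
#' @return A `triplet_test` object: log-likelihoods (`logL_poly`,
#'   `logL_tree`, `logL_hyb`), `t_hat`, `gamma_hat`, the major and
#'   alternative pairings, LR statistics and p-values.
#' @export
triplet_lrt <- function(counts) {
  n <- if (inherits(counts, "triplet_counts")) counts$n else as.numeric(counts)
  stopifnot(length(n) == 3L, all(n >= 0), sum(n) >= 1)
  labs <- if (inherits(counts, "triplet_counts")) names(counts$n) else
    c("110", "101", "011")
  N <- sum(n)
  ll_poly <- triplet_loglik(n, rep(1 / 3, 3L))
  # tree model: major topology is the best-count pattern; closed-form MLE
  major <- which.max(n)
  p_hat <- n[major] / N
  t_hat <- max(0, -log(1.5 * (1 - p_hat)))
  ll_tree <- triplet_loglik(n, triplet_probs(t_hat, major))
  # hybridization: mixture toward the better-supported minor pattern
  minors <- setdiff(1:3, major)
  alt <- minors[which.max(n[minors])]
  hyb_probs <- function(t, g) {
    (1 - g) * triplet_probs(t, major) + g * triplet_probs(t, alt)
  }
  negll <- function(par) -triplet_loglik(n, hyb_probs(par[1L], par[2L]))
  starts <- list(c(t_hat, 0), c(t_hat, 0.25), c(max(t_hat, 0.1), 0.5),
                 c(0.05, 0.05))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(30, 1)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("hybridization model optimization failed for counts (",
         paste(n, collapse = ","), ")")
  }
  ll_hyb <- max(-best$value, ll_tree) # nesting: gamma = 0 is the tree model
  t_hyb <- best$par[1L]
  g_hat <- if (-best$value >= ll_tree) best$par[2L] else 0
  lr_tp <- max(0, 2 * (ll_tree - ll_poly))
  lr_ht <- max(0, 2 * (ll_hyb - ll_tree))
  boundary_p <- function(lr) {
    if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1L, lower.tail = FALSE)
  }
  structure(list(n = stats::setNames(n, labs),
                 logL_poly = ll_poly, logL_tree = ll_tree, logL_hyb = ll_hyb,
                 t_hat = t_hat, t_hyb = t_hyb, gamma_hat = g_hat,
                 major = labs[major], alternative = labs[alt],
                 LR_tree_vs_polytomy = lr_tp,
                 p_tree_vs_polytomy = boundary_p(lr_tp),
                 LR_hyb_vs_tree = lr_ht,
                 p_hyb_vs_tree = boundary_p(lr_ht)),
            class = "triplet_test")
}

#' @export
print.triplet_test <- function(x, ...) {
  cat("Triplet LRT: counts", paste(x$n, collapse = "/"),
      "(major", paste0(x$major, ")"), "\n")
  cat(sprintf("  tree vs polytomy: t_hat=%.4f LR=%.2f p=%.4g\n",
              x$t_hat, x$LR_tree_vs_polytomy, x$p_tree_vs_polytomy))
  cat(sprintf("  hybridization vs tree: gamma_hat=%.3f LR=%.2f p=%.4g\n",
              x$gamma_hat, x$LR_hyb_vs_tree, x$p_hyb_vs_tree))
  invisible(x)
}
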