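# Coalescent-unit branch lengths and Bayesian local posterior
# probabilities from per-branch quartet tallies, plus the anomaly-zone
# boundary diagnostics.
#
# Under the multispecies coalescent the species-tree resolution of a
# quartet around an internal branch of length t (coalescent units) occurs
# with probability p(t) = 1 - (2/3) exp(-t); each alternative has
# q(t) = (1/3) exp(-t).  Inverting the observed majority frequency gives
# the branch length estimate; integrating the multinomial likelihood of
# the three counts against an exponential prior on t gives the local
# posterior probability of each resolution.

#' Coalescent-unit branch length from a quartet tally
#'
#' Estimates the internal branch length as
#' `t = -log((3/2) (1 - p))` with `p = n1 / m`, the observed frequency of
#' the species-tree resolution.  Frequencies at or below 1/3 give length 0
#' (flag `"at-polytomy"`); frequencies within `eps` of 1 are capped (flag
#' `"saturated"`).
#'
#' @param tally a `branch_tally` (or a 3-vector of counts).
#' @param eps saturation guard (default 1e-6).
#' @return List with `length_cu`, `flag` (`"ok"`, `"at-polytomy"`,
#'   `"saturated"` or `"undefined"`), and `p_hat`.
#' @export
branch_length_cu <- function(tally, eps = 1e-6) {
  n <- if (inherits(tally, "branch_tally")) tally$n else as.numeric(tally)
  m <- sum(n)
  if (m == 0) {
    return(list(length_cu = NA_real_, flag = "undefined", p_hat = NA_real_))
  }
  p <- n[[1L]] / m
  if (p <= 1 / 3) {
    list(length_cu = 0, flag = "at-polytomy", p_hat = p)
  } else if (p >= 1 - eps) {
    list(length_cu = -log(1.5 * eps), flag = "saturated", p_hat = p)
  } else {
    list(length_cu = -log(1.5 * (1 - p)), flag = "ok", p_hat = p)
  }
}

# log integrand of the local-PP weight for counts (k of m) at branch
# length t, with exponential(rate) prior
local_pp_log_integrand <- function(t, k, m, rate) {
  k * log1p(-(2 / 3) * exp(-t)) + (m - k) * (log(1 / 3) - t) +
    log(rate) - rate * t
}

#' Bayesian local posterior probabilities
#'
#' Posterior probability of each of the three resolutions around a branch,
#' from the quartet counts `(n1, n2, n3)`: equal 1/3 prior over the three
#' topologies, exponential(`prior_rate`) prior on the internal branch
#' length, and the MSC quartet frequencies as likelihood.  The weight of
#' resolution i is the integral over t of
#' `p(t)^{n_i} q(t)^{m - n_i}` against the prior; the integrals are
#' evaluated by adaptive quadrature on the log scale.
#'
#' @param tally a `branch_tally` or 3-vector of counts.
#' @param prior_rate exponential prior rate on branch lengths (default
#'   0.5).
#' @param rel_tol quadrature tolerance (default 1e-8).
#' @return Numeric 3-vector of posteriors summing to 1, in tally order.
#' @export
local_pp <- function(tally, prior_rate = 0.5, rel_tol = 1e-8) {
  stopifnot(prior_rate > 0)
  n <- if (inherits(tally, "branch_tally")) tally$n else as.numeric(tally)
  stopifnot(length(n) == 3L, all(n >= 0))
  m <- sum(n)
  if (m == 0) return(rep(1 / 3, 3L))
  # common scale so exp() stays in range: peak of the largest-count integrand
  scale_ref <- max(vapply(n, function(k) {
    tt <- seq(0, 20, length.out = 200L)
    max(local_pp_log_integrand(tt, k, m, prior_rate))
  }, 0))
  w <- vapply(n, function(k) {
    f <- function(t) exp(local_pp_log_integrand(t, k, m, prior_rate) - scale_ref)
    out <- tryCatch(
      stats::integrate(f, 0, Inf, rel.tol = rel_tol, abs.tol = 0,
                       subdivisions = 500L),
      error = function(e) stop("local PP quadrature failed for counts (",
                               paste(n, collapse = ","), "): ",
                               conditionMessage(e)))
    out$value
  }, 0)
  w / sum(w)
}

#' Annotate a species tree with CU lengths and local PPs
#'
#' Computes per-branch quartet tallies for every internal branch and
#' attaches coalescent-unit branch lengths (internal edges; terminal edges
#' get `NA`) and the local posterior probability of the displayed
#' resolution (node labels).
#'
#' @param species_tree a binary `phylo`.
#' @param loci an `ri_loci` list.
#' @param prior_rate exponential prior rate for [local_pp()].
#' @param weighted logical, weighted tallies.
#' @return List with `tree` (annotated `phylo`), and `table` (one row per
#'   internal branch: clade, n1..n3, m, EN, length_cu, flag, pp1..pp3).
#' @export
annotate_tree <- function(species_tree, loci, prior_rate = 0.5,
                          weighted = FALSE) {
  tl <- branch_tallies(species_tree, loci, weighted)
  taxa <- attr(loci, "taxa")
  rows <- lapply(names(tl), function(lab) {
    t <- tl[[lab]]
    bl <- branch_length_cu(t)
    pp <- local_pp(t, prior_rate)
    data.frame(clade = lab, n1 = t$n[1L], n2 = t$n[2L], n3 = t$n[3L],
               m = t$m, EN = t$EN, length_cu = bl$length_cu, flag = bl$flag,
               pp1 = pp[1L], pp2 = pp[2L], pp3 = pp[3L])
  })
  tab <- do.call(rbind, rows)
  phy <- species_tree
  n <- length(phy$tip.label)
  below <- below_tips(phy)
  phy$edge.length <- rep(NA_real_, nrow(phy$edge))
  phy$node.label <- rep("", phy$Nnode)
  used <- character() # one rooted edge per unrooted split
  for (e in seq_len(nrow(phy$edge))) {
    v <- phy$edge[e, 2L]
    if (v <= n) next
    side <- phy$tip.label[below[[v]]]
    key <- split_label(side, phy$tip.label)
    i <- match(key, tab$clade)
    if (is.na(i) || key %in% used) next
    used <- c(used, key)
    phy$edge.length[e] <- tab$length_cu[i]
    phy$node.label[v - n] <- sprintf("%.4f", tab$pp1[i])
  }
  list(tree = phy, table = tab)
}

#' Anomaly-zone boundary function
#'
#' For two adjacent internal branches of lengths x and y (coalescent
#' units), anomalous gene trees exist iff `y < a(x)` with
#' `a(x) = log(2/3 + (3 e^{2x} - 2) / (18 (e^{3x} - e^{2x})))`.
#' `a` is strictly decreasing; its fixed point `x* = a(x*)` is the length
#' at which two equal adjacent branches sit exactly on the boundary.
#'
#' @param x branch length(s) in coalescent units, > 0.
#' @return `a(x)`.
#' @export
anomaly_boundary <- function(x) {
  stopifnot(all(x > 0))
  log(2 / 3 + (3 * exp(2 * x) - 2) / (18 * (exp(3 * x) - exp(2 * x))))
}

#' Fixed point of the anomaly-zone boundary
#'
#' Solves `x = a(x)` by bracketed root finding on (0.01, 1).
#'
#' @param tol root-finding tolerance (default 1e-6).
#' @return The fixed point (about 0.1569 coalescent units).
#' @export
anomaly_fixed_point <- function(tol = 1e-6) {
  stats::uniroot(function(x) anomaly_boundary(x) - x,
                 interval = c(0.01, 1), tol = tol)$root
}

#' Convert million-year branch lengths to coalescent units
#'
#' Scalar conversion `CU = MY / factor` with `factor` in MY per CU.  The
#' default treats one million years as one coalescent unit; a rougher
#' alternative for birds is 0.4 MY per CU.
#'
#' @param length_my branch length(s) in millions of years.
#' @param factor millions of years per coalescent unit (> 0), default 1.
#' @export
my_to_cu <- function(length_my, factor = 1) {
  stopifnot(factor > 0)
  length_my / factor
}
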