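# Quartet agreement between a species tree and a set of input loci.
#
# A locus is an unrooted leaf-labeled tree over a subset of the taxa; an RI
# bipartition is the special case with exactly one internal edge.  The
# quartet score of a species tree is the number (or total weight) of
# 4-leaf subsets on which a locus and the species tree induce the same
# resolved quartet, summed over loci.  The weight of an induced quartet in
# a multi-edge gene tree is the minimum edge support along the internal
# path connecting its two cherries, which reduces to the single edge's
# weight for bipartition loci.

new_locus <- function(locus_id, leaves, sides, weights) {
  list(locus_id = locus_id, leaves = as.integer(sort(leaves)),
       sides = lapply(sides, as.integer),
       weights = as.numeric(weights))
}

#' Build quartet-engine loci from RI bipartitions
#'
#' @param bps an `ri_bipartitions` object from [to_bipartitions()].
#' @param taxa taxon vector fixing the indexing (default: the matrix taxa
#'   stored on `bps`).
#' @param weight weight applied to each RI bipartition in weighted analyses
#'   (default 100, the maximum support weight).
#' @return An `ri_loci` list usable with [quartet_score()] and the search
#'   functions.
#' @export
bp_loci <- function(bps, taxa = attr(bps, "taxa"), weight = 100) {
  loci <- lapply(bps, function(bp) {
    pres <- taxon_ids(bp$present, taxa)
    abs_ <- taxon_ids(bp$absent, taxa)
    new_locus(bp$locus_id, c(pres, abs_), list(sort(pres)), weight)
  })
  structure(loci, taxa = taxa, class = "ri_loci")
}

#' Build quartet-engine loci from gene trees
#'
#' Internal node labels are read as edge supports (on the edge subtending
#' the node).  With `weight_mode = "support"` each split carries its
#' support as weight; with `"equal"` every split weighs
#' `default_support`.  Splits with support at or below `collapse` are
#' contracted first (see [collapse_low_support()]).
#'
#' @param trees a `multiPhylo`/list of `phylo`, or a newick file path.
#' @param taxa full taxon vector.
#' @param weight_mode `"support"` or `"equal"`.
#' @param collapse optional support threshold at or below which gene tree
#'   edges are collapsed before use.
#' @param default_support support assumed for unlabeled edges (and used in
#'   `"equal"` mode), default 100.
#' @return An `ri_loci` list.
#' @export
gene_tree_loci <- function(trees, taxa, weight_mode = c("support", "equal"),
                           collapse = NULL, default_support = 100) {
  weight_mode <- match.arg(weight_mode)
  if (is.character(trees) && length(trees) == 1L && file.exists(trees)) {
    trees <- ape::read.tree(trees)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  loci <- lapply(seq_along(trees), function(i) {
    sp <- tree_splits(trees[[i]], taxa)
    leaf_ids <- attr(sp, "leaf_ids")
    sup <- vapply(sp, `[[`, 0, "support")
    sup[is.na(sup)] <- default_support
    keep <- if (is.null(collapse)) rep(TRUE, length(sp)) else sup > collapse
    w <- if (weight_mode == "equal") rep(default_support, sum(keep)) else sup[keep]
    new_locus(i, leaf_ids, split_sides(sp)[keep], w)
  })
  structure(loci, taxa = taxa, class = "ri_loci")
}

#' @export
print.ri_loci <- function(x, ...) {
  nsp <- vapply(x, function(l) length(l$sides), 0L)
  cat("Quartet-engine loci:", length(x), "loci over",
      length(attr(x, "taxa")), "taxa;",
      sum(nsp == 1L), "single-bipartition\n")
  invisible(x)
}

#' @export
c.ri_loci <- function(...) {
  parts <- list(...)
  taxa <- attr(parts[[1L]], "taxa")
  for (p in parts) {
    if (!identical(attr(p, "taxa"), taxa)) stop("loci taxa indexing differs")
  }
  structure(NextMethod(), taxa = taxa, class = "ri_loci")
}

#' @export
`[.ri_loci` <- function(x, i) {
  structure(unclass(x)[i], taxa = attr(x, "taxa"), class = "ri_loci")
}

#' Collapse weakly supported gene-tree edges
#'
#' Contracts internal edges with support at or below `threshold`,
#' producing a (possibly multifurcating) tree over the same leaves.  For a
#' quartet-engine locus this simply removes the corresponding splits; a
#' `phylo` is rebuilt from the surviving splits.
#'
#' @param x a single `ri_loci` locus, an `ri_loci` list, or a `phylo` with
#'   numeric node labels.
#' @param threshold support threshold (edges with support `<= threshold`
#'   are contracted).
#' @export
collapse_low_support <- function(x, threshold) UseMethod("collapse_low_support")

#' @export
collapse_low_support.ri_loci <- function(x, threshold) {
  out <- lapply(x, function(l) {
    keep <- l$weights > threshold
    new_locus(l$locus_id, l$leaves, l$sides[keep], l$weights[keep])
  })
  structure(out, taxa = attr(x, "taxa"), class = "ri_loci")
}

#' @export
collapse_low_support.phylo <- function(x, threshold) {
  taxa <- sort(x$tip.label)
  sp <- tree_splits(x, taxa)
  sup <- vapply(sp, `[[`, 0, "support")
  sup[is.na(sup)] <- Inf
  keep <- sup > threshold
  phy <- sides_to_phylo(split_sides(sp)[keep], attr(sp, "leaf_ids"), taxa)
  phy$node.label <- NULL
  phy
}

#' @export
collapse_low_support.default <- function(x, threshold) {
  keep <- x$weights > threshold
  new_locus(x$locus_id, x$leaves, x$sides[keep], x$weights[keep])
}

# resolve a species-tree argument (phylo or split set) to sides over `taxa`,
# checking that every locus leaf occurs in the tree
species_sides <- function(species_tree, loci) {
  taxa <- attr(loci, "taxa")
  if (inherits(species_tree, "phylo")) {
    used <- taxa[sort(unique(unlist(lapply(loci, `[[`, "leaves"))))]
    missing <- setdiff(used, species_tree$tip.label)
    if (length(missing)) {
      stop("locus taxa absent from species tree: ",
           paste(missing, collapse = ", "))
    }
    keep <- species_tree$tip.label %in% taxa
    sides <- lapply(tree_splits(species_tree, c(taxa, setdiff(species_tree$tip.label, taxa))),
                    function(s) s$side[s$side <= length(taxa)])
    sides
  } else {
    lapply(species_tree, as.integer)
  }
}

#' Quartet agreement score
#'
#' Sums, over loci and over the 4-leaf subsets each locus resolves, the
#' weight of agreements between the locus-induced quartet and the
#' species-tree-induced quartet.  Unweighted scoring uses weight 1 per
#' quartet and returns an integer-valued count.
#'
#' @param species_tree a `phylo`, or a list of split sides (integer ids).
#' @param loci an `ri_loci` list.
#' @param weighted logical; use per-quartet minimum edge support weights.
#' @return Total score (numeric).
#' @export
quartet_score <- function(species_tree, loci, weighted = FALSE) {
  sum(per_locus_scores(species_tree, loci, weighted))
}

#' Per-locus quartet agreement
#'
#' @inheritParams quartet_score
#' @return Numeric vector, one agreement score per locus.
#' @export
per_locus_scores <- function(species_tree, loci, weighted = FALSE) {
  if (!length(loci)) return(numeric())
  taxa <- attr(loci, "taxa")
  sides <- species_sides(species_tree, loci)
  cpp_locus_scores(sides, unclass(loci), length(taxa), weighted)
}

#' Brute-force quartet score (oracle)
#'
#' Independent reference implementation of [quartet_score()] by explicit
#' enumeration of all 4-leaf subsets of every locus; guarded to small
#' trees.
#'
#' @inheritParams quartet_score
#' @param max_taxa enumeration size guard (default 12).
#' @export
brute_force_score <- function(species_tree, loci, weighted = FALSE,
                              max_taxa = 12L) {
  taxa <- attr(loci, "taxa")
  st_sides <- species_sides(species_tree, loci)
  total <- 0
  for (l in loci) {
    if (length(l$leaves) > max_taxa) {
      stop("brute_force_score capped at ", max_taxa, " leaves per locus")
    }
    if (length(l$leaves) < 4L) next
    for (four in utils::combn(l$leaves, 4L, simplify = FALSE)) {
      code_l <- induced_quartet_code(l$sides, four)
      if (code_l == 0L) next
      if (code_l == induced_quartet_code(st_sides, four)) {
        w <- 1
        if (weighted) {
          # min weight over locus splits on the central path
          w <- min(vapply(seq_along(l$sides), function(si) {
            if (sum(four %in% l$sides[[si]]) == 2L) l$weights[si] else Inf
          }, 0))
        }
        total <- total + w
      }
    }
  }
  total
}

#' Per-branch quartet tallies
#'
#' For an internal branch of a binary species tree, the four leaf clusters
#' adjacent to its two ends define the quartets "around" the branch.  Each
#' locus contributes, for every 4-subset with one leaf per cluster that it
#' resolves, a count to the species-tree resolution (`n1`) or one of the
#' two alternatives (`n2`, `n3`).  `EN` is the effective number of loci:
#' those contributing at least one such quartet.
#'
#' @param species_tree a binary `phylo`.
#' @param loci an `ri_loci` list.
#' @param branch internal branch, as the taxon labels of one side of its
#'   split (a vector), or an edge index of `species_tree`.
#' @param weighted logical; weight quartets by minimum edge support.
#' @return A `branch_tally`: list with `clusters` (taxon labels), `n`
#'   (3-vector), `m`, `EN`, `freq`, and `per_locus` (loci x 3 matrix).
#' @export
branch_tally <- function(species_tree, loci, branch, weighted = FALSE) {
  taxa <- attr(loci, "taxa")
  cl <- branch_clusters(species_tree, branch, taxa)
  tally_from_clusters(cl, loci, weighted)
}

tally_from_clusters <- function(clusters, loci, weighted = FALSE) {
  taxa <- attr(loci, "taxa")
  per <- cpp_branch_tally(lapply(clusters, as.integer), unclass(loci),
                          length(taxa), weighted)
  rownames(per) <- vapply(loci, function(l) as.character(l$locus_id), "")
  colnames(per) <- c("n1", "n2", "n3")
  n <- colSums(per)
  structure(list(
    clusters = lapply(clusters, function(ids) taxa[ids]),
    n = n, m = sum(n), EN = sum(rowSums(per) > 0),
    freq = if (sum(n) > 0) n / sum(n) else rep(NA_real_, 3L),
    per_locus = per), class = "branch_tally")
}

#' @export
print.branch_tally <- function(x, ...) {
  cat(sprintf("Branch tally: n1=%g n2=%g n3=%g (m=%g, EN=%d)\n",
              x$n[1L], x$n[2L], x$n[3L], x$m, x$EN))
  invisible(x)
}

# the four clusters around an internal branch of a binary tree; branch
# given as an edge index or as the taxon labels of one side
branch_clusters <- function(phy, branch, taxa) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  ids <- taxon_ids(phy$tip.label, taxa)
  below <- below_tips(phy)
  internal <- which(phy$edge[, 2L] > n)
  if (length(branch) == 1L && is.numeric(branch)) {
    e <- as.integer(branch)
    if (!(e %in% seq_len(nrow(phy$edge)))) stop("no such edge: ", branch)
    if (phy$edge[e, 2L] <= n) stop("terminal branch has no quartet tally")
  } else {
    want <- sort(taxon_ids(branch, taxa))
    e <- NULL
    for (ei in internal) {
      side <- sort(ids[below[[phy$edge[ei, 2L]]]])
      if (identical(side, want) ||
          identical(side, sort(setdiff(ids, want)))) {
        e <- ei
        break
      }
    }
    if (is.null(e)) stop("branch not found in species tree")
  }
  u <- phy$edge[e, 1L]
  v <- phy$edge[e, 2L]
  kids_v <- phy$edge[phy$edge[, 1L] == v, 2L]
  if (length(kids_v) != 2L) stop("species tree must be binary at the branch")
  C <- ids[below[[kids_v[1L]]]]
  D <- ids[below[[kids_v[2L]]]]
  sibs <- setdiff(phy$edge[phy$edge[, 1L] == u, 2L], v)
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  if (u == root && length(sibs) == 2L) {
    A <- ids[below[[sibs[1L]]]]
    B <- ids[below[[sibs[2L]]]]
  } else if (u == root && length(sibs) == 1L) {
    # degree-2 root: the other end of this edge, unrooted, is the sibling
    w <- sibs[1L]
    kids_w <- phy$edge[phy$edge[, 1L] == w, 2L]
    if (length(kids_w) != 2L) stop("branch is not internal")
    A <- ids[below[[kids_w[1L]]]]
    B <- ids[below[[kids_w[2L]]]]
  } else if (length(sibs) == 1L) {
    A <- ids[below[[sibs[1L]]]]
    B <- setdiff(ids, c(A, C, D))
  } else {
    stop("species tree must be binary at the branch")
  }
  if (!length(A) || !length(B)) stop("branch is not internal")
  list(A = A, B = B, C = C, D = D)
}

#' Tallies for every internal branch
#'
#' @inheritParams branch_tally
#' @return Named list of `branch_tally` objects, one per internal branch;
#'   names are the smaller-side taxon sets (comma-separated).
#' @export
branch_tallies <- function(species_tree, loci, weighted = FALSE) {
  taxa <- attr(loci, "taxa")
  n <- length(species_tree$tip.label)
  below <- below_tips(species_tree)
  ids <- taxon_ids(species_tree$tip.label, taxa)
  out <- list()
  for (e in seq_len(nrow(species_tree$edge))) {
    v <- species_tree$edge[e, 2L]
    if (v <= n) next
    side <- ids[below[[v]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    # one entry per split (a rooted binary representation shows the root
    # split on two edges); labeled by the smaller side
    lab <- split_label(taxa[side], taxa[ids])
    if (!is.null(out[[lab]])) next
    out[[lab]] <- branch_tally(species_tree, loci, e, weighted)
  }
  out
}
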