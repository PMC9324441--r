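# Species-tree search over the quartet-agreement objective: exact
# enumeration for small taxon sets, seeded random-restart NNI hill
# climbing (with SPR kicks at plateaus) otherwise, anti-constraint
# searches that exclude a focal clade, and the quartet-parsimony + MRP
# supertree pathway.

search_result <- function(phy, sides, score, mode, restarts = NA_integer_,
                          seed = NA_integer_, tie = FALSE, ties = NULL,
                          extra = list()) {
  structure(c(list(tree = phy, sides = sides, score = score, mode = mode,
                   restarts = restarts, seed = seed, tie = tie, ties = ties),
              extra),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Species-tree search (", x$mode, "): score ", format(x$score),
      if (isTRUE(x$tie)) " [tied optimum]" else "", "\n", sep = "")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Exhaustive species-tree search
#'
#' Scores every unrooted binary topology on the given taxa and returns a
#' maximum-score tree.  Co-optimal trees are reported: ties are broken by
#' the canonical (lexicographically least) newick representative and
#' flagged.
#'
#' @param loci an `ri_loci` list.
#' @param taxa taxa to place (default: all loci taxa).
#' @param weighted logical, weighted quartet score.
#' @param accept optional predicate `function(sides)` restricting the
#'   search space (used by anti-constraint searches).
#' @param objective optional alternative objective `function(sides)` to
#'   maximize instead of the quartet score.
#' @param max_taxa enumeration cap (default 9; 135,135 topologies).
#' @return A `search_result`.
#' @export
exhaustive_search <- function(loci, taxa = attr(loci, "taxa"),
                              weighted = FALSE, accept = NULL,
                              objective = NULL, max_taxa = 9L) {
  ids <- taxon_ids(taxa, attr(loci, "taxa"))
  if (is.null(objective)) {
    objective <- function(sides) quartet_score(sides, loci, weighted)
  }
  best <- -Inf
  ties <- character()
  enumerate_topologies(ids, function(sides) {
    if (!is.null(accept) && !accept(sides)) return(invisible(NULL))
    sc <- objective(sides)
    if (sc > best + 1e-9) {
      best <<- sc
      ties <<- canonical_newick(sides, sort(ids), attr(loci, "taxa"))
    } else if (sc > best - 1e-9) {
      ties <<- c(ties, canonical_newick(sides, sort(ids), attr(loci, "taxa")))
    }
    invisible(NULL)
  }, max_taxa = max_taxa)
  if (!length(ties)) stop("no admissible topology found")
  ties <- sort(unique(ties))
  phy <- ape::read.tree(text = ties[1L])
  search_result(phy, tree_splits(phy, attr(loci, "taxa")) |> split_sides(),
                best, "exhaustive", tie = length(ties) > 1L, ties = ties)
}

# one greedy NNI climb (with optional SPR kicks) from a starting tree;
# objective(sides) is maximized, accept(sides) constrains the space
climb <- function(phy, objective, accept, taxa, use_spr = TRUE,
                  spr_kicks = 5L) {
  get_sides <- function(tr) split_sides(tree_splits(tr, taxa))
  cur_sides <- get_sides(phy)
  cur <- objective(cur_sides)
  kicks_left <- if (use_spr) spr_kicks else 0L
  repeat {
    nbs <- phangorn::nni(phy)
    improved <- FALSE
    best_nb <- NULL
    best_sc <- cur
    best_sides <- NULL
    for (j in seq_along(nbs)) {
      nb <- nbs[[j]] # [[ re-attaches tip labels of a compressed multiPhylo
      s <- get_sides(nb)
      if (!is.null(accept) && !accept(s)) next
      sc <- objective(s)
      if (sc > best_sc + 1e-9) {
        best_sc <- sc
        best_nb <- nb
        best_sides <- s
        improved <- TRUE
      }
    }
    if (improved) {
      phy <- best_nb
      cur <- best_sc
      cur_sides <- best_sides
      next
    }
    if (kicks_left > 0L) {
      kicks_left <- kicks_left - 1L
      kick <- phangorn::rSPR(phy, moves = 1L)
      s <- get_sides(kick)
      if ((is.null(accept) || accept(s)) && objective(s) > cur + 1e-9) {
        phy <- kick
        cur_sides <- s
        cur <- objective(s)
      }
      next
    }
    break
  }
  list(tree = phy, sides = cur_sides, score = cur)
}

# draw an admissible starting topology, repairing by NNI if needed
admissible_start <- function(phy, accept, taxa, labels, tries = 50L) {
  for (i in seq_len(tries)) {
    s <- split_sides(tree_splits(phy, taxa))
    if (is.null(accept) || accept(s)) return(phy)
    nbs <- phangorn::nni(phy)
    for (j in seq_along(nbs)) {
      nb <- nbs[[j]]
      if (accept(split_sides(tree_splits(nb, taxa)))) return(nb)
    }
    phy <- random_topology(labels)
  }
  stop("could not find an admissible starting tree")
}

#' Heuristic species-tree search
#'
#' Seeded random-restart greedy NNI hill climbing on the quartet score,
#' with random SPR kicks at plateaus.  Optional `candidate_pool` trees are
#' used as additional starting points, broadening the search space the way
#' extra input gene trees broaden a quartet-based search.  Deterministic
#' given `seed`.
#'
#' @inheritParams exhaustive_search
#' @param restarts number of independent climbs (>= 1).
#' @param seed RNG seed.
#' @param candidate_pool optional list of `phylo` starting trees.
#' @param start optional explicit starting tree used for the first climb.
#' @param use_spr logical, allow SPR kicks at plateaus.
#' @return A `search_result`.
#' @export
hillclimb_search <- function(loci, taxa = attr(loci, "taxa"), restarts = 20L,
                             seed = 1L, candidate_pool = NULL, start = NULL,
                             weighted = FALSE, accept = NULL,
                             objective = NULL, use_spr = TRUE) {
  stopifnot(restarts >= 1L)
  all_taxa <- attr(loci, "taxa")
  taxon_ids(taxa, all_taxa) # validate
  if (is.null(objective)) {
    objective <- function(sides) quartet_score(sides, loci, weighted)
  }
  set.seed(seed)
  starts <- list()
  if (!is.null(start)) starts <- c(starts, list(start))
  if (!is.null(candidate_pool)) starts <- c(starts, as.list(candidate_pool))
  best <- NULL
  for (r in seq_len(restarts)) {
    phy0 <- if (r <= length(starts)) starts[[r]] else random_topology(taxa)
    phy0 <- admissible_start(phy0, accept, all_taxa, taxa)
    res <- climb(phy0, objective, accept, all_taxa, use_spr = use_spr)
    if (is.null(best) || res$score > best$score + 1e-9) best <- res
  }
  search_result(best$tree, best$sides, best$score, "hillclimb",
                restarts = restarts, seed = seed)
}

#' Best species tree lacking a clade (anti-constraint search)
#'
#' Finds the best-scoring topology whose splits do not include the
#' forbidden clade; every candidate displaying `forbidden_clade` vs. the
#' rest is rejected during the search.  Used for coalescence support and
#' locus-removal analyses.
#'
#' @inheritParams hillclimb_search
#' @param forbidden_clade character vector of taxon labels (2 <= size <=
#'   n-2).
#' @param method `"auto"` (exhaustive up to `max_exhaustive` taxa, else
#'   hill climbing), `"exhaustive"` or `"hillclimb"`.
#' @param max_exhaustive taxon count up to which `"auto"` enumerates.
#' @return A `search_result`.
#' @export
anticonstraint_search <- function(loci, taxa = attr(loci, "taxa"),
                                  forbidden_clade, restarts = 20L, seed = 1L,
                                  candidate_pool = NULL, weighted = FALSE,
                                  method = c("auto", "exhaustive", "hillclimb"),
                                  max_exhaustive = 7L, use_spr = TRUE) {
  method <- match.arg(method)
  all_taxa <- attr(loci, "taxa")
  fids <- sort(taxon_ids(forbidden_clade, all_taxa))
  ids <- sort(taxon_ids(taxa, all_taxa))
  if (length(fids) < 2L || length(fids) > length(ids) - 2L) {
    stop("forbidden clade must have between 2 and n-2 taxa")
  }
  accept <- function(sides) !has_split(sides, fids, ids)
  if (method == "exhaustive" ||
      (method == "auto" && length(ids) <= max_exhaustive)) {
    exhaustive_search(loci, taxa, weighted, accept = accept)
  } else {
    hillclimb_search(loci, taxa, restarts = restarts, seed = seed,
                     candidate_pool = candidate_pool, weighted = weighted,
                     accept = accept, use_spr = use_spr)
  }
}

#' Quartet parsimony + MRP supertree (SDP-style)
#'
#' For every 4-taxon subset, unordered parsimony lengths of the three
#' quartet topologies are computed over the characters complete for the
#' subset (a character with a 2-vs-2 informative pattern fits its matching
#' topology in one step and the others in two; other characters are
#' equally parsimonious everywhere and are skipped).  All minimum-length
#' topologies are encoded as binary matrix-representation-with-parsimony
#' (MRP) rows, and a parsimony search over the MRP matrix (Fitch length,
#' minimized) returns the supertree.
#'
#' @param m an [ri_matrix()].
#' @param taxa taxa to place (default all).
#' @param backbone optional `phylo` backbone constraint; the search is
#'   restricted to trees displaying all its splits.
#' @param restarts,seed,use_spr heuristic search controls.
#' @param max_exhaustive taxon count up to which the MRP search enumerates
#'   exhaustively.
#' @return A `search_result` with extra elements `mrp` (the MRP matrix,
#'   taxa x rows), `treelength` (Fitch length of the MRP matrix on the
#'   returned tree) and `quartet_counts` (per-subset pattern counts).
#' @export
sdp_quartets <- function(m, taxa = m$taxa, backbone = NULL, restarts = 10L,
                         seed = 1L, max_exhaustive = 7L, use_spr = TRUE) {
  stopifnot(inherits(m, "ri_matrix"))
  ids <- taxon_ids(taxa, m$taxa)
  if (length(ids) < 4L) stop("need at least 4 taxa")
  subsets <- utils::combn(ids, 4L, simplify = FALSE)
  rows <- list()
  counts <- list()
  for (sub in subsets) {
    st <- m$states[sub, , drop = FALSE]
    ok <- colSums(is.na(st)) == 0L
    if (!any(ok)) {
      counts[[length(counts) + 1L]] <-
        c(sub, n1 = 0L, n2 = 0L, n3 = 0L)
      next
    }
    stc <- st[, ok, drop = FALSE]
    code <- 8L * stc[1L, ] + 4L * stc[2L, ] + 2L * stc[3L, ] + stc[4L, ]
    n1 <- sum(code == 12L | code == 3L)  # 1100/0011: t1t2|t3t4
    n2 <- sum(code == 10L | code == 5L)  # 1010/0101: t1t3|t2t4
    n3 <- sum(code == 9L | code == 6L)   # 1001/0110: t1t4|t2t3
    counts[[length(counts) + 1L]] <- c(sub, n1 = n1, n2 = n2, n3 = n3)
    nn <- c(n1, n2, n3)
    if (max(nn) == 0L) next
    for (topo in which(nn == max(nn))) {
      row <- rep(NA_integer_, length(m$taxa))
      pair <- switch(topo, sub[c(1L, 2L)], sub[c(1L, 3L)], sub[c(1L, 4L)])
      row[pair] <- 1L
      row[setdiff(sub, pair)] <- 0L
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no informative quartet in the matrix")
  mrp <- do.call(cbind, rows)
  rownames(mrp) <- m$taxa
  objective <- function(sides) {
    phy <- sides_to_phylo(sides, ids, m$taxa)
    -sum(fitch_lengths(mrp[phy$tip.label, , drop = FALSE], phy))
  }
  accept <- NULL
  if (!is.null(backbone)) {
    bb <- tree_splits(backbone, m$taxa)
    bb_ids <- attr(bb, "leaf_ids")
    bb_sides <- split_sides(bb)
    accept <- function(sides) displays_backbone(sides, bb_sides, bb_ids)
  }
  res <- if (length(ids) <= max_exhaustive) {
    # dummy loci carrier for taxa indexing
    exhaustive_search(structure(list(), taxa = m$taxa, class = "ri_loci"),
                      taxa, accept = accept, objective = objective)
  } else {
    hillclimb_search(structure(list(), taxa = m$taxa, class = "ri_loci"),
                     taxa, restarts = restarts, seed = seed, accept = accept,
                     objective = objective, use_spr = use_spr)
  }
  cnt <- do.call(rbind, counts)
  search_result(res$tree, res$sides, res$score, "sdp_quartets",
                restarts = res$restarts, seed = res$seed, tie = res$tie,
                ties = res$ties,
                extra = list(mrp = mrp, treelength = -res$score,
                             quartet_counts = cnt))
}
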