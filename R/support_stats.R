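# Clade support and stability for quartet-based species trees: character
# bootstrap, partitioned coalescence support (PCS), the greedy
# locus-removal index, and linked-support reports that expose
# interdependence of support across nodes.

as_phylo_tree <- function(x) {
  if (inherits(x, "search_result")) x$tree else x
}

tree_has_clade <- function(tree, clade, taxa) {
  sp <- tree_splits(as_phylo_tree(tree), taxa)
  has_split(split_sides(sp), taxon_ids(clade, taxa), attr(sp, "leaf_ids"))
}

#' Partitioned coalescence support (PCS)
#'
#' The coalescence support of a clade is the quartet-score difference
#' between the optimal tree and the best tree lacking the clade (the
#' anti-constraint tree).  PCS partitions that difference among the loci:
#' each locus's PCS is its quartet agreement with the optimal tree minus
#' its agreement with the anti-constraint tree, so the per-locus values
#' sum exactly to the coalescence support.
#'
#' @param loci an `ri_loci` list.
#' @param optimal the optimal tree (`search_result` or `phylo`).
#' @param clade character vector of taxon labels defining the focal clade.
#' @param anti optional precomputed anti-constraint tree; computed by
#'   [anticonstraint_search()] otherwise.
#' @param weighted logical, weighted scores.
#' @param ... passed to [anticonstraint_search()] (`seed`, `restarts`,
#'   `method`, ...).
#' @return A `pcs_table`: data frame (`locus_id`, `pcs`) sorted
#'   descending, with attributes `coalescence_support`, `clade` and
#'   `anti` (the anti-constraint `search_result`).
#' @export
pcs <- function(loci, optimal, clade, anti = NULL, weighted = FALSE, ...) {
  taxa <- attr(loci, "taxa")
  opt_tree <- as_phylo_tree(optimal)
  if (!tree_has_clade(opt_tree, clade, taxa)) {
    stop("clade {", paste(clade, collapse = ","),
         "} is not in the optimal tree")
  }
  if (is.null(anti)) {
    anti <- anticonstraint_search(loci, taxa = opt_tree$tip.label,
                                  forbidden_clade = clade,
                                  weighted = weighted, ...)
  }
  s_opt <- per_locus_scores(opt_tree, loci, weighted)
  s_anti <- per_locus_scores(as_phylo_tree(anti), loci, weighted)
  tab <- data.frame(
    locus_id = vapply(loci, function(l) as.character(l$locus_id), ""),
    pcs = s_opt - s_anti)
  tab <- tab[order(-tab$pcs), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "coalescence_support") <- sum(s_opt) - sum(s_anti)
  attr(tab, "clade") <- clade
  attr(tab, "anti") <- anti
  class(tab) <- c("pcs_table", "data.frame")
  tab
}

#' @export
print.pcs_table <- function(x, ...) {
  cat("PCS for clade {", paste(attr(x, "clade"), collapse = ","),
      "}: coalescence support ", format(attr(x, "coalescence_support")),
      "\n", sep = "")
  print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Locus-removal index of a clade
#'
#' Greedy estimate of the minimum number of locus removals required to
#' collapse a clade: at each step the loci are re-ranked by PCS against a
#' freshly computed anti-constraint tree, the top-ranked locus is removed,
#' and both the optimum and the anti-constraint tree are re-estimated.
#' The clade counts as collapsed as soon as it is no longer strictly
#' supported: either the new optimum lacks it, or its coalescence support
#' has dropped to zero (an equally good tree without the clade exists, so
#' the node would not survive a strict consensus of optima).  The
#' reported index is an upper bound on the true minimum.
#'
#' @param loci an `ri_loci` list.
#' @param clade focal clade (taxon labels); must be in the current
#'   optimum.
#' @param restarts,seed search controls for the per-step re-searches.
#' @param weighted logical.
#' @param max_steps stop after this many removals (default: the number of
#'   loci); reaching the cap reports the index as unbounded.
#' @param method passed to [anticonstraint_search()].
#' @return A `removal_index` object: `index` (integer, or `NA` with
#'   `unbounded = TRUE` when the clade never collapsed within the cap),
#'   `removed` (locus ids in removal order), `steps` (per-step search
#'   results), `final` (the collapse-witnessing tree).
#' @export
removal_index <- function(loci, clade, restarts = 10L, seed = 1L,
                          weighted = FALSE, max_steps = NULL,
                          method = c("auto", "exhaustive", "hillclimb")) {
  method <- match.arg(method)
  taxa <- attr(loci, "taxa")
  if (is.null(max_steps)) max_steps <- length(loci)
  cur <- loci
  opt <- hillclimb_search(cur, restarts = restarts, seed = seed,
                          weighted = weighted)
  if (!tree_has_clade(opt, clade, taxa)) {
    stop("clade is not in the optimal tree for the full locus set")
  }
  removed <- character()
  steps <- list()
  k <- 0L
  done <- function(index, unbounded, final) {
    structure(list(index = index, unbounded = unbounded, removed = removed,
                   steps = steps, clade = clade, final = final),
              class = "removal_index")
  }
  repeat {
    if (!tree_has_clade(opt, clade, taxa)) {
      return(done(k, FALSE, opt))
    }
    tab <- pcs(cur, opt, clade, weighted = weighted, seed = seed + k,
               restarts = restarts, method = method)
    anti <- attr(tab, "anti")
    if (attr(tab, "coalescence_support") <= 1e-9) {
      return(done(k, FALSE, anti))
    }
    if (k >= max_steps) {
      return(done(NA_integer_, TRUE, opt))
    }
    k <- k + 1L
    drop_id <- tab$locus_id[which.max(tab$pcs)]
    keep <- vapply(cur, function(l) as.character(l$locus_id) != drop_id,
                   logical(1))
    cur <- cur[keep]
    removed <- c(removed, drop_id)
    opt <- hillclimb_search(cur, restarts = restarts, seed = seed + k,
                            weighted = weighted,
                            candidate_pool = list(as_phylo_tree(opt),
                                                  as_phylo_tree(anti)))
    steps[[k]] <- opt
  }
}

#' @export
print.removal_index <- function(x, ...) {
  if (isTRUE(x$unbounded)) {
    cat("Locus-removal index: clade did not collapse (",
        length(x$removed), " removals tried)\n", sep = "")
  } else {
    cat("Locus-removal index:", x$index, "(upper bound); removed:",
        paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Character bootstrap support
#'
#' Resamples loci with replacement, re-estimates the species tree per
#' pseudoreplicate (seeded searches starting from the reference optimum
#' and any candidate pool), and reports the percentage of replicates
#' displaying each internal clade of the reference tree.
#'
#' @param loci an `ri_loci` list.
#' @param ref_tree reference optimal tree (`search_result` or `phylo`).
#' @param N number of pseudoreplicates (default 100).
#' @param seed master seed; replicate seeds are derived from it.
#' @param restarts per-replicate search restarts.
#' @param candidate_pool extra starting trees for every replicate search.
#' @param weighted logical.
#' @return A `bootstrap_support` object: data frame (`clade`, `percent`)
#'   plus `N` and `seed`.
#' @export
bootstrap_support <- function(loci, ref_tree, N = 100L, seed = 1L,
                              restarts = 3L, candidate_pool = NULL,
                              weighted = FALSE) {
  stopifnot(N >= 1L)
  taxa <- attr(loci, "taxa")
  ref <- as_phylo_tree(ref_tree)
  ref_clades <- internal_clades(ref)
  L <- length(loci)
  set.seed(seed)
  idx <- matrix(sample.int(L, L * N, replace = TRUE), nrow = L)
  rep_seeds <- sample.int(2^20, N)
  hits <- stats::setNames(integer(length(ref_clades)), names(ref_clades))
  for (i in seq_len(N)) {
    rloci <- loci[idx[, i]]
    res <- hillclimb_search(rloci, restarts = restarts, seed = rep_seeds[i],
                            candidate_pool = candidate_pool, start = ref,
                            weighted = weighted)
    for (key in names(ref_clades)) {
      if (tree_has_clade(res, ref_clades[[key]], taxa)) {
        hits[key] <- hits[key] + 1L
      }
    }
  }
  structure(list(table = data.frame(clade = names(ref_clades),
                                    percent = 100 * hits / N,
                                    row.names = NULL),
                 N = N, seed = seed),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat("Character bootstrap (", x$N, " pseudoreplicates)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Linked-support report
#'
#' Support for neighboring short branches is often interdependent: the
#' best tree lacking one clade may also lack others, and removing a few
#' key loci can collapse several clades at once.  For each focal clade
#' this report lists which other clades of the optimal tree are absent
#' from its anti-constraint tree; optional removal sets are re-searched to
#' show which clades collapse together.
#'
#' @param loci an `ri_loci` list.
#' @param optimal optimal tree (`search_result` or `phylo`).
#' @param clades list (or character vector for a single clade) of focal
#'   clades.
#' @param removal_sets optional list of locus-id vectors; for each, the
#'   tree is re-estimated without those loci and the collapsed clades
#'   reported.
#' @param weighted logical.
#' @param ... search controls passed on (`seed`, `restarts`, `method`).
#' @return List with `anti_constraint` (per focal clade: the other clades
#'   lost) and `joint_removal` (per removal set: clades collapsed).
#' @export
linked_support_report <- function(loci, optimal, clades,
                                  removal_sets = NULL, weighted = FALSE,
                                  ...) {
  if (is.character(clades)) clades <- list(clades)
  taxa <- attr(loci, "taxa")
  opt <- as_phylo_tree(optimal)
  opt_clades <- internal_clades(opt)
  # orientation-free split keys, so a focal clade and its complement are
  # reported under the same name
  canon <- function(side) split_label(side, opt$tip.label)
  names(opt_clades) <- vapply(opt_clades, canon, "")
  opt_clades <- opt_clades[!duplicated(names(opt_clades))]
  lost_in <- function(tree) {
    names(opt_clades)[!vapply(opt_clades, function(cl)
      tree_has_clade(tree, cl, taxa), logical(1))]
  }
  anti_tab <- lapply(clades, function(cl) {
    if (!tree_has_clade(opt, cl, taxa)) {
      stop("clade {", paste(cl, collapse = ","), "} not in optimal tree")
    }
    anti <- anticonstraint_search(loci, taxa = opt$tip.label,
                                  forbidden_clade = cl,
                                  weighted = weighted, ...)
    target_key <- canon(cl)
    list(clade = cl,
         lost = lost_in(anti),
         linked = setdiff(lost_in(anti), target_key),
         anti = anti)
  })
  names(anti_tab) <- vapply(clades, paste, "", collapse = ",")
  joint <- NULL
  if (!is.null(removal_sets)) {
    dots <- list(...)
    hc_dots <- dots[names(dots) %in% c("seed", "restarts", "use_spr")]
    joint <- lapply(removal_sets, function(ids) {
      keep <- vapply(loci, function(l)
        !(as.character(l$locus_id) %in% as.character(ids)), logical(1))
      reduced <- loci[keep]
      res <- do.call(hillclimb_search,
                     c(list(reduced, candidate_pool = list(opt),
                            weighted = weighted), hc_dots))
      # a clade is collapsed once it is absent from the re-searched
      # optimum or no longer strictly supported (an equally good tree
      # without it exists)
      collapsed <- lost_in(res)
      for (key in setdiff(names(opt_clades), collapsed)) {
        anti <- anticonstraint_search(reduced, taxa = opt$tip.label,
                                      forbidden_clade = opt_clades[[key]],
                                      weighted = weighted, ...)
        if (anti$score >= res$score - 1e-9) collapsed <- c(collapsed, key)
      }
      list(removed = ids, collapsed = collapsed, search = res)
    })
  }
  structure(list(anti_constraint = anti_tab, joint_removal = joint),
            class = "linked_support_report")
}

#' @export
print.linked_support_report <- function(x, ...) {
  for (nm in names(x$anti_constraint)) {
    a <- x$anti_constraint[[nm]]
    cat("Anti-constraint {", nm, "}: also lost ",
        if (length(a$linked)) paste(a$linked, collapse = "; ") else "none",
        "\n", sep = "")
  }
  invisible(x)
}
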