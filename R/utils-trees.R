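# Split-set plumbing shared by the scoring, search and annotation code.
#
# Unrooted leaf-labeled trees are handled in two interchangeable forms:
# an ape "phylo" object, and a "split set" -- the list of one side of each
# nontrivial bipartition, as integer taxon ids relative to a fixed taxon
# vector.  The split set is what the quartet counting kernel consumes.

# map taxon labels onto 1-based ids in `taxa`, erroring on unknown labels
taxon_ids <- function(labels, taxa) {
  ids <- match(labels, taxa)
  if (anyNA(ids)) {
    stop("unknown taxa: ", paste(labels[is.na(ids)], collapse = ", "))
  }
  ids
}

# tips below every node of a phylo, as local tip indices
below_tips <- function(phy) {
  n <- length(phy$tip.label)
  M <- n + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")$edge
  below <- vector("list", M)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]
    below[[p]] <- c(below[[p]], below[[po[e, 2L]]])
  }
  below
}

#' Nontrivial splits of a tree
#'
#' Decomposes an (un)rooted tree into its nontrivial bipartitions.  Each
#' split is reported as the side not containing the reference taxon
#' (the smallest id present in the tree), with the numeric support label of
#' the subtending edge when the tree carries node labels.
#'
#' @param phy a `phylo` object.
#' @param taxa character vector fixing the taxon indexing; defaults to the
#'   tree's own tip labels, sorted.
#' @return A list with one element per nontrivial split:
#'   `side` (integer ids), `support` (numeric or `NA`).  The full leaf id
#'   set is attached as attribute `leaf_ids`.
#' @export
tree_splits <- function(phy, taxa = sort(phy$tip.label)) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  ids <- taxon_ids(phy$tip.label, taxa)
  leaf_ids <- sort(ids)
  below <- below_tips(phy)
  has_lab <- !is.null(phy$node.label)
  out <- list()
  seen <- character()
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2L]
    if (child <= n) next
    tips <- below[[child]]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    side <- sort(ids[tips])
    if (leaf_ids[1L] %in% side) side <- setdiff(leaf_ids, side)
    key <- paste(side, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sup <- NA_real_
    if (has_lab) {
      lab <- phy$node.label[child - n]
      sup <- suppressWarnings(as.numeric(lab))
    }
    out[[length(out) + 1L]] <- list(side = side, support = sup)
  }
  attr(out, "leaf_ids") <- leaf_ids
  out
}

split_sides <- function(splits) lapply(splits, `[[`, "side")

# orientation-free display label for a split: the smaller side's taxa
# (lexicographically least on ties), comma-separated
split_label <- function(side_labels, all_labels) {
  a <- sort(side_labels)
  b <- sort(setdiff(all_labels, side_labels))
  k1 <- paste(a, collapse = ",")
  k2 <- paste(b, collapse = ",")
  if (length(a) < length(b)) k1
  else if (length(b) < length(a)) k2
  else min(k1, k2)
}

# does a split set contain clade|rest (either orientation)?
has_split <- function(sides, clade_ids, leaf_ids) {
  clade_ids <- sort(clade_ids)
  comp <- setdiff(leaf_ids, clade_ids)
  key1 <- paste(clade_ids, collapse = ",")
  key2 <- paste(comp, collapse = ",")
  any(vapply(sides, function(s) {
    k <- paste(sort(s), collapse = ",")
    k == key1 || k == key2
  }, logical(1)))
}

# canonical newick of the topology given by a split set: rooted for display
# at the alphabetically first taxon, children ordered by their alphabetically
# smallest descendant.  A deterministic total representative used for
# tie-breaking and tree identity.
canonical_newick <- function(sides, leaf_ids, taxa) {
  labs <- taxa[leaf_ids]
  ref_id <- leaf_ids[order(labs)][1L]
  clades <- lapply(sides, function(s) {
    if (ref_id %in% s) setdiff(leaf_ids, s) else sort(s)
  })
  # drop duplicates (both orientations of the same split)
  keys <- vapply(clades, paste, "", collapse = ",")
  clades <- clades[!duplicated(keys)]
  build <- function(set) {
    if (length(set) == 1L) return(taxa[set])
    inside <- clades[vapply(clades, function(cl)
      length(cl) < length(set) && all(cl %in% set), logical(1))]
    # maximal proper subclades
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j)
        j != i && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]]), logical(1)))
    }, logical(1))]
    covered <- unique(unlist(maximal))
    parts <- c(maximal, as.list(setdiff(set, covered)))
    subs <- vapply(parts, build, "")
    mins <- vapply(parts, function(p) min(taxa[p]), "")
    paste0("(", paste(subs[order(mins)], collapse = ","), ")")
  }
  paste0("(", taxa[ref_id], ",", build(setdiff(leaf_ids, ref_id)), ");")
}

# phylo from a split set (possibly non-binary), via the canonical newick
sides_to_phylo <- function(sides, leaf_ids, taxa) {
  ape::read.tree(text = canonical_newick(sides, leaf_ids, taxa))
}

# Enumerate all unrooted binary topologies on `ids` by stepwise insertion,
# calling fun(sides) for each (sides = nontrivial splits, global ids).
# Edges are tracked as clades away from the anchor taxon ids[1].
enumerate_topologies <- function(ids, fun, max_taxa = 9L) {
  n <- length(ids)
  if (n > max_taxa) {
    stop("exhaustive enumeration capped at ", max_taxa, " taxa")
  }
  if (n < 4L) {
    fun(list())
    return(invisible(NULL))
  }
  recurse <- function(clades, k) {
    if (k > n) {
      nontriv <- clades[vapply(clades, function(cl)
        length(cl) >= 2L && length(cl) <= n - 2L, logical(1))]
      fun(nontriv)
      return(invisible(NULL))
    }
    t_new <- ids[k]
    for (ei in seq_along(clades)) {
      C <- clades[[ei]]
      updated <- lapply(clades, function(D) {
        if (length(D) > length(C) && all(C %in% D)) c(D, t_new) else D
      })
      recurse(c(updated, list(c(C, t_new), t_new)), k + 1L)
    }
  }
  recurse(list(ids[2L], ids[3L], ids[c(2L, 3L)]), 4L)
  invisible(NULL)
}

# random unrooted binary topology on the given taxa (RNG-driven)
random_topology <- function(labels) {
  phy <- ape::rtree(length(labels), rooted = FALSE, tip.label = sample(labels))
  phy$edge.length <- NULL
  phy
}

# restriction of one split side to a 4-subset -> pairing code 0..3 (R oracle
# helper, independent of the C++ kernel)
induced_quartet_code <- function(sides, four) {
  four <- sort(four)
  for (s in sides) {
    inside <- four %in% s
    if (sum(inside) == 2L) {
      pair <- four[inside]
      if (all(pair == four[1:2]) || all(pair == four[3:4])) return(1L)
      if (all(pair == four[c(1, 3)]) || all(pair == four[c(2, 4)])) return(2L)
      return(3L)
    }
  }
  0L
}

# does `sides` (over leaf_ids) display every nontrivial split of a backbone
# tree (over a subset of the taxa)?
displays_backbone <- function(sides, backbone_sides, backbone_ids) {
  all(vapply(backbone_sides, function(bs) {
    bs <- sort(bs)
    comp <- setdiff(backbone_ids, bs)
    any(vapply(sides, function(s) {
      r <- sort(intersect(s, backbone_ids))
      identical(r, bs) || identical(r, comp)
    }, logical(1)))
  }, logical(1)))
}
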