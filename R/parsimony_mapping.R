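# Unordered (Fitch) parsimony of binary RI characters on fixed trees, and
# the synapomorphy bookkeeping built on it: perfectly congruent
# synapomorphies (characters explained by a single insertion on one
# branch), emergent clades (clades no character cleanly supports), and
# hidden synapomorphies (characters that become clean on a second tree).

# state-set codes: 1 = {absent}, 2 = {present}, 3 = {0,1} (missing)
state_codes <- function(states) {
  out <- matrix(3L, nrow(states), ncol(states))
  out[!is.na(states) & states == 0L] <- 1L
  out[!is.na(states) & states == 1L] <- 2L
  dimnames(out) <- dimnames(states)
  out
}

#' Fitch parsimony lengths of binary characters
#'
#' Two-pass (up-pass only is needed for lengths) Fitch counting on a
#' binary tree, vectorized across characters.  Missing entries carry the
#' full state set \{0, 1\} and never force a step.
#'
#' @param states taxa x characters matrix with entries 0, 1, `NA`;
#'   rownames must cover the tree's tip labels.
#' @param tree a binary `phylo` (a degree-2 or degree-3 root is fine).
#' @return Integer vector of parsimony lengths, one per character.
#' @export
fitch_lengths <- function(states, tree) {
  stopifnot(inherits(tree, "phylo"))
  states <- as.matrix(states)
  if (is.null(rownames(states))) stop("states must have taxon rownames")
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss)) stop("no states for: ", paste(miss, collapse = ", "))
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  codes <- state_codes(states[tree$tip.label, , drop = FALSE])
  L <- ncol(codes)
  sets <- matrix(0L, M, L)
  sets[seq_len(n), ] <- codes
  steps <- integer(L)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]
    child <- sets[po[e, 2L], ]
    acc <- sets[p, ]
    if (all(acc == 0L)) {
      sets[p, ] <- child
    } else {
      inter <- bitwAnd(acc, child)
      empty <- inter == 0L
      steps <- steps + empty
      sets[p, ] <- ifelse(empty, bitwOr(acc, child), inter)
    }
  }
  steps
}

#' Fitch analysis of a single character
#'
#' Parsimony length plus, for length-1 characters, the set of edges that
#' can host the single change across all most-parsimonious
#' reconstructions: exactly the edges whose split separates the
#' present-coded from the absent-coded taxa.  The change direction on each
#' feasible edge is a gain (0 to 1, an insertion) when the present taxa
#' sit on the clade side of a rooted tree, a loss otherwise.
#'
#' @param character named vector of states (0/1/`NA`) covering the tree
#'   tips, or a 1-column piece of an [ri_matrix()].
#' @param tree a binary `phylo`; rooted orientation is used to call
#'   gain vs. loss.
#' @return A `fitch_result`: `length`, `edges` (list of feasible change
#'   edges, each with `clade` tip labels and `direction`), `unequivocal`
#'   (exactly one feasible edge).
#' @export
fitch_length <- function(character, tree) {
  ch <- character
  if (is.null(names(ch))) stop("character must be named by taxon")
  if (sum(!is.na(ch)) < 1L) stop("character has no scored taxa")
  st <- matrix(as.integer(ch), ncol = 1L, dimnames = list(names(ch), NULL))
  len <- fitch_lengths(st, tree)[1L]
  edges <- list()
  if (len == 1L) {
    n <- length(tree$tip.label)
    below <- below_tips(tree)
    ones <- names(ch)[!is.na(ch) & ch == 1L]
    zeros <- names(ch)[!is.na(ch) & ch == 0L]
    found <- list() # keyed by unrooted split, so the two edges of a
                    # degree-2 root collapse into one feasible edge
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 2L]
      clade <- tree$tip.label[below[[v]]]
      rest <- setdiff(tree$tip.label, clade)
      sep_gain <- all(ones %in% clade) && all(zeros %in% rest)
      sep_loss <- all(zeros %in% clade) && all(ones %in% rest)
      if (!sep_gain && !sep_loss) next
      key <- min(paste(sort(clade), collapse = ","),
                 paste(sort(rest), collapse = ","))
      hit <- list(clade = sort(clade),
                  direction = if (sep_gain) "gain" else "loss")
      if (is.null(found[[key]]) || hit$direction == "gain") {
        found[[key]] <- hit
      }
    }
    edges <- unname(found)
  }
  structure(list(length = len, edges = edges,
                 unequivocal = len == 1L && length(edges) == 1L),
            class = "fitch_result")
}

#' @export
print.fitch_result <- function(x, ...) {
  cat("Fitch length", x$length,
      if (x$unequivocal) "(unequivocal)" else "", "\n")
  invisible(x)
}

# internal clades of a rooted phylo as sorted label vectors (non-trivial
# in the unrooted sense)
internal_clades <- function(tree) {
  n <- length(tree$tip.label)
  below <- below_tips(tree)
  out <- list()
  seen <- character()
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2L]
    if (v <= n) next
    clade <- sort(tree$tip.label[below[[v]]])
    if (length(clade) > n - 2L) next
    key <- paste(clade, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[key]] <- clade
  }
  out
}

#' Perfectly congruent RI synapomorphies per clade
#'
#' Maps every character of the matrix onto the tree and counts, for each
#' internal clade, the characters whose single unequivocal change is a
#' gain (insertion) on the branch subtending that clade.  Clades with no
#' such character are flagged emergent: their support arises only from
#' combining conflicting quartets.  Losses (single 1-to-0 changes) are
#' tallied separately and do not count as synapomorphies.
#'
#' With `relaxed = TRUE`, characters whose feasible change-edge set is
#' ambiguous because of missing data are assigned to the shallowest
#' (smallest-clade) feasible gain edge instead of being set aside as
#' equivocal.
#'
#' @param m an [ri_matrix()].
#' @param tree a rooted binary `phylo` over the matrix taxa (rooting fixes
#'   the gain/loss orientation).
#' @param relaxed logical; resolve missing-data ambiguity to the
#'   shallowest feasible edge (default `FALSE`, strict).
#' @return A `synapomorphy_report`: data frame (`clade`, `synapomorphies`,
#'   `losses`, `emergent`) plus attributes `equivocal` (character ids set
#'   aside) and `assignments` (per-character clade, strict or relaxed).
#' @export
synapomorphy_scan <- function(m, tree, relaxed = FALSE) {
  stopifnot(inherits(m, "ri_matrix"))
  clades <- internal_clades(tree)
  syn <- stats::setNames(integer(length(clades)), names(clades))
  loss <- syn
  equivocal <- character()
  assignments <- list()
  for (j in seq_len(ncol(m$states))) {
    ch <- stats::setNames(m$states[, j], m$taxa)
    ones <- sum(!is.na(ch) & ch == 1L)
    zeros <- sum(!is.na(ch) & ch == 0L)
    if (ones == 0L || zeros == 0L) next # constant or all-missing: no change
    fr <- fitch_length(ch, tree)
    if (fr$length != 1L) next
    gains <- Filter(function(e) e$direction == "gain", fr$edges)
    gains <- Filter(function(e) length(e$clade) <= length(m$taxa) - 2L, gains)
    if (!length(gains)) { # single change but only as a loss
      losses <- Filter(function(e) e$direction == "loss", fr$edges)
      if (length(losses) == 1L) {
        key <- paste(losses[[1L]]$clade, collapse = ",")
        if (key %in% names(loss)) loss[key] <- loss[key] + 1L
      }
      next
    }
    pick <- NULL
    if (length(gains) == 1L && fr$unequivocal) {
      pick <- gains[[1L]]
    } else if (relaxed) {
      sizes <- vapply(gains, function(e) length(e$clade), 0L)
      pick <- gains[[which.min(sizes)]]
    } else {
      equivocal <- c(equivocal, as.character(m$locus_ids[j]))
      next
    }
    key <- paste(pick$clade, collapse = ",")
    if (key %in% names(syn)) {
      syn[key] <- syn[key] + 1L
      assignments[[as.character(m$locus_ids[j])]] <- pick$clade
    }
  }
  out <- data.frame(clade = names(clades),
                    synapomorphies = as.integer(syn),
                    losses = as.integer(loss),
                    emergent = syn == 0L, row.names = NULL)
  attr(out, "equivocal") <- equivocal
  attr(out, "assignments") <- assignments
  class(out) <- c("synapomorphy_report", "data.frame")
  out
}

#' Hidden synapomorphies between two trees
#'
#' Characters that are unequivocal gain synapomorphies on `tree_b` (say, a
#' combined-data species tree) but not on `tree_a` (the tree from the RI
#' data alone), listed per clade of `tree_b`.
#'
#' @param m an [ri_matrix()].
#' @param tree_a,tree_b rooted binary `phylo` objects on the same taxa.
#' @param relaxed passed to the per-tree scans.
#' @return Data frame (`locus_id`, `clade`) of hidden synapomorphies.
#' @export
hidden_synapomorphies <- function(m, tree_a, tree_b, relaxed = FALSE) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees must share the same taxon set")
  }
  scan_a <- synapomorphy_scan(m, tree_a, relaxed)
  scan_b <- synapomorphy_scan(m, tree_b, relaxed)
  in_a <- names(attr(scan_a, "assignments"))
  in_b <- attr(scan_b, "assignments")
  hidden <- setdiff(names(in_b), in_a)
  if (!length(hidden)) {
    return(data.frame(locus_id = character(), clade = character()))
  }
  data.frame(
    locus_id = hidden,
    clade = vapply(in_b[hidden], paste, "", collapse = ","),
    row.names = NULL)
}
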