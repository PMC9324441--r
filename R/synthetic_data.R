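# Coalescent simulation of RI presence/absence characters.
#
# Gene genealogies are simulated backward in time under the multispecies
# coalescent on an ultrametric species tree with branch lengths in
# coalescent units (one sampled haploid lineage per species; coalescence
# rate k(k-1)/2 for k lineages within a branch).  An optional single
# reticulation lets each lineage present in the recipient branch at the
# event time follow the donor branch independently with probability gamma
# (the admixture fraction).  An RI character arises by dropping one
# insertion on a genealogy branch chosen with probability proportional to
# its length (a constant insertion accumulation rate); the taxa
# descending from the insertion are coded present, the rest absent.
# Conflict between characters and the species tree is then genuine
# hemiplasy (or introgression), never coding error.

#' Simulation configuration
#'
#' @param species_tree rooted ultrametric `phylo` with branch lengths in
#'   coalescent units.
#' @param n_characters number of RI characters to generate.
#' @param reticulation optional list `(donor, recipient, time, gamma)`:
#'   `donor`/`recipient` give the taxon labels of the clade below the
#'   respective branch (a single label for a terminal branch), `time` the
#'   event age in CU (strictly inside both branches), `gamma` the
#'   probability a recipient lineage traces the donor branch.
#' @param placement `"any-branch"` (default) or `"internal-only"`:
#'   genealogy branches eligible for insertions.
#' @param informative_only logical; resample each character until it has
#'   at least two present and two absent taxa (before masking).
#' @param missing_probs per-taxon probability of masking a cell to
#'   missing; scalar or vector over taxa (default 0).
#' @param seed optional RNG seed applied by the simulation entry points.
#' @return A `sim_config` object (validated, with precomputed node ages).
#' @export
sim_config <- function(species_tree, n_characters = 1000L,
                       reticulation = NULL,
                       placement = c("any-branch", "internal-only"),
                       informative_only = FALSE, missing_probs = 0,
                       seed = NULL) {
  placement <- match.arg(placement)
  phy <- species_tree
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("species tree needs branch lengths (CU)")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.ultrametric(phy, tol = 1e-6)) {
    stop("species tree must be ultrametric (contemporaneous tips)")
  }
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(n)]) - depth
  age[age < 0] <- 0
  M <- n + phy$Nnode
  parent <- integer(M)
  for (e in seq_len(nrow(phy$edge))) parent[phy$edge[e, 2L]] <- phy$edge[e, 1L]
  children <- lapply(seq_len(M), function(v) phy$edge[phy$edge[, 1L] == v, 2L])
  root <- which(parent == 0L)[1L]
  below <- below_tips(phy)
  retic <- NULL
  if (!is.null(reticulation)) {
    stopifnot(all(c("donor", "recipient", "time", "gamma") %in%
                    names(reticulation)))
    g <- reticulation$gamma
    if (g < 0 || g > 1) stop("gamma must lie in [0, 1]")
    find_branch <- function(labels) {
      want <- sort(match(labels, phy$tip.label))
      if (anyNA(want)) stop("unknown taxon in reticulation spec")
      for (v in seq_len(M)) {
        if (v == root) next
        if (identical(sort(below[[v]]), want)) return(v)
      }
      stop("no branch subtends clade {", paste(labels, collapse = ","), "}")
    }
    d <- find_branch(reticulation$donor)
    r <- find_branch(reticulation$recipient)
    tau <- reticulation$time
    for (v in c(d, r)) {
      if (!(tau > age[v] && tau < age[parent[v]])) {
        stop("reticulation time must lie strictly inside both branches")
      }
    }
    if (d == r) stop("donor and recipient branches must differ")
    retic <- list(donor = d, recipient = r, time = tau, gamma = g)
  }
  missing_probs <- rep_len(missing_probs, n)
  if (any(missing_probs < 0 | missing_probs >= 1)) {
    stop("missing probabilities must lie in [0, 1)")
  }
  structure(list(tree = phy, n_tips = n, age = age, parent = parent,
                 children = children, root = root,
                 node_order = order(age[(n + 1L):M]) + n,
                 reticulation = retic, n_characters = as.integer(n_characters),
                 placement = placement, informative_only = informative_only,
                 missing_probs = stats::setNames(missing_probs, phy$tip.label),
                 seed = seed),
            class = "sim_config")
}

# one genealogy in compact form: parent pointers and ages over
# n_tips + (n_tips - 1) nodes (tips first), root parent = 0
sim_genealogy_compact <- function(cfg) {
  n <- cfg$n_tips
  gpar <- integer(2L * n - 1L)
  gage <- numeric(2L * n - 1L)
  nxt <- n # last allocated genealogy node id
  pool <- vector("list", length(cfg$parent))
  frontier <- numeric(length(cfg$parent))
  for (i in seq_len(n)) {
    pool[[i]] <- i
    frontier[i] <- cfg$age[i]
  }
  coalesce <- function(v, up) {
    lin <- pool[[v]]
    t <- frontier[v]
    k <- length(lin)
    while (k >= 2L) {
      t <- t + stats::rexp(1L, k * (k - 1L) / 2)
      if (t > up) break
      pick <- sample.int(k, 2L)
      nxt <<- nxt + 1L
      gpar[lin[pick]] <<- nxt
      gage[nxt] <<- t
      lin <- c(lin[-pick], nxt)
      k <- k - 1L
    }
    pool[[v]] <<- lin
    frontier[v] <<- up
    invisible(NULL)
  }
  events <- data.frame(age = cfg$age[cfg$node_order], node = cfg$node_order,
                       type = "node")
  if (!is.null(cfg$reticulation)) {
    events <- rbind(events,
                    data.frame(age = cfg$reticulation$time, node = NA_integer_,
                               type = "retic"))
    events <- events[order(events$age), , drop = FALSE]
  }
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == "retic") {
      re <- cfg$reticulation
      coalesce(re$recipient, re$time)
      coalesce(re$donor, re$time)
      lin <- pool[[re$recipient]]
      move <- stats::runif(length(lin)) < re$gamma
      if (any(move)) {
        pool[[re$donor]] <- c(pool[[re$donor]], lin[move])
        pool[[re$recipient]] <- lin[!move]
      }
    } else {
      u <- events$node[i]
      merged <- integer()
      for (ch in cfg$children[[u]]) {
        coalesce(ch, cfg$age[u])
        merged <- c(merged, pool[[ch]])
        pool[[ch]] <- integer()
      }
      pool[[u]] <- merged
      frontier[u] <- cfg$age[u]
    }
  }
  coalesce(cfg$root, Inf)
  list(parent = gpar, age = gage, n_tips = n)
}

# tips descending from a genealogy node
tips_below_compact <- function(g, node) {
  if (node <= g$n_tips) return(node)
  out <- integer()
  for (tip in seq_len(g$n_tips)) {
    v <- tip
    while (v != 0L) {
      if (v == node) {
        out <- c(out, tip)
        break
      }
      v <- g$parent[v]
    }
  }
  out
}

compact_to_phylo <- function(g, tip_labels, with_lengths = TRUE) {
  build <- function(v) {
    kids <- which(g$parent == v)
    if (!length(kids)) {
      lab <- tip_labels[v]
    } else {
      lab <- paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
    }
    if (with_lengths && g$parent[v] != 0L) {
      paste0(lab, ":", format(g$age[g$parent[v]] - g$age[v], digits = 10))
    } else {
      lab
    }
  }
  root <- which(g$parent == 0L)[1L] # full coalescence leaves one root
  ape::read.tree(text = paste0(build(root), ";"))
}

#' Simulate one MSC gene genealogy
#'
#' @param config a [sim_config()].
#' @return A `phylo` with branch lengths in coalescent units.
#' @export
simulate_msc_gene_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- sim_genealogy_compact(config)
  compact_to_phylo(g, config$tree$tip.label)
}

#' Simulate an RI character matrix
#'
#' Per character: a gene genealogy is simulated, an insertion branch is
#' drawn with probability proportional to branch length (restricted by
#' the placement mode), descendant taxa are coded present and the rest
#' absent; optionally the character is resampled until informative (at
#' least two present and two absent taxa); per-taxon missing masking is
#' applied last.  The truth record keeps each character's insertion clade
#' and (optionally) its genealogy.
#'
#' @param config a [sim_config()].
#' @param keep_genealogies logical; retain each character's genealogy
#'   (`phylo`) in the truth record (memory-hungry for many characters).
#' @return List with `matrix` (an [ri_matrix()]) and `truth` (per
#'   character: `insertion_clade` taxon labels; optionally `genealogy`).
#' @export
simulate_ri_matrix <- function(config, keep_genealogies = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_tips
  labs <- config$tree$tip.label
  L <- config$n_characters
  states <- matrix(0L, n, L, dimnames = list(labs, NULL))
  clades <- vector("list", L)
  gens <- if (keep_genealogies) vector("list", L) else NULL
  max_tries <- 1000L
  for (j in seq_len(L)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      g <- sim_genealogy_compact(config)
      nodes <- which(g$parent != 0L)
      if (config$placement == "internal-only") {
        nodes <- nodes[nodes > n]
      }
      len <- g$age[g$parent[nodes]] - g$age[nodes]
      if (!length(nodes) || sum(len) <= 0) {
        stop("no genealogy branch eligible for insertion placement")
      }
      ins <- nodes[sample.int(length(nodes), 1L, prob = len)]
      pres <- tips_below_compact(g, ins)
      if (config$informative_only &&
          (length(pres) < 2L || n - length(pres) < 2L)) {
        next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("informative character unattainable after ", max_tries,
           " resampling attempts")
    }
    col <- integer(n)
    col[pres] <- 1L
    states[, j] <- col
    clades[[j]] <- sort(labs[pres])
    if (keep_genealogies) gens[[j]] <- compact_to_phylo(g, labs)
  }
  # independent per-cell masking with per-taxon rates
  mp <- config$missing_probs
  if (any(mp > 0)) {
    mask <- matrix(stats::runif(n * L), n, L) < mp
    states[mask] <- NA_integer_
  }
  truth <- list(insertion_clade = clades)
  if (keep_genealogies) truth$genealogy <- gens
  list(matrix = ri_matrix(states, taxa = labs), truth = truth)
}

#' Simulate support-labeled gene trees
#'
#' MSC genealogies whose internal edges are independently perturbed by a
#' nearest-neighbor interchange with probability `error_rate`, emulating
#' gene-tree reconstruction error.  Internal nodes carry bootstrap-like
#' support labels: perturbed edges draw uniformly from
#' `support_low`, intact edges from `support_high`.
#'
#' @param config a [sim_config()].
#' @param n_trees number of gene trees.
#' @param error_rate per-internal-edge NNI perturbation probability in
#'   \[0, 1).
#' @param support_low,support_high label ranges (default 0-49 and
#'   70-100).
#' @return A `multiPhylo` of topologies with node labels (no branch
#'   lengths).
#' @export
simulate_support_gene_trees <- function(config, n_trees, error_rate = 0,
                                        support_low = c(0, 49),
                                        support_high = c(70, 100)) {
  stopifnot(inherits(config, "sim_config"),
            error_rate >= 0, error_rate < 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (n_trees == 0L) {
    out <- list()
    class(out) <- "multiPhylo"
    return(out)
  }
  n <- config$n_tips
  labs <- config$tree$tip.label
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    g <- sim_genealogy_compact(config)
    par <- g$parent
    kids <- function(v) which(par == v)
    root <- which(par == 0L)
    root <- root[root > n][1L]
    perturbed <- logical(length(par))
    for (v in seq_along(par)) {
      if (v <= n || par[v] == 0L) next # tip or root
      if (stats::runif(1L) >= error_rate) next
      sib <- setdiff(kids(par[v]), v)
      ch <- kids(v)
      if (!length(sib) || length(ch) < 2L) next
      sib <- sib[1L]
      swap <- ch[sample.int(length(ch), 1L)]
      par[swap] <- par[v]
      par[sib] <- v
      perturbed[v] <- TRUE
    }
    support <- function(v) {
      rng <- if (perturbed[v]) support_low else support_high
      round(stats::runif(1L, rng[1L], rng[2L]))
    }
    build <- function(v) {
      kv <- which(par == v)
      if (!length(kv)) return(labs[v])
      s <- paste0("(", paste(vapply(kv, build, ""), collapse = ","), ")")
      if (par[v] != 0L) paste0(s, support(v)) else s
    }
    out[[i]] <- ape::read.tree(text = paste0(build(root), ";"))
  }
  class(out) <- "multiPhylo"
  out
}
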