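# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately naive (explicit enumeration, fine-grid quadrature) and
# share no code with the implementation paths they check.

sides_of <- function(phy, taxa = sort(phy$tip.label)) {
  lapply(tree_splits(phy, taxa), `[[`, "side")
}

# does a tree display clade | rest (either orientation)?
displays_clade <- function(tree, clade, taxa = sort(tree$tip.label)) {
  ids <- sort(match(clade, taxa))
  full <- sort(match(tree$tip.label, taxa))
  any(vapply(sides_of(tree, taxa), function(s) {
    s <- sort(s)
    identical(s, ids) || identical(s, sort(setdiff(full, ids)))
  }, logical(1)))
}

# unrooted topological identity
same_topology <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0
}

# ri_matrix whose characters are clean copies of the nontrivial splits of
# a tree (zero conflict, zero missing data)
clean_matrix_from_tree <- function(phy, copies = 1L) {
  taxa <- sort(phy$tip.label)
  sides <- sides_of(phy, taxa)
  cols <- do.call(cbind, rep(lapply(sides, function(s) {
    col <- rep(0L, length(taxa))
    col[s] <- 1L
    col
  }), copies))
  rownames(cols) <- taxa
  ri_matrix(cols)
}

# loci list for explicit split columns given as taxon-label lists
loci_from_splits <- function(split_list, taxa, excluded = NULL) {
  cols <- vapply(seq_along(split_list), function(i) {
    col <- rep(0L, length(taxa))
    col[match(split_list[[i]], taxa)] <- 1L
    if (!is.null(excluded) && length(excluded[[i]])) {
      col[match(excluded[[i]], taxa)] <- NA_integer_
    }
    col
  }, integer(length(taxa)))
  rownames(cols) <- taxa
  bp_loci(to_bipartitions(ri_matrix(cols), min_side = 2L))
}

# random binary matrix with missing cells; returned as quartet-engine loci
random_instance <- function(n_taxa, n_loci, miss = 0.15) {
  taxa <- paste0("t", seq_len(n_taxa))
  repeat {
    states <- matrix(sample(c(0L, 1L), n_taxa * n_loci, replace = TRUE),
                     n_taxa, n_loci, dimnames = list(taxa, NULL))
    states[matrix(runif(n_taxa * n_loci) < miss, n_taxa)] <- NA_integer_
    bps <- to_bipartitions(ri_matrix(states), min_side = 2L)
    if (length(bps) >= max(2L, n_loci %/% 2L)) {
      return(list(taxa = taxa, loci = bp_loci(bps), states = states))
    }
  }
}

random_unrooted <- function(taxa) {
  phy <- ape::rtree(length(taxa), rooted = FALSE, tip.label = sample(taxa))
  phy$edge.length <- NULL
  phy
}

# brute-force minimum parsimony length: enumerate every 0/1 assignment to
# internal nodes and to missing tips
brute_fitch <- function(ch, tree) {
  n <- length(tree$tip.label)
  ch <- ch[tree$tip.label]
  free_tips <- which(is.na(ch))
  n_int <- tree$Nnode
  stopifnot(n_int + length(free_tips) <= 14L)
  states <- integer(n + n_int)
  states[seq_len(n)] <- ifelse(is.na(ch), 0L, as.integer(ch))
  best <- Inf
  n_free <- n_int + length(free_tips)
  for (mask in 0:(2^n_free - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(n_free)]
    st <- states
    if (length(free_tips)) st[free_tips] <- bits[seq_along(free_tips)]
    st[n + seq_len(n_int)] <- bits[length(free_tips) + seq_len(n_int)]
    len <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
    if (len < best) best <- len
  }
  best
}

# fine-grid Simpson quadrature for the local-PP posterior weights
pp_oracle <- function(n, rate = 0.5, upper = 60, pts = 60001L) {
  m <- sum(n)
  if (m == 0) return(rep(1 / 3, 3L))
  tt <- seq(0, upper, length.out = pts)
  h <- tt[2L] - tt[1L]
  logf <- function(k) {
    k * log(1 - (2 / 3) * exp(-tt)) + (m - k) * (log(1 / 3) - tt) +
      log(rate) - rate * tt
  }
  K <- max(vapply(n, function(k) max(logf(k)), 0))
  simpson <- function(y) {
    h / 3 * (y[1L] + y[pts] + 4 * sum(y[seq(2L, pts - 1L, 2L)]) +
               2 * sum(y[seq(3L, pts - 2L, 2L)]))
  }
  w <- vapply(n, function(k) simpson(exp(logf(k) - K)), 0)
  w / sum(w)
}

# grid-search oracle for the triplet hybridization likelihood
triplet_grid_loglik <- function(n, major, alt,
                                t_grid = seq(0, 4, by = 0.002),
                                g_grid = seq(0, 1, by = 0.002)) {
  probs_for <- function(t, which) {
    p <- 1 - (2 / 3) * exp(-t)
    q <- (1 / 3) * exp(-t)
    out <- rep(q, 3L)
    out[which] <- p
    out
  }
  best <- -Inf
  for (t in t_grid) {
    pa <- probs_for(t, major)
    pb <- probs_for(t, alt)
    for (g in g_grid) {
      pr <- (1 - g) * pa + g * pb
      ll <- sum(n[n > 0] * log(pr[n > 0]))
      if (ll > best) best <- ll
    }
  }
  best
}

# ultrametric species tree with a focal internal branch of length t:
# ((A,B) joined at 1, +C at 1+t, +D, then the (E,F) cherry)
six_taxon_tree <- function(t_focal) {
  txt <- sprintf(
    "((((A:1,B:1):%g,C:%g):1,D:%g):1,(E:0.5,F:0.5):%g);",
    t_focal, 1 + t_focal, 2 + t_focal, 2.5 + t_focal)
  ape::read.tree(text = txt)
}
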