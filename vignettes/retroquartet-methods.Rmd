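---
title: "Quartet-based coalescent analysis of retroelement insertion characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet-based coalescent analysis of retroelement insertion characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroquartet)
```

## The model

A retroelement insertion (RI) at an orthologous genomic site is a
rare-genomic-change character: present (1) in the taxa descending from the
insertion event, absent (0) elsewhere, missing (?) where the locus cannot
be recovered from the assembly. Because precise excision is rare, a
conflicting RI distribution is usually not homoplasy but *hemiplasy*: the
insertion happened on a gene genealogy branch that is discordant with the
species tree because of incomplete lineage sorting (ILS), or it crossed
lineages by introgression.

`retroquartet` treats each RI character as a minimal "gene tree": an
unrooted tree over the taxa scored for that character, with one internal
edge separating the present side from the absent side. Everything
downstream is built on quartet agreement under the multispecies coalescent
(MSC). For an internal species-tree branch of length $t$ coalescent units
(CU), a quartet with one lineage entering from each of the four clusters
adjacent to the branch resolves to the species-tree pairing with
probability

$$p(t) = 1 - \tfrac{2}{3} e^{-t},$$

and to each alternative with $q(t) = \tfrac13 e^{-t}$. This single
relation powers the whole pipeline:

* **Scoring and search.** The quartet score of a candidate species tree is
  the number (or support weight) of 4-leaf subsets on which an input locus
  and the candidate agree. Scores are computed exactly (no quartet
  sampling) by a compiled kernel that assigns each 4-subset of a locus its
  induced topology once; search is exhaustive up to 9 taxa and seeded
  random-restart NNI hill climbing with SPR kicks beyond that. An
  anti-constraint mode finds the best tree *lacking* a focal clade.
* **Branch annotation.** Around each internal branch the counts
  $(n_1, n_2, n_3)$ of quartets supporting the three resolutions give the
  length estimate $\hat t = -\log\bigl(\tfrac32 (1 - n_1/m)\bigr)$
  (clamped to 0 at frequencies $\le 1/3$, capped near saturation) and a
  Bayesian local posterior probability: topology $i$ gets weight
  $\int_0^\infty p(t)^{n_i} q(t)^{m-n_i}\,\lambda e^{-\lambda t}\,dt$
  under equal topology priors, evaluated by adaptive quadrature on the log
  scale.
* **Support and stability.** Character bootstrap; partitioned coalescence
  support (PCS), the per-locus share of the score difference between the
  optimum and the best anti-constraint tree (the shares sum exactly to
  that difference); a greedy locus-removal index; and linked-support
  reports that show which clades collapse together.
* **Parsimony mapping.** Binary Fitch lengths identify *perfectly
  congruent synapomorphies* (a single unequivocal gain on one branch),
  *emergent* clades (no clean supporting character at all), and *hidden
  synapomorphies* (characters that become clean only on a combined-data
  tree). The quartet-parsimony + MRP supertree route (parsimony on every
  4-taxon subset, assembled by matrix representation with parsimony)
  provides an independent topological cross-check.
* **Introgression.** Under the MSC the two minority resolutions of a
  quartet are symmetric; an exact two-tailed binomial test (doubled
  smaller tail, capped at 1) flags skew. For species triples, a
  multinomial likelihood-ratio test compares polytomy, tree, and a
  hybridization mixture $(1-\gamma)\,P(t;\text{major}) +
  \gamma\,P(t;\text{alt})$, reporting $\hat\gamma$ and boundary-corrected
  ($\tfrac12\chi^2_0 + \tfrac12\chi^2_1$) p-values.

## Worked example

```{r example}
tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
m <- clean <- ri_matrix(structure(
  vapply(lapply(tree_splits(tr, sort(tr$tip.label)), `[[`, "side"),
         function(s) { col <- rep(0L, 6); col[s] <- 1L; col },
         integer(6)),
  dimnames = list(sort(tr$tip.label), NULL)))
loci <- bp_loci(to_bipartitions(m, min_side = 2))
opt <- hillclimb_search(loci, restarts = 5, seed = 1)
opt$score
annotate_tree(opt$tree, loci)$table[, c("clade", "n1", "n2", "n3", "EN")]
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_side` | 2 | taxa required on each side of a bipartition; 2+2 is the minimal condition for a character to induce any quartet, so the default retains exactly the quartet-informative characters |
| `prior_rate` | 0.5 | exponential prior rate (per CU) on branch lengths in the local-PP integral; 0.5 is the conventional default for this posterior |
| `collapse` | — | gene-tree edges with support at or below this are contracted; 5 removes arbitrarily resolved nodes, 49 keeps only majority-supported ones |
| weight of an RI bipartition | 100 | in weighted analyses an RI counts like a maximally supported gene-tree edge, no more |
| `restarts`, `seed` | 20, user | hill-climbing is seeded and deterministic; restarts trade time for search thoroughness |
| saturation guard `eps` | 1e-6 | majority frequencies above $1-\epsilon$ report the capped length $-\log(1.5\epsilon)$ with a `saturated` flag rather than infinity |

Three numerical choices deserve note. (1) *Weights for multi-edge gene
trees*: the weight of an induced quartet is the minimum edge support along
the internal path connecting its two cherries. This is monotone, reduces
to the single edge's support for bipartition loci, and approximates
support-weighted scoring without re-deriving a full weighting scheme.
(2) *Ties*: wherever one tree must be returned from a tied optimum the
canonical (lexicographically least) representative is chosen and the tie
is flagged; per-4-subset parsimony ties contribute every co-optimal
topology as an MRP row. (3) *Collapse in the removal index*: a clade
counts as collapsed as soon as its coalescence support reaches zero — an
equally good tree without the clade exists — rather than only when a
particular search run happens to return a tree lacking it; this makes the
greedy index insensitive to tie-breaking inside the search. The index is
reported as an upper bound on the true minimum, which the greedy
procedure cannot certify.

## The simulator, and what passing tests show

`sim_config()` + `simulate_ri_matrix()` generate characters by the same
process the analyses assume: MSC genealogies on an ultrametric species
tree in CU (one haploid lineage per species; rate $k(k-1)/2$), an optional
single reticulation where each recipient-branch lineage independently
follows the donor with probability $\gamma$, and one insertion per
character placed on a genealogy branch with probability proportional to
its length (a constant accumulation rate; the root stem is excluded since
it would yield an invariant character). Missing data are masked
independently per cell with per-taxon rates; the bundled study conditions
use a 0.28 rate, matching the mean missing-data load of large empirical
RI matrices. Gene trees with reconstruction error are emulated
topologically: each internal edge is NNI-perturbed with a set
probability and labeled with a low (0–49) support, intact edges with a
high (70–100) one.

The simulator is calibrated against closed forms (triplet and quartet
pairing frequencies within Monte-Carlo error of $1-\tfrac23 e^{-t}$, both
for triples and for the four-cluster tallies around an internal branch)
and drives the end-to-end checks: branch-length recovery from 5000
informative characters at $t \in \{0.05, 0.15, 0.30\}$ (median over 20
seeds, ±20% target), asymmetry-test size at $\gamma = 0$ and power at
$\gamma = 0.3$. Problem sizes in the test suite (6–15 taxa, hundreds to
thousands of characters, tens of replicates) were chosen as the smallest
at which these properties are stably visible.

The recovery check exposes a real property of the estimator worth
understanding before trusting absolute branch lengths. A character
resolves a given quartet only when its insertion falls on the central
path of that quartet in the gene genealogy, so under a constant
accumulation rate genealogy classes are weighted by central-path length —
and concordant genealogies (which can coalesce inside the focal branch,
low in the tree) carry systematically longer central paths than
discordant ones. The majority frequency, and hence $\hat t$, is inflated.
On the bundled six-taxon study tree the tally applied to the raw
genealogies recovers $t$ within Monte-Carlo error, while the same tally
on the derived RI characters lands the median estimate within the ±20%
target only at $t = 0.15$, overshooting by roughly 25–35% at 0.05 and
0.30. The short-branch *ranking* (which internodes are radiation-like) is
unaffected; absolute CU values from RI characters should be read as
modest overestimates.

What the simulator does *not* emulate: real missing data are driven by
assembly quality and are strongly non-independent across loci; insertion
rates vary across lineages; characters can be mis-coded; and sequence-
based gene-tree error is not an NNI process. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness of RI phylogenomics to these violations.

## Design decisions on genuinely open points

* **Informativeness rule.** A character is quartet-informative iff at
  least two taxa are coded on each side after dropping missing entries —
  the minimal condition for inducing any quartet. This is a
  reconstruction; it is validated only against the known informative
  count of the motivating 48-taxon matrix (2113 of 2118).
* **EN.** The effective number of loci at a branch is defined as the
  count of loci inducing at least one quartet across the branch's four
  clusters; for single-bipartition loci this coincides with the usual
  gene-tree definition.
* **Branch-length input.** $\hat t$ uses raw quartet counts $n_1/m$, not
  a per-locus-normalized frequency; for bipartition loci each locus
  contributes one split, so the distinction is immaterial there.
* **Synapomorphy orientation.** The derived state is presence: a single
  unequivocal 0→1 change is a synapomorphy; a single 1→0 change is
  reported separately as a loss. Characters whose change edge is
  ambiguous because of missing data are set aside as equivocal by
  default; a relaxed mode assigns them to the shallowest feasible gain
  edge, and both counts are reported rather than silently choosing one.
* **Triplet test.** The triplet LRT is a re-implementation as a
  two-parameter multinomial mixture model; its p-values are not expected
  to match any particular web tool's. The direction of introgression is
  not identifiable from unrooted triplet counts, so $\hat\gamma$ is
  reported as the contribution of the alternative pairing.
* **Two-tailed convention.** The binomial p is the doubled smaller exact
  tail capped at 1; this convention reproduces the reference value 0.0817
  for minority counts 40 vs 25.

## Known limitations

* Terminal branch lengths are not estimated (quartet tallies only inform
  internal branches); `my_to_cu()` provides the scalar conversion used to
  graft clock-based terminal lengths when needed.
* The greedy removal index is an upper bound; certifying the true minimum
  would require search over all removal subsets.
* The hill climb matches the exact optimum on essentially all small
  instances tested, but like any heuristic carries no global guarantee;
  exhaustive mode is capped at 9 taxa (135,135 topologies).
* Fitch machinery assumes binary trees (a degree-2 or degree-3 root is
  handled); multifurcating inputs should be resolved first.
* With heavily incomplete loci the around-branch clusters may be sampled
  by few characters; EN is reported precisely so that short-branch
  lengths and posteriors can be read with appropriate suspicion.
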