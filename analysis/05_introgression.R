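#!/usr/bin/env Rscript
# Step 5: introgression tests.  RI characters are simulated on a
# one-reticulation network (admixture fraction gamma = 0.3 between two
# non-sister lineages); the quartet asymmetry binomial test and the
# triplet likelihood-ratio test are then asked to recover the signal,
# with a matched gamma = 0 simulation as the negative control.

suppressPackageStartupMessages(library(retroquartet))
dir.create("results", showWarnings = FALSE)

# 5-taxon ultrametric tree: ((A,B),(C,D)) radiation plus outgroup E
tr <- ape::read.tree(text = paste0(
  "(((A:1,B:1):0.2,(C:1,D:1):0.2):2,E:3.2);"))
sptree <- ape::read.tree(text = "(((A,B),(C,D)),E);")
retic <- list(donor = "C", recipient = "B", time = 0.5, gamma = 0.3)

for (scenario in c("msc", "introgression")) {
  cfg <- sim_config(tr, n_characters = 1500L, seed = 60000L +
                      (scenario == "introgression"),
                    informative_only = TRUE,
                    reticulation = if (scenario == "introgression") retic)
  sim <- simulate_ri_matrix(cfg)
  qa <- all_quartet_asymmetry(sim$matrix, tr$tip.label, sptree,
                              correction = "none")
  write.table(qa, sprintf("results/quartet_asymmetry_%s.tsv", scenario),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] most skewed quartet: %s (p = %.4g)\n", scenario,
              qa$taxa[which.min(qa$p)], min(qa$p, na.rm = TRUE)))

  tc <- triplet_counts(sim$matrix, c("A", "B", "C"))
  lrt <- triplet_lrt(tc)
  cat(sprintf(
    "[%s] triplet A/B/C counts %s: t_hat=%.3f gamma_hat=%.2f p(hyb vs tree)=%.4g\n",
    scenario, paste(tc$n, collapse = "/"), lrt$t_hat, lrt$gamma_hat,
    lrt$p_hyb_vs_tree))
  capture.output(print(lrt),
                 file = sprintf("results/triplet_lrt_%s.txt", scenario))
}
cat("Introgression tables written under results/\n")
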