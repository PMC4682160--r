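#!/usr/bin/env Rscript
# Species-accumulation curves for every taxon: 999 permutations of plot
# sampling order, cross-checked against the analytic (hypergeometric)
# expectation, and written as one long table.
suppressMessages(library(scalediv))

study <- load_study("results/synthetic_study")
seed <- 20151210

curves <- lapply(names(study$matrices), function(nm) {
  cm <- study$matrices[[nm]]
  perm <- accumulate_permutation(cm, n_permutations = 999, seed = seed)
  exact <- accumulate_exact(cm)
  mc_gap <- max(abs(perm$mean_richness - exact$mean_richness))
  cat(sprintf("%-16s richness %5.1f -> %6.1f  (perm vs exact gap %.3f)\n",
              nm, perm$mean_richness[1], max(perm$mean_richness), mc_gap))
  cbind(taxon = nm, as.data.frame(perm),
        exact_richness = exact$mean_richness)
})

dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, curves), "results/accumulation_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/accumulation_curves.tsv\n")
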