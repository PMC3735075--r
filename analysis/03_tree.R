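#!/usr/bin/env Rscript
# Neighbor-Joining tree of the barcodes with nonparametric bootstrap
# support on its bipartitions.

library(motubar)
aln <- read_fasta("results/data/barcodes.fasta")

tree <- bootstrap_support(aln, B = 1000, seed = 101)
write_newick(tree, "results/nj_tree.nwk")

sup <- attr(tree, "support")
sup <- sup[!is.na(sup)]
cat(sprintf(
  "NJ tree over %d tips; %d of %d scored bipartitions have bootstrap support >= 95%%\n",
  length(tree$tip.label), sum(sup >= 95), length(sup)
))
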