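#!/usr/bin/env Rscript
# Identity-based species naming of MOTUs against the local synthetic
# reference library, at the 95% identity rule.

library(motubar)

aln <- read_fasta("results/data/barcodes.fasta")
dm <- distance_matrix(aln)
tree <- read_newick("results/nj_tree.nwk")
motus <- tree_guided_motus(tree, dm, 2)
ref <- read_fasta("results/data/reference_synthetic.fasta",
                  label_pattern = NULL)

named <- assign_names(motus, aln, ref, min_identity = 95)
utils::write.csv(named, "results/motu_names.csv", row.names = FALSE)

n_named <- sum(named$name != "unidentified")
cat(sprintf(
  "%d of %d MOTUs named at >= 95%% identity; best identities of the rest span %.0f-%.0f%%\n",
  n_named, nrow(named),
  min(named$best_identity[named$name == "unidentified"]),
  max(named$best_identity[named$name == "unidentified"])
))
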