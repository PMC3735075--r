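# motubar

Species delimitation from DNA barcodes, and its congruence with
morphology, as a reproducible R workflow.

Biodiversity inventories of hyperdiverse groups (the motivating case is
litter ants, genus *Pheidole*) often sort specimens two ways: into
**morphospecies** from measured characters, and into **MOTUs**
(molecular operational taxonomic units) from a mitochondrial CO1 barcode
fragment. `motubar` implements the molecular route end to end and scores
how well the two routes agree:

* **K2P distances** — pairwise Kimura two-parameter divergences
  `d = -1/2 · ln[(1 − 2P − Q)·√(1 − 2Q)]` with pairwise deletion of
  `N`/gap sites, plus composition tables by codon position and the
  pairwise-distance histogram (the "barcoding gap").
* **Neighbor-Joining tree** with column-resampling bootstrap supports;
  deterministic tie-breaking, optional outgroup rooting.
* **Tree-guided MOTU delineation** — least inclusive subtrees whose mean
  internal divergence is at or below a threshold (2% and 3% by default),
  with an average-linkage threshold clustering as tree-free cross-check.
* **Congruence scoring** — strict set-equality matching of MOTUs against
  morphospecies, with merges and splits classified and annotated by
  their divergences.
* **Reference naming** — best percent identity against a local FASTA of
  named barcodes, assigning a name at ≥ 95% identity.
* **Morphometrics** — standardization (mean 0, variance 1) of 16 worker
  measurements and average-linkage clustering into morphospecies.
* **A calibrated simulator** — two-level star phylogenies under an
  HKY-style substitution process with fixed substitution load, so every
  stage is testable against known truth without any downloads.

## Worked example

```r
library(motubar)

scen  <- paper_scale_scenario(seed = 101)   # 47 specimens, 20 species, 636 bp
dm    <- distance_matrix(scen$alignment)
tree  <- nj_tree(dm)
motus <- tree_guided_motus(tree, dm, threshold = 2)
motus
#> motu_result: 20 MOTUs at 2% threshold (5 singletons)
#>   mean within 1.89%, mean between 20.08%, ratio 10.6
match_success(motus, scen$truth$partition)
#> congruence_report: 20 of 20 MOTUs match a morphospecies (100% match success)
#>   morphospecies: 20; merged MOTUs: none; split morphospecies: none
```

The 20 MOTUs recover the generating species exactly at both the 2% and
3% thresholds; conspecific specimens differ by ~1.9% on average while
heterospecific ones differ by ~20% — an 11-fold separation that is what
makes threshold delimitation work.

## The analysis workflow

Numbered drivers under `analysis/` run the study-scale analysis and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic barcodes + morphometrics
Rscript analysis/02_distances.R    # K2P matrix, composition, histogram
Rscript analysis/03_tree.R         # NJ + 1,000 bootstrap replicates
Rscript analysis/04_motu.R         # MOTUs at 2%/3%, threshold sweep
Rscript analysis/05_congruence.R   # morphospecies, congruence, discordance
Rscript analysis/06_naming.R       # reference-library naming
```

`run_pipeline()` performs the same stages in one call on any aligned
FASTA (plus optional metadata, reference and morphometric files).

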