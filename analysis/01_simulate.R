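#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-group ceRNA study.
#
# Emulates the design the pipeline targets: 8 control vs 8 case samples,
# log2-scale expression for 400 mRNAs / 150 lncRNAs / 200 miRNAs,
# planted |log2FC| = 1.5 effects, and 10 planted ceRNA triads whose
# mRNA-lncRNA pairs share 4 DE miRNAs (pairing scores >= 0.8) and a
# latent factor inducing positive co-expression.

suppressMessages(library(ceRNAnet))

cfg <- synthetic_config(seed = 101)
ds <- generate(cfg)
print(ds)

paths <- write_synthetic_dataset(ds, "results/synthetic")
cat("wrote", length(paths), "files under results/synthetic/\n")
cat(sprintf("planted: %d DE mRNAs, %d DE lncRNAs, %d DE miRNAs, %d triads\n",
            nrow(ds$truth$de$mRNA), nrow(ds$truth$de$lncRNA),
            nrow(ds$truth$de$miRNA), nrow(ds$truth$triads)))
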