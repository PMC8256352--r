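#!/usr/bin/env Rscript
# Stage 3: triple-network assembly and ceRNA-pair calling.
#
# DE miRNAs bridge DE mRNAs and DE lncRNAs through score-filtered
# (>= 0.8) target predictions; candidate pairs must be positively
# co-expressed (Pearson r > 0.4) and are then tested for shared-miRNA
# significance. Pairs are called at BH q < 0.05 (the raw-p gate of the
# original procedure is also reported); called pairs are expanded into
# one triple per shared miRNA and exported as SIF + GraphML.

suppressMessages(library(ceRNAnet))

design <- read.delim("results/synthetic/design.tsv")
em_m <- read_expression_matrix("results/synthetic/expr_mrna.tsv", "mRNA", design, -Inf)
em_l <- read_expression_matrix("results/synthetic/expr_lncrna.tsv", "lncRNA", design, -Inf)
it_m <- read_interaction_table("results/synthetic/targets_mrna.tsv", "mRNA")
it_l <- read_interaction_table("results/synthetic/targets_lncrna.tsv", "lncRNA")

de_m <- read_de_table("results/de_mrna.tsv")
de_l <- read_de_table("results/de_lncrna.tsv")
de_i <- read_de_table("results/de_mirna.tsv")

params <- cerna_params(adjust_pairs = TRUE)
tn <- build_triple_network(de_i$gene[de_i$is_de], it_m, it_l, params)
print(tn)

cand <- expand.grid(
  mrna = intersect(de_m$gene[de_m$is_de],
                   tn$edges$target[tn$edges$target_class == "mRNA"]),
  lncrna = intersect(de_l$gene[de_l$is_de],
                     tn$edges$target[tn$edges$target_class == "lncRNA"]),
  stringsAsFactors = FALSE)
corr <- pearson_filter(cand, em_m, em_l, params$r_threshold)
net <- call_cerna_pairs(tn, corr, params)
cat(sprintf("%d candidates -> %d pass r > %.1f -> %d called pairs, %d triples (BH q < %.2f)\n",
            nrow(cand), nrow(corr), params$r_threshold,
            sum(net$pairs$called), nrow(net$triples), params$p_threshold))
cat(sprintf("raw p < 0.05 would call %d pairs\n",
            sum(net$pairs$x >= 1 & net$pairs$p < 0.05)))

write_cerna_tables(net, "results/cerna_pairs.tsv", "results/cerna_triples.tsv")
export_network(net, "results/cerna_network.sif", "sif")
export_network(net, "results/cerna_network.graphml", "graphml")

# recovery against the planted triads
truth <- read.delim("results/synthetic/truth_triads.tsv")
got <- net$pairs[net$pairs$called, ]
tp <- sum(paste(got$mrna, got$lncrna) %in% paste(truth$mrna, truth$lncrna))
cat(sprintf("planted-pair recovery: precision %.2f (%d/%d), recall %.2f (%d/%d)\n",
            tp / nrow(got), tp, nrow(got), tp / nrow(truth), tp, nrow(truth)))
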