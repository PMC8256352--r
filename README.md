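# ceRNAnet

Inference and topological assessment of competing endogenous RNA
(ceRNA) networks in R.

Transcripts that share miRNA binding sites compete for a finite miRNA
pool: when an mRNA and a lncRNA are regulated by the same miRNAs, the
lncRNA can act as a sponge that de-represses the mRNA, which predicts
positive co-expression of the pair. ceRNAnet is for analysts who have
two-group expression screens of mRNAs, lncRNAs and miRNAs plus scored
miRNA→target prediction tables, and want a tested, reproducible path
from those inputs to a called ceRNA network with a quantitative
assessment of whether that network is biologically organised.

## Method

The pipeline implements, end to end:

1. **Differential expression** per RNA class: two-sample t on log2
   expression, calls at |log2FC| ≥ 1 and p < 0.05 (BH q reported, and
   available as the gate).
2. **Triple network**: DE miRNAs bridge DE mRNAs and DE lncRNAs
   through prediction edges with pairing score ≥ 0.8.
3. **ceRNA calling**: candidate (mRNA, lncRNA) pairs must be
   positively co-expressed (Pearson r > 0.4) and have a significant
   shared-miRNA overlap under the hypergeometric test

   ```
   P(X ≥ x) = 1 − Σ_{t=0}^{x−1} C(K,t) C(M−K, N−t) / C(M,N)
   ```

   with K, N the miRNA regulator counts of the mRNA and lncRNA, M the
   miRNA universe and x the shared count. Called pairs expand into one
   mRNA–miRNA–lncRNA triple per shared miRNA.
4. **Topology fitness**: node degree, topological coefficient,
   closeness and betweenness on the (undirected, simple, tripartite)
   network, each series fitted with y = a·x^b by log–log least squares;
   the four R² values summarise how power-law-like the network is.
5. **Enrichment**: hypergeometric over-representation against GMT gene
   sets, and a targeted GSEA (rank genes by correlation with a hub
   gene, weighted Kolmogorov–Smirnov enrichment score, gene-label
   permutation null).

A seeded synthetic-data generator plants DE effects and ceRNA triads
with known truth so every stage is testable without downloads, and the
package ships a transcribed, published 99-triple reference network
(27 mRNAs, 15 lncRNAs, 25 miRNAs) as a fixed test article for the
topology stage. See the methods vignette
(`vignettes/cerna-network-inference.Rmd`) for models, conventions and
design rationale.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a
thin driver over package functions and writes its tables under
`results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_cerna_network.R
Rscript analysis/04_topology.R
Rscript analysis/05_enrichment.R
```

Stage 3 prints, for the default simulated study (seed 101):

```
TripleNetwork: 286 edges, 47 miRNAs (45 bridging both classes), M universe 200
338 candidates -> 177 pass r > 0.4 -> 9 called pairs, 35 triples (BH q < 0.05)
raw p < 0.05 would call 22 pairs
planted-pair recovery: precision 1.00 (9/9), recall 0.90 (9/10)
```

i.e. of 338 DE mRNA × DE lncRNA candidates, 177 are positively
co-expressed, 9 survive the shared-miRNA test at BH q < 0.05 — all 9
are planted truth, and 9 of the 10 planted pairs are recovered (the
10th lost a member at the fold-change gate). Stage 4 then validates the
packaged reference network:

```
reference-network composition: 27 mRNAs, 15 lncRNAs, 25 miRNAs, 99 triples [ok]
  degree_distribution      R2 = 0.827 (reference 0.827, |delta| = 0.000)
  topological_coefficient  R2 = 0.936 (reference 0.936, |delta| = 0.000)
  closeness                R2 = 0.690 (reference 0.690, |delta| = 0.000)
  betweenness              R2 = 0.688 (reference 0.688, |delta| = 0.000)
```

The four R² values computed under the package's default per-node
fitting convention agree with the values published for this network to
three decimals.

Equivalent in code:

```r
library(ceRNAnet)
net <- load_table2_fixture()
fitness_report(net)$fits
validate_against_fixture()
```

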