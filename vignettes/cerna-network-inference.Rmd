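---
title: "Inferring and assessing competing endogenous RNA networks"
author: "ceRNAnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and assessing competing endogenous RNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Competing endogenous RNAs (ceRNAs) are transcripts — protein-coding
mRNAs and long non-coding RNAs — that regulate each other indirectly by
competing for a shared pool of miRNA binding. When an mRNA and a lncRNA
are bound by the same miRNAs, increased abundance of one sequesters
those miRNAs and de-represses the other, which predicts *positive*
co-expression of the pair. ceRNAnet infers such mRNA–lncRNA ceRNA pairs
from three differential-expression screens (mRNA, lncRNA, miRNA) plus
scored miRNA→target prediction tables, and then asks whether the
resulting network looks like a biologically organised (scale-free-like)
network rather than noise.

The pipeline has five stages, each backed by package functions and
driven by the numbered scripts under `analysis/`:

1. **simulate** — a seeded synthetic study with planted ground truth
   (`generate()`);
2. **de** — per-class two-group screening (`differential_expression()`);
3. **cerna** — triple-network assembly, co-expression gating and
   shared-miRNA testing (`build_triple_network()`, `pearson_filter()`,
   `call_cerna_pairs()`);
4. **topology** — fitness assessment by power-law fits
   (`fitness_report()`, `validate_against_fixture()`);
5. **enrich** — hub-gene validation by ORA and a targeted GSEA
   statistic (`ora_collection()`, `gsea_es()`, `gsea_permutation_p()`).

## Differential-expression screen

Expression is modelled on the log2 scale. For each gene the screen
computes `log2FC = mean(case) − mean(control)`, a two-sample t
statistic (pooled-variance by default, Welch optional), a two-sided
p-value and a Benjamini–Hochberg q-value. A gene is called
differentially expressed when `|log2FC| ≥ 1` **and** `p < 0.05`; the
q-value gate is available via `use_adjusted`. The defaults deliberately
mirror the common screening convention for this kind of two-group
design; a moderated (empirical-Bayes) t is intentionally *not*
implemented — the embodied method is the pair of gates, and the plain
t-test keeps the screen self-contained and exactly testable against
`stats::t.test()`. Genome-scale DE counts obtained with moderated
statistics are therefore not expected to be reproduced.

Zero within-group variance would give an infinite t; instead the pooled
variance is floored at `var_floor = 1e-8` (configurable), which turns a
degenerate gene into a very large but finite statistic.

## Triple network and ceRNA calling

DE miRNAs act as bridges. Both interaction tables are restricted to DE
miRNAs and to edges with pairing score ≥ 0.8 (the high-confidence
cutoff of sequence-based target predictors whose output format the
package consumes). miRNAs retaining targets in both classes are the
*bridge* set; only they can mediate a ceRNA pair.

Candidate (mRNA, lncRNA) pairs must first pass the co-expression gate:
sample Pearson correlation `r > 0.4`, **signed**, because ceRNA
competition predicts positive co-regulation. (An `use_abs_r` flag
exists for exploratory use.) The gate is applied before the overlap
test; the stage order is configurable but filtering first is both
cheaper and the natural reading of the procedure.

The overlap statistic is the shared-miRNA hypergeometric test. With
`M` miRNAs in the genome, `K` regulating the mRNA, `N` regulating the
lncRNA and `x` shared, the p-value is the upper tail

```
P = P(X >= x) = 1 - sum_{t=0}^{x-1} C(K,t) C(M-K, N-t) / C(M,N).
```

Two conventions are implemented. The default `upper_inclusive` is the
form above. The `as_printed` variant sums `t = 0..x` (strict
`P(X > x)`); it is provided because the equation is sometimes typeset
that way, but it assigns `p < 1` to a zero overlap, which cannot be the
intended test, so it is not the default. Probabilities are accumulated
with log-gamma arithmetic (`lchoose` plus log-sum-exp), which is exact
to ~1e-12 against integer enumeration on small instances and stable for
`M` up to at least 1e5.

`M` defaults to the number of distinct miRNAs across both supplied
interaction tables (`total_mirnas_in_tables`): the "genome" is whatever
universe the predictions were drawn from. A `user_supplied` policy
exists for profiled-genome sizes (e.g. the ~1000 miRNAs of a
genome-wide screen). Note the test's small-sample pathology: for
`x = 1, K = 1` the p-value is `N/M`, so single chance overlaps can be
nominally significant. Raw `p < 0.05` per pair is the default (matching
the original procedure, which applies no multiplicity correction here);
`adjust_pairs = TRUE` gates on BH q across all tested pairs and is what
the recovery analyses use, precisely because it suppresses those
single-overlap calls.

Called pairs are expanded into one (mRNA, miRNA, lncRNA) triple per
shared miRNA; the expansion is lossless and the pair list can be
rebuilt from the triples exactly.

## Topology fitness

The network graph is undirected and simple; regulatory direction is a
presentation detail, not a topological one, matching how network
analysis tools treat such graphs. Four node-level quantities are
computed:

- **degree** `k`;
- **topological coefficient** `T(n) = mean_m J(n,m) / k(n)` over all
  nodes `m ≠ n` sharing at least one neighbour with `n`, where `J` is
  the shared-neighbour count plus 1 if `n` and `m` are adjacent; nodes
  with `k ≤ 1` take the value 0 and are excluded from fits;
- **closeness** = reachable count / sum of distances (component-local,
  0 for isolated nodes);
- **betweenness**, exact and normalised by `(V−1)(V−2)/2`.

Degree and closeness/betweenness use igraph's machinery; the
topological coefficient is computed from the adjacency matrix directly
(no igraph equivalent exists). All three centralities are verified in
the test suite against independently written oracles — Floyd–Warshall
distances, shortest-path counting by adjacency-matrix powers, and naive
neighbour-set enumeration — on hundreds of random small graphs.

Each series is fitted with `y = a·x^b` by ordinary least squares on
`(log10 x, log10 y)`; R² is the coefficient of determination in log
space, where the fit is performed. Non-positive values cannot be
log-transformed and are dropped (zero topological coefficients are the
`k ≤ 1` convention values; zero betweenness is common for leaves).

**Fitting convention.** The degree series is by definition aggregated:
`P(k)` (node count per degree) versus `k`. For the three centrality
metrics two modes exist: fitting the raw node-level scatter
(metric versus the node's degree; mode `"per_node"`, the default) or
averaging the metric per degree first (`"per_degree"`). The per-node
mode is the default because it is what interactive network-analysis
plugins actually fit when they display a node-level scatter with a
fitted curve, and because the packaged reference network reproduces its
published fit quality (R² 0.827 / 0.936 / 0.690 / 0.688) essentially
exactly under this convention — `validate_against_fixture()` computes
both modes side by side, so the choice is inspectable rather than
hidden.

The packaged reference network itself is a transcribed, published table
of 99 mRNA–miRNA–lncRNA triples (27 mRNAs, 15 lncRNAs, 25 miRNAs) from
a Parkinson's disease differential-expression study; it serves as a
fixed, real-shaped test article for the topology stage.

## Enrichment

Over-representation uses the same hypergeometric kernel: upper-tail
overlap of a hit list with each GMT set inside a finite universe, BH
across sets. The targeted GSEA statistic ranks all genes by Pearson
correlation with a chosen hub gene (descending, ties broken by id) and
walks the classical weighted Kolmogorov–Smirnov running sum: increments
`|metric|^p / Σ_set |metric|^p` at members, decrements
`1/(n − n_set)` elsewhere; the enrichment score is the extremum of the
running sum, with the positive extremum taken on (numerical) ties. At
`weight_p = 0` this is the classical KS statistic and reversing the
list negates the score. The null is gene-label permutation with
`p = (1 + #{|ES*| ≥ |ES|}) / (1 + n_perm)`, deterministic under a
seed; phenotype permutation is impossible for a correlation ranking
without raw per-sample phenotypes, and the label null is the standard
fallback for single-gene rankings. The ranking metric, weight and null
are method choices, not facts inherited from any particular study.

The two packaged GMT sets (`sphingolipid_metabolism`,
`glutathione_metabolism`) have *synthetic* membership — they exist so
the enrichment stage has a runnable demonstration, and their file name
says so.

## The synthetic generator

`generate()` produces the conditions the pipeline assumes:

| parameter | default | meaning |
|---|---|---|
| `n_control`, `n_case` | 8, 8 | samples per group |
| `n_mrna`, `n_lncrna`, `n_mirna` | 400, 150, 200 | genome sizes |
| `n_de_*` | 60, 25, 50 | planted DE genes per class |
| `effect_size` | 1.5 | planted \|log2FC\| |
| `noise_sd` | 0.5 | per-observation log2 noise |
| `n_planted_triads` | 10 | planted ceRNA pairs |
| `shared_pool_size` | 4 | shared DE miRNAs per pair (disjoint pools) |
| `background_edge_prob` | 0.02 | density of random interactions |
| `latent_weight` | 0.5 | shared latent-factor loading |

Expression is `baseline + group effect + latent + noise`, all Gaussian
on the log2 scale: the screening model is a log-scale linear model, so
the generator plants exactly the structure the screen assumes;
count-level (negative-binomial) noise is out of scope. Each planted
pair shares a per-sample latent factor — the simplest mechanism that
produces the positive co-expression the ceRNA hypothesis predicts
without simulating titration kinetics — and its two members get the
same effect direction, since opposite shifts would fight the
correlation the pair is supposed to show. With `latent_weight = 0.5`
and `noise_sd = 0.5`, the aligned group effect plus latent factor gives
planted pairs an expected correlation near 0.76, well above the 0.4
gate, while keeping within-group variance low enough that the
`|log2FC| ≥ 1` gate remains reachable at effect 1.5.

Two deliberate design points. First, triad miRNA pools are **disjoint**:
if pools overlapped, cross-triad pairs would genuinely share planted
regulators and the "truth" would be ambiguous; disjointness makes
precision/recall well defined (hence `n_planted_triads ·
shared_pool_size ≤ n_de_mirna` is enforced). Second, background edges
are independent Bernoulli draws with scores uniform on [0.5, 1], so
roughly 40% survive the 0.8 score cut — enough to exercise every filter
without drowning the planted signal.

All randomness flows from one root seed through R's default generator;
identical seeds give byte-identical datasets, which the manifest
checksums of `run_pipeline()` verify end to end.

What the generator does **not** emulate: microarray probe effects,
batch or platform heterogeneity (e.g. tissue vs cell-line profiles in
the same study), count-level mean–variance coupling, and realistic
miRNA-family target correlation. Passing recovery tests therefore shows
the pipeline is correct under its own model assumptions, not that those
assumptions hold for any particular real dataset.

## Numerical and convention choices

- Abundance floor: "low abundance" is interpreted as mean log2
  expression below `log2(4) = 2`, configurable; filtering is
  idempotent. Duplicate gene ids keep the row with the larger mean
  (first occurrence on ties).
- Hypergeometric tail: inclusive upper tail by default (see above).
- Variance floor `1e-8` for degenerate t denominators.
- Power-law fits need ≥ 3 positive points; a series that cannot be
  fitted is reported as an NA row, not an error for the whole report.
- Exactly constant series fit with slope 0 and R² 1 (zero residuals).
- GSEA extremum ties resolve to the positive deviation within a 1e-9
  relative tolerance, so results do not depend on floating-point
  accumulation order.
- Null calibration: the DE screen's raw p-values are uniform under the
  null, so the p < 0.05 rate is compared two-sidedly to 0.05; the
  shared-miRNA test is discrete, so its rejection rate is compared to
  its exact attainable level at the 0.05 gate (computed by integer
  enumeration), which is below nominal by construction.

## Problem sizes

The test suite and analysis scripts run at desk scale by choice: the
synthetic default of 400/150/200 genes × 16 samples with 10 planted
triads; oracle equivalence sweeps over all hypergeometric instances
with `M ≤ 25` and 200 random graphs of ≤ 8 nodes; recovery at five
fixed seeds; 100–1000 permutations for GSEA nulls. These sizes make
every quantity exactly checkable while exercising the same code paths
a genome-scale run would use.

## Known limitations

- The moderated-t substitution means published genome-scale DE counts
  from empirical-Bayes screens will not be numerically reproduced.
- The shared-miRNA test is anti-conservative for tiny regulator sets at
  raw p < 0.05 (the `N/M` pathology); use `adjust_pairs = TRUE` when
  precision matters.
- The per-node fitting default reproduces the packaged reference
  values, but other tools may aggregate before fitting; both modes are
  always reported so the comparison is explicit.
- GMT contents are user-supplied; the packaged sets are synthetic
  demonstrations, and no curated pathway database is bundled.
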