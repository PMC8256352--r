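small_cfg <- function(...) {
  synthetic_config(n_mrna = 150, n_lncrna = 60, n_mirna = 100,
                   n_de_mrna = 30, n_de_lncrna = 12, n_de_mirna = 30,
                   n_planted_triads = 6, ...)
}

test_that("identical seeds give identical datasets, different seeds differ", {
  d1 <- generate(small_cfg(seed = 42))
  d2 <- generate(small_cfg(seed = 42))
  expect_identical(d1, d2)
  d3 <- generate(small_cfg(seed = 43))
  expect_false(identical(d1$mrna$values, d3$mrna$values))

  dir1 <- file.path(tempdir(), "ds_a"); dir2 <- file.path(tempdir(), "ds_b")
  write_synthetic_dataset(d1, dir1); write_synthetic_dataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
})

test_that("truth references only ids present in the data", {
  ds <- generate(small_cfg(seed = 2))
  expect_true(all(ds$truth$de$mRNA$gene %in% rownames(ds$mrna$values)))
  expect_true(all(ds$truth$de$lncRNA$gene %in% rownames(ds$lncrna$values)))
  expect_true(all(ds$truth$triads$mrna %in% rownames(ds$mrna$values)))
  pools <- unlist(strsplit(ds$truth$triads$shared_mirnas, ";"))
  expect_true(all(pools %in% rownames(ds$mirna$values)))
  # planted edges present with scores >= 0.8
  for (i in seq_len(nrow(ds$truth$triads))) {
    pool <- strsplit(ds$truth$triads$shared_mirnas[i], ";")[[1]]
    e <- ds$mrna_targets[ds$mrna_targets$target == ds$truth$triads$mrna[i] &
                           ds$mrna_targets$mirna %in% pool, ]
    expect_equal(nrow(e), length(pool))
    expect_true(all(e$score >= 0.8))
  }
  # disjoint pools across triads
  expect_false(anyDuplicated(pools) > 0)
})

test_that("round-tripping a dataset through TSV preserves the matrices", {
  ds <- generate(small_cfg(seed = 12))
  dir <- file.path(tempdir(), "ds_rt")
  write_synthetic_dataset(ds, dir)
  design <- utils::read.delim(file.path(dir, "design.tsv"))
  em <- read_expression_matrix(file.path(dir, "expr_mrna.tsv"), "mRNA", design,
                               abundance_floor = -Inf)
  expect_equal(dim(em), dim(ds$mrna))
  expect_equal(em$values, ds$mrna$values, tolerance = 1e-10)
  it <- read_interaction_table(file.path(dir, "targets_mrna.tsv"), "mRNA")
  expect_equal(nrow(it), nrow(ds$mrna_targets))
})

test_that("null configuration is calibrated: ~5% of genes reach p < 0.05", {
  hits <- 0; total <- 0
  for (seed in 1:6) {
    ds <- generate(synthetic_config(effect_size = 0, n_planted_triads = 0,
                                    seed = seed))
    for (cls in c("mrna", "lncrna", "mirna")) {
      det <- differential_expression(ds[[cls]])
      hits <- hits + sum(det$p < 0.05)
      total <- total + nrow(det)
    }
  }
  rate <- hits / total
  ci <- 2.576 * sqrt(0.05 * 0.95 / total)
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)
})

test_that("planted pairs are positively correlated above the 0.4 gate", {
  # Monte-Carlo over seeded replicates: every planted pair should clear
  # the correlation gate in the vast majority of replicates
  ok <- 0; n_rep <- 25
  for (seed in seq_len(n_rep)) {
    ds <- generate(small_cfg(seed = seed))
    corr <- pearson_filter(ds$truth$triads[c("mrna", "lncrna")],
                           ds$mrna, ds$lncrna, r_threshold = -2)
    ok <- ok + all(corr$r > 0.4)
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("recovery improves with stronger planted structure", {
  recall_at <- function(pool, lw, seed = 3) {
    ds <- generate(synthetic_config(shared_pool_size = pool, latent_weight = lw,
                                    seed = seed))
    det <- list(m = differential_expression(ds$mrna),
                l = differential_expression(ds$lncrna),
                i = differential_expression(ds$mirna))
    params <- cerna_params(adjust_pairs = TRUE)
    tn <- build_triple_network(det$i$gene[det$i$is_de],
                               ds$mrna_targets, ds$lncrna_targets, params)
    cand <- expand.grid(
      mrna = intersect(det$m$gene[det$m$is_de],
                       tn$edges$target[tn$edges$target_class == "mRNA"]),
      lncrna = intersect(det$l$gene[det$l$is_de],
                         tn$edges$target[tn$edges$target_class == "lncRNA"]),
      stringsAsFactors = FALSE)
    corr <- pearson_filter(cand, ds$mrna, ds$lncrna)
    truth_recovery_report(ds, call_cerna_pairs(tn, corr, params))$recall
  }
  expect_gte(recall_at(4, 0.5), recall_at(2, 0.5) - 0.1)
  expect_gte(recall_at(4, 0.8), 0.6)
})

test_that("degenerate truth-recovery inputs are flagged", {
  ds <- generate(small_cfg(seed = 1))
  empty <- cerna_network(data.frame(mrna = character(0), mirna = character(0),
                                    lncrna = character(0)))
  rec <- truth_recovery_report(ds, empty)
  expect_true(rec$no_calls)
  expect_equal(rec$precision, 0)
  expect_equal(rec$recall, 0)

  perfect <- cerna_network(data.frame(
    mrna = ds$truth$triads$mrna[1], mirna = "miR_9999",
    lncrna = ds$truth$triads$lncrna[1]))
  expect_error(truth_recovery_report(ds, perfect), NA)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(shared_pool_size = 300), "infeasible")
  expect_error(synthetic_config(n_planted_triads = 40, n_de_lncrna = 20),
               "infeasible")
  expect_error(synthetic_config(n_de_mrna = 1000), "genome size")
})
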