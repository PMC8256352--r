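toy_tables <- function(mrna_rows, lncrna_rows) {
  list(m = interaction_table(mrna_rows, "mRNA"),
       l = interaction_table(lncrna_rows, "lncRNA"))
}

test_that("triple network applies the score filter and flags bridge miRNAs", {
  tabs <- toy_tables(data.frame(mirna = "mir1", target = "m1", score = 0.9),
                     data.frame(mirna = "mir1", target = "l1", score = 0.85))
  tn <- build_triple_network("mir1", tabs$m, tabs$l)
  expect_equal(nrow(tn$edges), 2)
  expect_equal(length(unique(c(tn$edges$mirna, tn$edges$target))), 3)
  expect_equal(tn$bridge_mirnas, "mir1")

  tabs2 <- toy_tables(data.frame(mirna = "mir1", target = "m1", score = 0.9),
                      data.frame(mirna = "mir1", target = "l1", score = 0.7))
  tn2 <- build_triple_network("mir1", tabs2$m, tabs2$l)
  expect_equal(nrow(tn2$edges), 1)
  expect_length(tn2$bridge_mirnas, 0)

  expect_error(build_triple_network("mirX", tabs$m, tabs$l), "empty")
  expect_error(build_triple_network(character(0), tabs$m, tabs$l), "non-empty")
})

test_that("every planted triad's edges survive construction from truth tables", {
  ds <- generate(synthetic_config(seed = 4))
  tn <- build_triple_network(ds$truth$de$miRNA$gene, ds$mrna_targets, ds$lncrna_targets)
  for (i in seq_len(nrow(ds$truth$triads))) {
    pool <- strsplit(ds$truth$triads$shared_mirnas[i], ";")[[1]]
    em <- tn$edges[tn$edges$target == ds$truth$triads$mrna[i], ]
    el <- tn$edges[tn$edges$target == ds$truth$triads$lncrna[i], ]
    expect_true(all(pool %in% em$mirna))
    expect_true(all(pool %in% el$mirna))
  }
})

test_that("pearson filter keeps positive co-expression and matches closed form", {
  samples <- paste0("S", 1:4); grp <- c("control", "control", "case", "case")
  me <- toy_matrix(c(1, 2, 3, 4), "m1", samples, grp, "mRNA")
  le <- toy_matrix(c(1, 2, 3, 4,
                     4, 3, 2, 1,
                     1.1, 1.9, 3.2, 3.8), c("copy", "neg", "l1"),
                   samples, grp, "lncRNA")
  pairs <- data.frame(mrna = "m1", lncrna = c("copy", "neg", "l1"))
  out <- pearson_filter(pairs, me, le, r_threshold = 0.4)
  expect_equal(out$lncrna, c("copy", "l1"))
  expect_equal(out$r[out$lncrna == "copy"], 1)
  r_hand <- cor(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(out$r[out$lncrna == "l1"], r_hand, tolerance = 1e-12)

  # negated profile survives under the absolute-value flag
  out_abs <- pearson_filter(pairs, me, le, r_threshold = 0.4, use_abs = TRUE)
  expect_true("neg" %in% out_abs$lncrna)

  flat <- toy_matrix(rep(c(1, 5), c(4, 4)), c("zv", "ok"),
                     samples, grp, "lncRNA")
  expect_warning(
    res <- pearson_filter(data.frame(mrna = "m1", lncrna = "zv"), me, flat),
    "zero-variance")
  expect_equal(nrow(res), 0)
})

test_that("ceRNA calling gates on the hypergeometric p and expands triples losslessly", {
  # toy: M = 10 miRNAs, mRNA regulated by {a, b, c}, lncRNA by {a, b, d}
  mir <- paste0("mir", 1:10)
  m_rows <- data.frame(mirna = c("mir1", "mir2", "mir3", mir),
                       target = c(rep("m1", 3), rep("mX", 10)),
                       score = 0.9)
  l_rows <- data.frame(mirna = c("mir1", "mir2", "mir4", mir),
                       target = c(rep("l1", 3), rep("lX", 10)),
                       score = 0.9)
  tabs <- toy_tables(m_rows, l_rows)
  tn <- build_triple_network(mir, tabs$m, tabs$l)
  expect_equal(tn$n_mirna_universe, 10)
  corr <- data.frame(mrna = "m1", lncrna = "l1", r = 0.9)
  net <- call_cerna_pairs(tn, corr)
  row <- net$pairs[1, ]
  expect_equal(row[, c("x", "K", "N", "M")], data.frame(x = 2L, K = 3L, N = 3L, M = 10L),
               ignore_attr = TRUE)
  p_oracle <- hyper_oracle(3, 3, 10, 2)
  expect_equal(row$p, p_oracle, tolerance = 1e-12)
  expect_equal(row$called, p_oracle < 0.05)
  if (row$called) {
    expect_equal(nrow(net$triples), 2)
    expect_setequal(net$triples$mirna, c("mir1", "mir2"))
  }

  # zero shared miRNAs: never called
  m_rows2 <- data.frame(mirna = "mir1", target = "mA", score = 0.95)
  l_rows2 <- data.frame(mirna = "mir2", target = "lA", score = 0.95)
  tabs2 <- toy_tables(m_rows2, l_rows2)
  tn2 <- build_triple_network(c("mir1", "mir2"), tabs2$m, tabs2$l)
  net2 <- call_cerna_pairs(tn2, data.frame(mrna = "mA", lncrna = "lA", r = 0.8))
  expect_false(any(net2$pairs$called))
  expect_equal(nrow(net2$triples), 0)
})

test_that("triple expansion rebuilds the called pair list exactly", {
  ds <- generate(synthetic_config(seed = 6))
  det <- list(m = differential_expression(ds$mrna),
              l = differential_expression(ds$lncrna),
              i = differential_expression(ds$mirna))
  tn <- build_triple_network(det$i$gene[det$i$is_de], ds$mrna_targets, ds$lncrna_targets)
  cand <- expand.grid(
    mrna = intersect(det$m$gene[det$m$is_de],
                     tn$edges$target[tn$edges$target_class == "mRNA"]),
    lncrna = intersect(det$l$gene[det$l$is_de],
                       tn$edges$target[tn$edges$target_class == "lncRNA"]),
    stringsAsFactors = FALSE)
  corr <- pearson_filter(cand, ds$mrna, ds$lncrna)
  net <- call_cerna_pairs(tn, corr)
  called <- net$pairs[net$pairs$called, ]
  rebuilt <- unique(net$triples[c("mrna", "lncrna")])
  expect_setequal(paste(rebuilt$mrna, rebuilt$lncrna),
                  paste(called$mrna, called$lncrna))
  # shared-miRNA enumeration is lossless
  n_triples <- sum(called$x)
  expect_equal(nrow(net$triples), n_triples)
  # every called pair satisfies all three gates
  expect_true(all(called$x >= 1))
  expect_true(all(called$p < 0.05))
  expect_true(all(called$r > 0.4))
  edge_scores <- tn$edges$score
  expect_true(all(edge_scores >= 0.8))
})
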