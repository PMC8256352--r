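#' Configuration of the synthetic ceRNA study generator
#'
#' Defaults emulate the statistical structure of the two-group brain
#' profiling design the pipeline was built for: eight control and eight
#' case samples, log2-scale Gaussian expression, planted differential
#' effects of |log2FC| 1.5, and planted ceRNA triads whose mRNA-lncRNA
#' pairs share miRNA regulators (pairing scores >= 0.8) and a latent
#' factor that makes them positively co-expressed.
#'
#' @param n_control,n_case Samples per group (default 8 each).
#' @param n_mrna,n_lncrna,n_mirna Genome sizes per RNA class.
#' @param n_de_mrna,n_de_lncrna,n_de_mirna Planted DE genes per class.
#' @param effect_size Planted |log2FC| in cases (default 1.5).
#' @param noise_sd Per-observation Gaussian sd on the log2 scale
#'   (default 0.5).
#' @param n_planted_triads Number of planted mRNA-lncRNA ceRNA pairs
#'   (default 10); their members are drawn from the planted DE sets with
#'   matching effect direction.
#' @param shared_pool_size DE miRNAs shared per planted pair (default 4);
#'   pools are disjoint across triads.
#' @param background_edge_prob Density of random non-planted
#'   miRNA-target interactions (default 0.02); background scores are
#'   uniform on \[0.5, 1\], planted scores uniform on \[0.8, 1\].
#' @param latent_weight Loading of the per-triad latent factor shared by
#'   the pair (default 0.5; together with the aligned group effect and
#'   the default noise this puts the expected planted-pair correlation
#'   near 0.76, comfortably above the 0.4 gate, without drowning the
#'   fold-change gate in extra within-group variance).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 abundance (defaults 7 and 1).
#' @param seed Root integer seed; every random draw flows from it.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_control = 8, n_case = 8,
                             n_mrna = 400, n_lncrna = 150, n_mirna = 200,
                             n_de_mrna = 60, n_de_lncrna = 25, n_de_mirna = 50,
                             effect_size = 1.5, noise_sd = 0.5,
                             n_planted_triads = 10, shared_pool_size = 4,
                             background_edge_prob = 0.02, latent_weight = 0.5,
                             baseline_mean = 7, baseline_sd = 1, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_control, n_case, n_mrna, n_lncrna, n_mirna)
  if (any(counts <= 0)) stop("sample and genome counts must be positive")
  if (n_de_mrna > n_mrna || n_de_lncrna > n_lncrna || n_de_mirna > n_mirna)
    stop("n_de cannot exceed the genome size of its class")
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("background_edge_prob must lie in [0, 1]")
  if (shared_pool_size > n_mirna)
    stop("infeasible config: shared_pool_size exceeds the miRNA genome")
  if (n_planted_triads * shared_pool_size > n_de_mirna)
    stop("infeasible config: planted triads need n_planted_triads * shared_pool_size DE miRNAs (pools are disjoint)")
  if (n_planted_triads > min(n_de_mrna, n_de_lncrna))
    stop("infeasible config: more planted triads than DE mRNAs or lncRNAs")
  if (noise_sd < 0 || effect_size < 0) stop("effect_size and noise_sd must be >= 0")
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a seeded synthetic ceRNA dataset
#'
#' Expression follows
#' `log2 x = baseline(gene) + group effect + latent_weight * z(triad, sample) + N(0, noise_sd)`:
#' planted DE genes shift by +/- `effect_size` in cases, and each planted
#' mRNA-lncRNA pair shares a per-sample latent factor z so the pair is
#' positively correlated. Planted pairs also share `shared_pool_size`
#' DE miRNAs in the interaction tables with pairing scores >= 0.8.
#' Identical seeds give identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `SyntheticDataset`: `mrna`, `lncrna`, `mirna`
#'   ([expression_matrix()]s), `mrna_targets`, `lncrna_targets`
#'   ([interaction_table()]s), `truth` (planted DE tables and triads)
#'   and `config`.
#' @export
generate <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(as.integer(config$seed))
  n_s <- config$n_control + config$n_case
  samples <- sprintf("S%02d", seq_len(n_s))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))

  mrna_ids <- sprintf("mRNA_%04d", seq_len(config$n_mrna))
  lnc_ids  <- sprintf("lnc_%04d", seq_len(config$n_lncrna))
  mir_ids  <- sprintf("miR_%04d", seq_len(config$n_mirna))

  de_mrna <- sample(mrna_ids, config$n_de_mrna)
  de_lnc  <- sample(lnc_ids, config$n_de_lncrna)
  de_mir  <- sample(mir_ids, config$n_de_mirna)
  dir_mrna <- sample(c(1, -1), config$n_de_mrna, replace = TRUE)
  dir_lnc  <- sample(c(1, -1), config$n_de_lncrna, replace = TRUE)
  dir_mir  <- sample(c(1, -1), config$n_de_mirna, replace = TRUE)

  nt <- config$n_planted_triads
  triad_mrna <- de_mrna[seq_len(nt)]
  triad_lnc  <- de_lnc[seq_len(nt)]
  # co-expression of a ceRNA pair is positive: align the lncRNA's
  # planted direction with its partner mRNA's
  dir_lnc[seq_len(nt)] <- dir_mrna[seq_len(nt)]
  # disjoint regulator pools: each planted pair owns its shared miRNAs, so
  # the planted truth is the unique shared-regulator structure
  triad_pools <- if (nt > 0) {
    pool_draw <- sample(de_mir, nt * config$shared_pool_size)
    lapply(split(pool_draw, rep(seq_len(nt), each = config$shared_pool_size)), sort)
  } else list()

  effect_vec <- function(ids, de, dirs) {
    e <- stats::setNames(rep(0, length(ids)), ids)
    e[de] <- dirs * config$effect_size
    e
  }
  latent <- matrix(stats::rnorm(nt * n_s), nrow = max(nt, 1))

  build_matrix <- function(ids, de, dirs, cls, latent_rows = NULL) {
    base <- stats::rnorm(length(ids), config$baseline_mean, config$baseline_sd)
    eff <- effect_vec(ids, de, dirs)
    v <- matrix(base, length(ids), n_s) +
      outer(eff, as.numeric(group == "case")) +
      matrix(stats::rnorm(length(ids) * n_s, 0, config$noise_sd), length(ids))
    rownames(v) <- ids; colnames(v) <- samples
    if (!is.null(latent_rows) && nt > 0)
      for (i in seq_len(nt))
        v[latent_rows[i], ] <- v[latent_rows[i], ] + config$latent_weight * latent[i, ]
    expression_matrix(v, group, cls)
  }
  em_m <- build_matrix(mrna_ids, de_mrna, dir_mrna, "mRNA", triad_mrna)
  em_l <- build_matrix(lnc_ids, de_lnc, dir_lnc, "lncRNA", triad_lnc)
  em_i <- build_matrix(mir_ids, de_mir, dir_mir, "miRNA")

  background_edges <- function(targets) {
    grid <- expand.grid(mirna = mir_ids, target = targets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < config$background_edge_prob
    grid <- grid[keep, , drop = FALSE]
    grid$score <- stats::runif(nrow(grid), 0.5, 1)
    grid
  }
  planted_edges <- function(targets_by_triad) {
    if (nt == 0) return(data.frame(mirna = character(0), target = character(0), score = numeric(0)))
    do.call(rbind, lapply(seq_len(nt), function(i) {
      data.frame(mirna = triad_pools[[i]], target = targets_by_triad[i],
                 score = stats::runif(config$shared_pool_size, 0.8, 1),
                 stringsAsFactors = FALSE)
    }))
  }
  it_m <- interaction_table(rbind(background_edges(mrna_ids), planted_edges(triad_mrna)), "mRNA")
  it_l <- interaction_table(rbind(background_edges(lnc_ids), planted_edges(triad_lnc)), "lncRNA")

  truth <- list(
    de = list(mRNA = data.frame(gene = de_mrna, direction = ifelse(dir_mrna > 0, "up", "down"),
                                stringsAsFactors = FALSE),
              lncRNA = data.frame(gene = de_lnc, direction = ifelse(dir_lnc > 0, "up", "down"),
                                  stringsAsFactors = FALSE),
              miRNA = data.frame(gene = de_mir, direction = ifelse(dir_mir > 0, "up", "down"),
                                 stringsAsFactors = FALSE)),
    triads = if (nt > 0) data.frame(
      mrna = triad_mrna, lncrna = triad_lnc,
      shared_mirnas = vapply(triad_pools, paste, "", collapse = ";"),
      stringsAsFactors = FALSE)
      else data.frame(mrna = character(0), lncrna = character(0), shared_mirnas = character(0)))

  structure(list(mrna = em_m, lncrna = em_l, mirna = em_i,
                 mrna_targets = it_m, lncrna_targets = it_l,
                 truth = truth, config = config),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d mRNA / %d lncRNA / %d miRNA genes x %d samples; %d planted triads (seed %d)\n",
              nrow(x$mrna$values), nrow(x$lncrna$values), nrow(x$mirna$values),
              ncol(x$mrna$values), nrow(x$truth$triads), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits the three expression matrices, the design table, both
#' interaction tables and the truth tables in the same formats the
#' readers consume.
#'
#' @param ds A [generate()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, c("expr_mrna.tsv", "expr_lncrna.tsv", "expr_mirna.tsv",
                        "design.tsv", "targets_mrna.tsv", "targets_lncrna.tsv",
                        "truth_de.tsv", "truth_triads.tsv"))
  write_expression_matrix(ds$mrna, p[1])
  write_expression_matrix(ds$lncrna, p[2])
  write_expression_matrix(ds$mirna, p[3])
  utils::write.table(data.frame(sample = colnames(ds$mrna$values),
                                group = as.character(ds$mrna$group)),
                     p[4], sep = "\t", quote = FALSE, row.names = FALSE)
  write_interaction_table(ds$mrna_targets, p[5])
  write_interaction_table(ds$lncrna_targets, p[6])
  de <- do.call(rbind, lapply(names(ds$truth$de), function(cls)
    cbind(rna_class = cls, ds$truth$de[[cls]])))
  utils::write.table(de, p[7], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$triads, p[8], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Precision and recall of called ceRNA pairs against planted truth
#'
#' @param dataset A [generate()] result with planted triads.
#' @param called A [cerna_network()] produced from that dataset.
#' @return list with `precision`, `recall`, `n_called`, `n_planted`,
#'   `n_true_positive` and `no_calls` (TRUE when nothing was called, in
#'   which case precision is reported as 0).
#' @export
truth_recovery_report <- function(dataset, called) {
  stopifnot(inherits(dataset, "SyntheticDataset"), inherits(called, "CeRNANetwork"))
  cp <- called$pairs
  if ("called" %in% names(cp)) cp <- cp[cp$called, , drop = FALSE]
  known <- c(gene_ids(dataset$mrna), gene_ids(dataset$lncrna))
  if (nrow(cp) && !all(c(cp$mrna, cp$lncrna) %in% known))
    stop("called network names genes absent from the dataset")
  planted <- paste(dataset$truth$triads$mrna, dataset$truth$triads$lncrna)
  got <- paste(cp$mrna, cp$lncrna)
  tp <- sum(got %in% planted)
  no_calls <- length(got) == 0
  list(precision = if (no_calls) 0 else tp / length(got),
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       n_called = length(got), n_planted = length(planted),
       n_true_positive = tp, no_calls = no_calls)
}
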