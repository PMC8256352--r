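#' Parameters for ceRNA network construction
#'
#' @param score_threshold Minimum pairing score for a miRNA-target edge
#'   to enter the triple network (default 0.8).
#' @param r_threshold Minimum mRNA-lncRNA Pearson correlation (default
#'   0.4; signed unless `use_abs_r`).
#' @param p_threshold Significance gate of the shared-miRNA test
#'   (default 0.05, raw p).
#' @param M_policy `"total_mirnas_in_tables"` (default: the genome size M
#'   of the hypergeometric test is the number of distinct miRNAs across
#'   both interaction tables) or `"user_supplied"` (pass `M`).
#' @param M Genome miRNA count when `M_policy = "user_supplied"`.
#' @param tail Tail convention of [shared_mirna_test()].
#' @param use_abs_r Gate on `|r|` instead of signed r (default FALSE:
#'   ceRNA co-regulation predicts positive co-expression).
#' @param adjust_pairs Apply BH across tested pairs and gate on q
#'   (default FALSE: raw p per pair).
#' @return A list of class `CeRNAParams`.
#' @export
cerna_params <- function(score_threshold = 0.8, r_threshold = 0.4,
                         p_threshold = 0.05,
                         M_policy = c("total_mirnas_in_tables", "user_supplied"),
                         M = NULL,
                         tail = c("upper_inclusive", "as_printed"),
                         use_abs_r = FALSE, adjust_pairs = FALSE) {
  M_policy <- match.arg(M_policy)
  tail <- match.arg(tail)
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            r_threshold >= -1, r_threshold <= 1,
            p_threshold > 0, p_threshold <= 1)
  if (M_policy == "user_supplied" && is.null(M))
    stop("M must be given under the user_supplied policy")
  structure(list(score_threshold = score_threshold, r_threshold = r_threshold,
                 p_threshold = p_threshold, M_policy = M_policy, M = M,
                 tail = tail, use_abs_r = use_abs_r, adjust_pairs = adjust_pairs),
            class = "CeRNAParams")
}

#' Build the miRNA-bridged triple network
#'
#' Restricts both interaction tables to differentially expressed miRNAs
#' and to edges at or above the pairing-score threshold, and records the
#' "bridge" miRNAs that retain at least one mRNA and one lncRNA target —
#' only those can mediate a ceRNA pair.
#'
#' @param de_mirnas Character vector of DE miRNA ids.
#' @param mrna_targets [interaction_table()] with `target_class` mRNA.
#' @param lncrna_targets [interaction_table()] with `target_class` lncRNA.
#' @param params [cerna_params()].
#' @return Object of class `TripleNetwork`: list with `edges`
#'   (mirna, target, target_class, score), `mirnas`, `bridge_mirnas`,
#'   and `n_mirna_universe` (distinct miRNAs across the unfiltered input
#'   tables, the default genome size M).
#' @export
build_triple_network <- function(de_mirnas, mrna_targets, lncrna_targets,
                                 params = cerna_params()) {
  if (!length(de_mirnas)) stop("de_mirnas must be non-empty")
  universe <- union(unique(mrna_targets$mirna), unique(lncrna_targets$mirna))
  keep_edges <- function(it, cls) {
    e <- as.data.frame(it)[it$mirna %in% de_mirnas & it$score >= params$score_threshold, , drop = FALSE]
    if (nrow(e)) e$target_class <- cls else e$target_class <- character(0)
    e
  }
  em <- keep_edges(mrna_targets, "mRNA")
  el <- keep_edges(lncrna_targets, "lncRNA")
  edges <- rbind(em, el)
  if (!nrow(edges)) stop("triple network is empty after score/DE filtering")
  rownames(edges) <- NULL
  if (any(edges$mirna == edges$target)) stop("self-loop in interaction tables")
  structure(list(edges = edges,
                 mirnas = unique(edges$mirna),
                 bridge_mirnas = intersect(unique(em$mirna), unique(el$mirna)),
                 n_mirna_universe = length(universe)),
            class = "TripleNetwork")
}

#' @export
print.TripleNetwork <- function(x, ...) {
  cat(sprintf("TripleNetwork: %d edges, %d miRNAs (%d bridging both classes), M universe %d\n",
              nrow(x$edges), length(x$mirnas), length(x$bridge_mirnas),
              x$n_mirna_universe))
  invisible(x)
}

# regulator sets of the triple network, split by target class
regulator_sets <- function(net, target_class) {
  e <- net$edges[net$edges$target_class == target_class, , drop = FALSE]
  split(e$mirna, e$target)
}

#' Co-expression filter for candidate mRNA-lncRNA pairs
#'
#' Computes the sample Pearson correlation of each candidate pair across
#' the samples shared by the two matrices and keeps pairs with
#' `r > r_threshold` (signed; `use_abs` gates on `|r|`). Pairs involving
#' a zero-variance gene are dropped with a warning.
#'
#' @param pairs data.frame with columns `mrna`, `lncrna`.
#' @param mrna_expr,lncrna_expr [expression_matrix()] objects.
#' @param r_threshold Correlation gate, default 0.4.
#' @param use_abs Gate on absolute correlation.
#' @return The surviving rows of `pairs` with an `r` column appended.
#' @export
pearson_filter <- function(pairs, mrna_expr, lncrna_expr, r_threshold = 0.4,
                           use_abs = FALSE) {
  stopifnot(all(c("mrna", "lncrna") %in% names(pairs)))
  shared <- intersect(sample_ids(mrna_expr), sample_ids(lncrna_expr))
  if (length(shared) < 3) stop("need at least 3 shared samples for correlation")
  miss_m <- setdiff(unique(pairs$mrna), gene_ids(mrna_expr))
  miss_l <- setdiff(unique(pairs$lncrna), gene_ids(lncrna_expr))
  if (length(miss_m) || length(miss_l))
    stop("pair gene(s) absent from expression matrices: ",
         paste(c(miss_m, miss_l), collapse = ", "))
  mv <- mrna_expr$values[, shared, drop = FALSE]
  lv <- lncrna_expr$values[, shared, drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- mv[pairs$mrna[i], ]; b <- lv[pairs$lncrna[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(r))
    warning(sum(is.na(r)), " pair(s) dropped for zero-variance genes")
  pairs$r <- r
  stat <- if (use_abs) abs(r) else r
  out <- pairs[!is.na(r) & stat > r_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call ceRNA pairs by the shared-miRNA hypergeometric test
#'
#' For every correlation-surviving (mRNA, lncRNA) candidate, counts the
#' miRNAs shared between the mRNA's and the lncRNA's regulator sets in
#' the triple network and tests the overlap with
#' [shared_mirna_test()]. A pair is called when `x >= 1` and its
#' (optionally BH-adjusted) p-value beats the gate. Each called pair is
#' expanded into one triple per shared miRNA.
#'
#' @param net A [build_triple_network()] result.
#' @param corr Candidate pairs with `r` column, from [pearson_filter()].
#' @param params [cerna_params()].
#' @return Object of class `CeRNANetwork`; see [cerna_network()].
#' @export
call_cerna_pairs <- function(net, corr, params = cerna_params()) {
  stopifnot(inherits(net, "TripleNetwork"))
  M <- switch(params$M_policy,
              total_mirnas_in_tables = net$n_mirna_universe,
              user_supplied = params$M)
  reg_m <- regulator_sets(net, "mRNA")
  reg_l <- regulator_sets(net, "lncRNA")
  rows <- lapply(seq_len(nrow(corr)), function(i) {
    mr <- corr$mrna[i]; ln <- corr$lncrna[i]
    Kset <- unique(reg_m[[mr]]); Nset <- unique(reg_l[[ln]])
    shared <- intersect(Kset, Nset)
    K <- length(Kset); N <- length(Nset); x <- length(shared)
    if (K > M || N > M)
      stop("M (", M, ") smaller than an observed regulator set; check M_policy")
    p <- if (x >= 1) shared_mirna_test(K, N, M, x, tail = params$tail) else 1
    data.frame(mrna = mr, lncrna = ln, x = x, K = K, N = N, M = M,
               p = p, r = corr$r[i],
               shared_mirnas = paste(sort(shared), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(pairs)) pairs <- empty_pairs()
  pairs$q <- bh_adjust(pairs$p)
  gate <- if (params$adjust_pairs) pairs$q else pairs$p
  pairs$called <- pairs$x >= 1 & gate < params$p_threshold
  called <- pairs[pairs$called, , drop = FALSE]
  triples <- if (nrow(called)) {
    do.call(rbind, lapply(seq_len(nrow(called)), function(i) {
      data.frame(mrna = called$mrna[i],
                 mirna = strsplit(called$shared_mirnas[i], ";", fixed = TRUE)[[1]],
                 lncrna = called$lncrna[i], stringsAsFactors = FALSE)
    }))
  } else data.frame(mrna = character(0), mirna = character(0), lncrna = character(0))
  cerna_network(triples, pairs = pairs)
}

empty_pairs <- function() {
  data.frame(mrna = character(0), lncrna = character(0), x = integer(0),
              K = integer(0), N = integer(0), M = integer(0), p = numeric(0),
              r = numeric(0), shared_mirnas = character(0), stringsAsFactors = FALSE)
}
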