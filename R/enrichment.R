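#' Read a GMT gene-set collection
#'
#' Standard tab format: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of class `GeneSetCollection`,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nms <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nms)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  structure(sets, class = "GeneSetCollection",
            descriptions = stats::setNames(vapply(parts, `[`, "", 2), nms))
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail hypergeometric p-value for the overlap between a hit list
#' and a gene set within a finite universe (the same kernel as
#' [shared_mirna_test()]).
#'
#' @param hits Character vector of genes of interest (intersected with
#'   the universe).
#' @param gene_set Character vector of set members (intersected with the
#'   universe).
#' @param universe Character vector, the background.
#' @return One-row data.frame: `overlap`, `set_size`, `n_hits`,
#'   `universe_size`, `p`.
#' @export
ora_test <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- intersect(unique(hits), universe)
  gene_set <- intersect(unique(gene_set), universe)
  x <- length(intersect(hits, gene_set))
  p <- shared_mirna_test(K = length(gene_set), N = length(hits),
                         M = length(universe), x = x)
  data.frame(overlap = x, set_size = length(gene_set), n_hits = length(hits),
             universe_size = length(universe), p = p)
}

#' Over-representation analysis across a collection, BH-adjusted
#'
#' @inheritParams ora_test
#' @param collection A [read_gmt()] collection (or named list of sets).
#' @return data.frame with one row per set: name, overlap, set_size,
#'   n_hits, universe_size, p, q.
#' @export
ora_collection <- function(hits, collection, universe) {
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    cbind(data.frame(set = nm, stringsAsFactors = FALSE),
          ora_test(hits, collection[[nm]], universe))
  }))
  res$q <- bh_adjust(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Rank all genes by correlation with a hub gene
#'
#' Ranking metric for targeted, single-gene GSEA: every other gene in the
#' matrix is ordered by its Pearson correlation with the hub's
#' expression profile, descending. Ties are broken by gene id so the
#' ranking is deterministic.
#'
#' @param hub Gene id present in `em`.
#' @param em An [expression_matrix()] with >= 3 samples.
#' @return data.frame of class `RankedList` with columns `gene`,
#'   `metric`, ordered by decreasing metric.
#' @export
rank_by_correlation <- function(hub, em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!(hub %in% gene_ids(em))) stop("hub gene '", hub, "' not in matrix")
  if (ncol(em$values) < 3) stop("need at least 3 samples")
  prof <- em$values[hub, ]
  if (stats::sd(prof) == 0) stop("hub gene has zero variance")
  others <- setdiff(gene_ids(em), hub)
  r <- as.numeric(stats::cor(t(em$values[others, , drop = FALSE]), prof))
  ok <- is.finite(r)
  out <- data.frame(gene = others[ok], metric = r[ok], stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("RankedList", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom; at set members the running
#' sum gains `|metric|^weight_p / sum_set |metric|^weight_p`, at
#' non-members it loses `1 / (n_total - n_set)`. The enrichment score is
#' the signed extremum of the running sum. `weight_p = 0` recovers the
#' classical (unweighted) KS statistic.
#'
#' @param ranked A [rank_by_correlation()] result, or any data.frame
#'   with `gene` and `metric` ordered by decreasing metric.
#' @param gene_set Character vector of member ids; must overlap the list
#'   and must not cover it entirely.
#' @param weight_p Metric weight exponent, default 1.
#' @return list with `es`, `running_sum` (length = list length),
#'   `hit_positions`, `n_hits`.
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(all(c("gene", "metric") %in% names(ranked)))
  genes <- ranked$gene
  hit <- genes %in% gene_set
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  if (all(hit)) stop("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  rs <- cumsum(inc - dec)
  hi <- max(rs); lo <- min(rs)
  # positive deviation wins ties (within rounding) between the extrema
  tol <- 1e-9 * max(abs(hi), abs(lo), 1)
  es <- if (hi + lo >= -tol) hi else lo
  list(es = es, running_sum = rs, hit_positions = which(hit), n_hits = sum(hit))
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Gene-label permutation null: the metric vector keeps its order while
#' set membership is reassigned uniformly at random; the p-value is
#' `(1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)`. Deterministic under
#' `seed`.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer seed.
#' @return One-row data.frame of class `EnrichmentResult`: `es`, `p`,
#'   `n_hits`, `direction` (positive/negative), `n_perm`.
#' @export
gsea_permutation_p <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                               weight_p = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  obs <- gsea_es(ranked, gene_set, weight_p)
  n <- nrow(ranked); nh <- obs$n_hits
  exceed <- local({
    set.seed(as.integer(seed))
    sum(vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, nh)] <- TRUE
      w <- abs(ranked$metric)^weight_p
      inc <- ifelse(hit, w / sum(w[hit]), 0)
      dec <- ifelse(hit, 0, 1 / sum(!hit))
      rs <- cumsum(inc - dec)
      abs(rs[which.max(abs(rs))]) >= abs(obs$es)
    }, logical(1)))
  })
  structure(data.frame(es = obs$es, p = (1 + exceed) / (1 + n_perm),
                       n_hits = nh,
                       direction = if (obs$es >= 0) "positive" else "negative",
                       n_perm = n_perm, stringsAsFactors = FALSE),
            class = c("EnrichmentResult", "data.frame"))
}
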