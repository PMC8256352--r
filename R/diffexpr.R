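#' Differential-expression screening parameters
#'
#' @param p_threshold Significance gate, default 0.05.
#' @param lfc_threshold Absolute log2 fold-change gate, default 1.
#' @param use_adjusted Gate on the BH-adjusted q-value instead of the raw
#'   p-value (default FALSE: the screen uses raw p < 0.05, with the
#'   adjusted value reported alongside).
#' @param test `"pooled_t"` (equal-variance two-sample t, default) or
#'   `"welch_t"`.
#' @param var_floor Smallest within-group variance allowed when forming
#'   the t denominator; genes with zero sample variance in both groups
#'   get this floor instead of an infinite statistic. Default 1e-8.
#' @return A list of class `DEParams`.
#' @export
de_params <- function(p_threshold = 0.05, lfc_threshold = 1,
                      use_adjusted = FALSE, test = c("pooled_t", "welch_t"),
                      var_floor = 1e-8) {
  test <- match.arg(test)
  stopifnot(p_threshold > 0, lfc_threshold > 0, var_floor > 0)
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                 use_adjusted = use_adjusted, test = test, var_floor = var_floor),
            class = "DEParams")
}

#' Two-group differential expression screen
#'
#' Per-gene two-sample t-test on log2 expression (case vs control), with
#' log2 fold change taken as the difference of group means, BH-adjusted
#' q-values, and a differential-expression call requiring
#' `|log2FC| >= lfc_threshold` together with the significance gate.
#'
#' @param em An [expression_matrix()]; both groups need >= 2 samples.
#' @param params A [de_params()] object.
#' @return data.frame of class `DETable` with columns `gene`, `log2fc`,
#'   `t`, `p`, `q`, `direction` (up/down/none) and `is_de`.
#' @export
differential_expression <- function(em, params = de_params()) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(params, "DEParams"))
  v <- em$values
  ctrl <- v[, em$group == "control", drop = FALSE]
  case <- v[, em$group == "case", drop = FALSE]
  n0 <- ncol(ctrl); n1 <- ncol(case)
  if (n0 < 2 || n1 < 2) stop("each group needs at least 2 samples")
  m0 <- rowMeans(ctrl); m1 <- rowMeans(case)
  v0 <- apply(ctrl, 1, stats::var); v1 <- apply(case, 1, stats::var)
  lfc <- m1 - m0
  if (params$test == "pooled_t") {
    sp2 <- pmax(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2), params$var_floor)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2, length(lfc))
  } else {
    v0f <- pmax(v0, params$var_floor); v1f <- pmax(v1, params$var_floor)
    se <- sqrt(v0f / n0 + v1f / n1)
    df <- (v0f / n0 + v1f / n1)^2 /
      ((v0f / n0)^2 / (n0 - 1) + (v1f / n1)^2 / (n1 - 1))
  }
  t <- lfc / se
  p <- 2 * stats::pt(-abs(t), df)
  q <- stats::p.adjust(p, method = "BH")
  gate <- if (params$use_adjusted) q else p
  is_de <- abs(lfc) >= params$lfc_threshold & gate < params$p_threshold
  direction <- ifelse(is_de, ifelse(lfc > 0, "up", "down"), "none")
  structure(data.frame(gene = rownames(v), log2fc = lfc, t = t, p = p, q = q,
                       direction = direction, is_de = is_de,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("DETable", "data.frame"), rna_class = em$rna_class)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Partition differential-expression calls by direction
#'
#' @param det A `DETable` from [differential_expression()].
#' @return list with character vectors `up` and `down`.
#' @export
de_sets <- function(det) {
  stopifnot(inherits(det, "DETable") || is.data.frame(det))
  list(up = det$gene[det$is_de & det$direction == "up"],
       down = det$gene[det$is_de & det$direction == "down"])
}

#' @export
write_de_table <- function(det, path) {
  utils::write.table(as.data.frame(det), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
read_de_table <- function(path) {
  det <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "t", "p", "q", "direction", "is_de")
  if (!all(need %in% names(det))) stop("DE table needs columns: ", paste(need, collapse = ", "))
  structure(det, class = c("DETable", "data.frame"))
}
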