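#' Construct an expression matrix with a two-group design
#'
#' Container for log2-scale abundance of one RNA class (mRNA, lncRNA or
#' miRNA) across samples split into a control and a case group.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Log2 scale.
#' @param group Character or factor of length `ncol(values)` with values
#'   `"control"` / `"case"`, one per sample column.
#' @param rna_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `group` (factor with levels control, case) and `rna_class`.
#' @export
expression_matrix <- function(values, group, rna_class = c("mRNA", "lncRNA", "miRNA")) {
  rna_class <- match.arg(rna_class)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (length(group) != ncol(values))
    stop("'group' must have one entry per sample column")
  group <- factor(as.character(group), levels = c("control", "case"))
  if (anyNA(group))
    stop("group labels must be 'control' or 'case'")
  if (any(table(group) == 0))
    stop("both groups must be non-empty")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  structure(list(values = values, group = group, rna_class = rna_class),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples (%d control, %d case)\n",
              x$rna_class, nrow(x$values), ncol(x$values),
              sum(x$group == "control"), sum(x$group == "case")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and gene
#' ids in the first column. Duplicate gene ids are collapsed to the row
#' with the largest mean abundance (ties broken by first occurrence), and
#' genes whose mean log2 abundance falls below `abundance_floor` are
#' removed.
#'
#' @param path Path to the TSV file.
#' @param rna_class RNA class of the matrix.
#' @param design Sample-to-group assignment: either a named character
#'   vector (`names` = sample ids, values `"control"`/`"case"`) or a
#'   data.frame with columns `sample` and `group`.
#' @param abundance_floor Minimum mean log2 abundance for a gene to be
#'   retained; default `2` (i.e. abundance 4 on the linear scale). Set to
#'   `-Inf` to disable.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, rna_class, design, abundance_floor = 2) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs a gene-id column plus >=1 sample column")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!vapply(seq_len(ncol(vals)), function(j) is.numeric(tab[[j + 1]]), logical(1))]
    stop("non-numeric expression values in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(vals) <- NULL
  design <- as_design(design)
  missing <- setdiff(colnames(vals), names(design))
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  vals <- collapse_duplicate_genes(vals, ids)
  vals <- vals[rowMeans(vals) >= abundance_floor, , drop = FALSE]
  if (nrow(vals) == 0) stop("no genes left after abundance filtering")
  expression_matrix(vals, design[colnames(vals)], rna_class)
}

as_design <- function(design) {
  if (is.data.frame(design)) {
    if (!all(c("sample", "group") %in% names(design)))
      stop("design data.frame needs columns 'sample' and 'group'")
    stats::setNames(as.character(design$group), as.character(design$sample))
  } else if (is.character(design) && !is.null(names(design))) {
    design
  } else stop("design must be a named character vector or a sample/group data.frame")
}

# keep, per duplicated id, the row with the largest mean (first wins ties)
collapse_duplicate_genes <- function(vals, ids) {
  means <- rowMeans(vals)
  ord <- order(ids, -means, seq_along(ids))
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)
  vals <- vals[keep, , drop = FALSE]
  rownames(vals) <- ids[keep]
  vals
}

#' Apply the mean-abundance floor to an existing matrix
#'
#' @param em An [expression_matrix()].
#' @param abundance_floor Minimum mean log2 abundance.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_low_abundance <- function(em, abundance_floor = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  keep <- rowMeans(em$values) >= abundance_floor
  if (!any(keep)) stop("no genes left after abundance filtering")
  expression_matrix(em$values[keep, , drop = FALSE], em$group, em$rna_class)
}

#' Write an expression matrix to TSV (gene column first)
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = gene_ids(em), em$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
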