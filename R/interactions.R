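#' Construct a scored miRNA-target interaction table
#'
#' @param records data.frame with columns `mirna`, `target`, `score`
#'   (pairing score in \[0, 1\]).
#' @param target_class `"mRNA"` or `"lncRNA"`.
#' @param dedupe Keep the maximum score per (mirna, target) pair
#'   (default TRUE).
#' @return data.frame of class `InteractionTable` with attribute
#'   `target_class`.
#' @export
interaction_table <- function(records, target_class = c("mRNA", "lncRNA"), dedupe = TRUE) {
  target_class <- match.arg(target_class)
  need <- c("mirna", "target", "score")
  if (!all(need %in% names(records)))
    stop("interaction records need columns: ", paste(need, collapse = ", "))
  records <- records[need]
  records$mirna <- as.character(records$mirna)
  records$target <- as.character(records$target)
  records$score <- as.numeric(records$score)
  if (anyNA(records$score) || any(records$score < 0 | records$score > 1))
    stop("pairing scores must lie in [0, 1]")
  if (dedupe && nrow(records)) {
    ord <- order(records$mirna, records$target, -records$score)
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(records[c("mirna", "target")]), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(records, class = c("InteractionTable", "data.frame"),
            target_class = target_class)
}

#' Read a miRNA-target interaction table from TSV
#'
#' Columns `mirna`, `target`, `score`; duplicated (mirna, target) pairs
#' keep the maximum score.
#'
#' @inheritParams interaction_table
#' @param path Path to the TSV file.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path, target_class) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_table(tab, target_class)
}

#' @export
write_interaction_table <- function(it, path) {
  utils::write.table(as.data.frame(it), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
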