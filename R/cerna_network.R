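#' Construct a ceRNA network from mRNA-miRNA-lncRNA triples
#'
#' A ceRNA network is a set of (mRNA, miRNA, lncRNA) triples — one row
#' per shared miRNA of a called ceRNA pair — together with the pair-level
#' test records and the simple undirected tripartite graph of the
#' deduplicated miRNA-mRNA and miRNA-lncRNA links.
#'
#' @param triples data.frame with columns `mrna`, `mirna`, `lncrna`.
#' @param pairs Optional pair-level records (as produced by
#'   [call_cerna_pairs()]); when omitted, minimal records (shared counts
#'   only) are derived from the triples.
#' @return Object of class `CeRNANetwork`: list with `triples`, `pairs`.
#' @export
cerna_network <- function(triples, pairs = NULL) {
  need <- c("mrna", "mirna", "lncrna")
  stopifnot(is.data.frame(triples), all(need %in% names(triples)))
  triples <- data.frame(lapply(triples[need], as.character), stringsAsFactors = FALSE)
  ids <- c(triples$mrna, triples$mirna, triples$lncrna)
  if (nrow(triples) && anyDuplicated(do.call(paste, triples)))
    stop("duplicate triples")
  if (nrow(triples)) {
    classes <- rbind(data.frame(id = triples$mrna, cls = "mRNA"),
                     data.frame(id = triples$mirna, cls = "miRNA"),
                     data.frame(id = triples$lncrna, cls = "lncRNA"))
    conflict <- tapply(classes$cls, classes$id, function(x) length(unique(x)))
    if (any(conflict > 1))
      stop("id(s) used as more than one RNA class: ",
           paste(names(conflict)[conflict > 1], collapse = ", "))
  }
  if (is.null(pairs)) {
    key <- paste(triples$mrna, triples$lncrna, sep = "\r")
    agg <- split(triples$mirna, key)
    pairs <- data.frame(
      mrna = vapply(strsplit(names(agg), "\r", fixed = TRUE), `[`, "", 1),
      lncrna = vapply(strsplit(names(agg), "\r", fixed = TRUE), `[`, "", 2),
      x = lengths(agg),
      shared_mirnas = vapply(agg, function(m) paste(sort(m), collapse = ";"), ""),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(triples = triples, pairs = pairs), class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  cat(sprintf("CeRNANetwork: %d triples | %d mRNAs, %d miRNAs, %d lncRNAs | %d pair records\n",
              nrow(x$triples), length(unique(x$triples$mrna)),
              length(unique(x$triples$mirna)), length(unique(x$triples$lncrna)),
              nrow(x$pairs)))
  invisible(x)
}

#' Convert a ceRNA network to an igraph graph
#'
#' Undirected simple graph over the deduplicated miRNA-mRNA and
#' miRNA-lncRNA links of the triples, with vertex attribute `rna_class`.
#' Direct mRNA-lncRNA edges never occur at this stage.
#'
#' @param net A [cerna_network()].
#' @return An [igraph::igraph] object.
#' @export
cerna_graph <- function(net) {
  stopifnot(inherits(net, "CeRNANetwork"))
  tr <- net$triples
  if (!nrow(tr)) stop("empty network")
  edges <- unique(rbind(data.frame(from = tr$mirna, to = tr$mrna),
                        data.frame(from = tr$mirna, to = tr$lncrna)))
  cls <- c(stats::setNames(rep("mRNA", length(unique(tr$mrna))), unique(tr$mrna)),
           stats::setNames(rep("miRNA", length(unique(tr$mirna))), unique(tr$mirna)),
           stats::setNames(rep("lncRNA", length(unique(tr$lncrna))), unique(tr$lncrna)))
  verts <- data.frame(name = names(cls), rna_class = unname(cls),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  igraph::simplify(g)
}

#' Load the packaged 99-interaction reference ceRNA network
#'
#' The package ships, as a plain-text fixture, a published table of 99
#' mRNA-miRNA-lncRNA interactive triples inferred from a Parkinson's
#' disease differential-expression screen (27 mRNAs, 15 lncRNAs and 25
#' miRNAs). This is the network used by [validate_against_fixture()] and
#' the topology acceptance checks.
#'
#' @return A [cerna_network()] with 99 triples.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_cerna_triples.tsv", package = "ceRNAnet")
  if (path == "" || !file.exists(path)) stop("packaged triple-table fixture not found")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 99) stop("fixture corrupted: expected 99 rows, found ", nrow(tab))
  cerna_network(tab)
}

#' Export a ceRNA network to SIF or GraphML
#'
#' SIF rows are `miRNA<TAB>targets<TAB>target`; GraphML carries the
#' vertex attribute `rna_class` (via igraph) and round-trips the graph
#' exactly.
#'
#' @param net A [cerna_network()] or [igraph::igraph].
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  g <- if (inherits(net, "CeRNANetwork")) cerna_graph(net) else net
  if (igraph::ecount(g) == 0) stop("refusing to export an empty network")
  if (format == "sif") {
    el <- igraph::as_edgelist(g)
    cls <- igraph::V(g)$rna_class[match(el[, 1], igraph::V(g)$name)]
    # orient rows miRNA -> target where the miRNA side is known
    swap <- !is.null(cls) & cls != "miRNA"
    el[swap, ] <- el[swap, c(2, 1)]
    writeLines(paste(el[, 1], "targets", el[, 2], sep = "\t"), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a GraphML network written by [export_network()]
#' @param path GraphML file.
#' @return An [igraph::igraph].
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @export
write_cerna_tables <- function(net, pairs_path, triples_path) {
  utils::write.table(net$pairs, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$triples, triples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pairs_path, triples_path))
}
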