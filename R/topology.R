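#' @title Topological fitness of a ceRNA network
#' @description Per-node degree, topological coefficient, closeness and
#'   betweenness, power-law fits of each metric against degree, and the
#'   R-squared of those fits — the network "fitness assessment".
#' @name topology
NULL

as_topology_graph <- function(net) {
  g <- if (inherits(net, "CeRNANetwork")) cerna_graph(net) else net
  stopifnot(inherits(g, "igraph"))
  if (igraph::is_directed(g)) g <- igraph::as.undirected(g)
  igraph::simplify(g)
}

#' Node degrees and the degree distribution
#'
#' @param net [cerna_network()] or [igraph::igraph].
#' @return list with `degree` (named per-node vector) and `distribution`
#'   (data.frame `k`, `count`).
#' @export
node_degree <- function(net) {
  g <- as_topology_graph(net)
  if (igraph::vcount(g) == 0) stop("empty graph")
  k <- igraph::degree(g)
  tab <- table(k)
  list(degree = k,
       distribution = data.frame(k = as.numeric(names(tab)),
                                 count = as.numeric(tab)))
}

#' Topological coefficient per node
#'
#' For node n with degree k(n) > 1, the mean over all nodes m (m != n)
#' sharing at least one neighbour with n of
#' `J(n, m) / k(n)`, where `J(n, m)` is the shared-neighbour count plus
#' one if n and m are adjacent. Nodes with k <= 1 are assigned 0 and are
#' excluded from fits.
#'
#' @param net [cerna_network()] or [igraph::igraph].
#' @return Named numeric vector.
#' @export
topological_coefficient <- function(net) {
  g <- as_topology_graph(net)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  S <- A %*% A          # S[n, m] = number of shared neighbours
  k <- rowSums(A)
  n_nodes <- nrow(A)
  tc <- numeric(n_nodes)
  for (n in seq_len(n_nodes)) {
    if (k[n] <= 1) next
    share <- S[n, ] > 0
    share[n] <- FALSE
    if (!any(share)) next
    J <- S[n, share] + A[n, share]
    tc[n] <- mean(J) / k[n]
  }
  stats::setNames(tc, rownames(A))
}

#' Closeness centrality (component-local)
#'
#' Reciprocal of the mean shortest-path distance to the nodes reachable
#' from each node: `C(n) = reachable / sum(distances)`. Isolated nodes
#' get 0. Computed within each connected component, so a disconnected
#' graph is handled without infinities.
#'
#' @param net [cerna_network()] or [igraph::igraph].
#' @return Named numeric vector in (0, 1\] (0 for isolated nodes).
#' @export
closeness_centrality <- function(net) {
  g <- as_topology_graph(net)
  D <- igraph::distances(g)
  vapply(seq_len(nrow(D)), function(n) {
    d <- D[n, -n]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1)) -> cc
  stats::setNames(cc, rownames(D))
}

#' Betweenness centrality, pair-normalized
#'
#' Exact shortest-path betweenness (endpoints excluded) divided by the
#' number of node pairs `(V - 1)(V - 2) / 2`, so values lie in \[0, 1\].
#'
#' @param net [cerna_network()] or [igraph::igraph].
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  g <- as_topology_graph(net)
  V <- igraph::vcount(g)
  if (V < 3) return(stats::setNames(rep(0, V), igraph::V(g)$name))
  igraph::betweenness(g, directed = FALSE) / ((V - 1) * (V - 2) / 2)
}

#' Fit a power law by log-log least squares
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, giving
#' `y = a * x^b`; points with non-positive x or y are dropped (with a
#' warning when any y <= 0 is removed). R-squared is the coefficient of
#' determination in log space; an exactly constant y fits with slope 0
#' and R-squared 1 (zero residuals).
#'
#' @param x,y Numeric vectors of equal length.
#' @return list with `a`, `b`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(is.finite(y) & y <= 0))
    warning(sum(is.finite(y) & y <= 0), " non-positive y value(s) dropped before log transform")
  lx <- log10(x[ok]); ly <- log10(y[ok])
  if (length(lx) < 3) stop("need at least 3 positive points to fit")
  fit <- stats::lm(ly ~ lx)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) (if (ss_res < 1e-24) 1 else 0) else 1 - ss_res / ss_tot
  list(a = unname(10^stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r_squared = r2, n_points = length(lx))
}

#' Network fitness report: four metrics, four power-law fits
#'
#' Computes the degree distribution and the three per-node centrality
#' metrics, fits `y = a * x^b` to each series, and reports the four
#' R-squared values. The degree series is always the aggregated
#' distribution (count of nodes per degree vs degree). For topological
#' coefficient, closeness and betweenness the default mode `"per_node"`
#' fits the raw node-level scatter (metric vs the node's degree), the
#' convention under which the packaged reference network reproduces its
#' published fit quality; `"per_degree"` instead averages the metric
#' over nodes of equal degree before fitting. In both modes zero
#' topological coefficients (k <= 1 nodes) and zero betweenness values
#' are dropped before the log transform.
#'
#' @param net [cerna_network()] or [igraph::igraph].
#' @param mode `"per_node"` (default) or `"per_degree"`.
#' @return Object of class `TopologyReport`: list with `node_metrics`
#'   (data.frame node, rna_class, degree, topological_coefficient,
#'   closeness, betweenness), `degree_distribution`, `series` (the
#'   fitted (x, y) points per metric), `fits` (data.frame metric, a, b,
#'   r_squared, n_points, with NA rows for series that could not be
#'   fitted) and `mode`.
#' @export
fitness_report <- function(net, mode = c("per_node", "per_degree")) {
  mode <- match.arg(mode)
  g <- as_topology_graph(net)
  if (!is.null(igraph::V(g)$rna_class)) {
    cls <- igraph::V(g)$rna_class
    el <- igraph::as_edgelist(g)
    c1 <- cls[match(el[, 1], igraph::V(g)$name)]
    c2 <- cls[match(el[, 2], igraph::V(g)$name)]
    if (any(c1 != "miRNA" & c2 != "miRNA"))
      stop("tripartite violation: direct mRNA/lncRNA-mRNA/lncRNA edge present")
  }
  deg <- node_degree(g)
  k <- deg$degree
  node_names <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name
                else as.character(seq_len(igraph::vcount(g)))
  metrics <- data.frame(
    node = node_names,
    rna_class = if (!is.null(igraph::V(g)$rna_class)) igraph::V(g)$rna_class else NA_character_,
    degree = as.numeric(k),
    topological_coefficient = as.numeric(topological_coefficient(g)),
    closeness = as.numeric(closeness_centrality(g)),
    betweenness = as.numeric(betweenness_centrality(g)),
    row.names = NULL, stringsAsFactors = FALSE)

  series <- list(degree_distribution = list(x = deg$distribution$k,
                                            y = deg$distribution$count))
  for (m in c("topological_coefficient", "closeness", "betweenness")) {
    v <- metrics[[m]]
    keep <- v > 0        # k<=1 TC zeros and zero betweenness leave the series
    x <- metrics$degree[keep]; y <- v[keep]
    if (mode == "per_degree") {
      mu <- tapply(y, x, mean)
      x <- as.numeric(names(mu)); y <- as.numeric(mu)
    }
    series[[m]] <- list(x = x, y = y)
  }
  fits <- do.call(rbind, lapply(names(series), function(m) {
    f <- tryCatch(suppressWarnings(fit_power_law(series[[m]]$x, series[[m]]$y)),
                  error = function(e) list(a = NA_real_, b = NA_real_,
                                           r_squared = NA_real_, n_points = length(series[[m]]$x),
                                           error = conditionMessage(e)))
    data.frame(metric = m, a = f$a, b = f$b, r_squared = f$r_squared,
               n_points = f$n_points, stringsAsFactors = FALSE)
  }))
  structure(list(node_metrics = metrics, degree_distribution = deg$distribution,
                 series = series, fits = fits, mode = mode),
            class = "TopologyReport")
}

#' @export
print.TopologyReport <- function(x, ...) {
  cat(sprintf("TopologyReport (%s mode): %d nodes\n", x$mode, nrow(x$node_metrics)))
  print(x$fits, row.names = FALSE)
  invisible(x)
}
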