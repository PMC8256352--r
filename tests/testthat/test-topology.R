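path3 <- function() graph_from_adjacency(matrix(c(0,1,0, 1,0,1, 0,1,0), 3,
                                                dimnames = rep(list(c("a","b","c")), 2)))
star <- function(k) igraph::make_star(k + 1, mode = "undirected")

test_that("degree and the handshake identity on the reference graph", {
  tri <- graph_from_adjacency(matrix(1, 3, 3) - diag(3))
  expect_true(all(node_degree(tri)$degree == 2))
  s5 <- star(5)
  expect_equal(sort(unique(as.numeric(node_degree(s5)$degree))), c(1, 5))

  g <- cerna_graph(load_table2_fixture())
  deg <- node_degree(g)
  expect_equal(sum(deg$degree), 2 * igraph::ecount(g))
  expect_equal(sum(deg$distribution$count), igraph::vcount(g))
})

test_that("topological coefficient matches hand computations", {
  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(unname(topological_coefficient(k4)), rep(1, 4))
  # star leaves have k = 1 -> excluded convention value 0
  expect_equal(as.numeric(topological_coefficient(star(4)))[-1], rep(0, 4))
  # k <= 1 ends of a path take the convention value 0 as well
  tc <- topological_coefficient(path3())
  expect_equal(unname(tc[c("a", "c")]), c(0, 0))
  # 4-cycle: each node's only neighbour-sharer is the opposite corner,
  # sharing both neighbours and not adjacent -> T = 2/2 = 1
  c4 <- graph_from_adjacency(matrix(c(0,1,0,1, 1,0,1,0, 0,1,0,1, 1,0,1,0), 4))
  expect_equal(as.numeric(topological_coefficient(c4)), rep(1, 4))
})

test_that("closeness matches hand computations and is component-local", {
  cc <- closeness_centrality(path3())
  expect_equal(unname(cc["b"]), 1)
  expect_equal(unname(cc["a"]), 2 / 3)
  k5 <- graph_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_true(all(closeness_centrality(k5) == 1))
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  two_edges <- graph_from_adjacency(A)
  expect_true(all(closeness_centrality(two_edges) == 1))
})

test_that("betweenness matches hand computations", {
  b <- betweenness_centrality(path3())
  expect_equal(unname(b["b"]), 1)
  tri <- graph_from_adjacency(matrix(1, 3, 3) - diag(3))
  expect_true(all(betweenness_centrality(tri) == 0))
  s4 <- star(4)
  expect_equal(as.numeric(betweenness_centrality(s4))[1], 1)
})

test_that("centrality metrics agree with exhaustive oracles on random small graphs", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    A <- random_adjacency(n, p = runif(1, 0.2, 0.8))
    g <- graph_from_adjacency(A)
    expect_equal(as.numeric(betweenness_centrality(g)), betweenness_oracle(A),
                 tolerance = 1e-10)
    expect_equal(as.numeric(closeness_centrality(g)), closeness_oracle(A),
                 tolerance = 1e-12)
    expect_equal(as.numeric(topological_coefficient(g)),
                 topological_coefficient_oracle(A), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(123)
  A <- random_adjacency(7, 0.5)
  perm <- sample(7)
  B <- A[perm, perm]
  g1 <- graph_from_adjacency(A); g2 <- graph_from_adjacency(B)
  expect_equal(sort(as.numeric(betweenness_centrality(g1))),
               sort(as.numeric(betweenness_centrality(g2))), tolerance = 1e-12)
  expect_equal(sort(as.numeric(closeness_centrality(g1))),
               sort(as.numeric(closeness_centrality(g2))), tolerance = 1e-12)
})

test_that("power-law fits recover exact parameters and reject tiny series", {
  x <- 1:5
  f <- fit_power_law(x, 2 * x^-1)
  expect_equal(f$b, -1, tolerance = 1e-12)
  expect_equal(f$a, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  fc <- fit_power_law(x, rep(3, 5))
  expect_equal(fc$b, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 1)

  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, -3, 3)
    f <- fit_power_law(1:6, a * (1:6)^b)
    expect_equal(f$a, a, tolerance = 1e-8)
    expect_equal(f$b, b, tolerance = 1e-8)
  }
  noisy <- fit_power_law(1:10, 2 * (1:10)^-1 * exp(rnorm(10, sd = 0.3)))
  expect_lt(noisy$r_squared, 1)
  expect_error(fit_power_law(1:2, c(1, 2)), "at least 3")
  expect_warning(fit_power_law(1:4, c(1, 2, 0, 3)), "non-positive")
})

test_that("the fitness report reproduces the reference network's fit quality", {
  net <- load_table2_fixture()
  rep_node <- fitness_report(net)
  expect_equal(rep_node$fits$metric,
               c("degree_distribution", "topological_coefficient",
                 "closeness", "betweenness"))
  r2 <- stats::setNames(rep_node$fits$r_squared, rep_node$fits$metric)
  expect_equal(unname(r2["degree_distribution"]), 0.827, tolerance = 2e-3)
  expect_equal(unname(r2["topological_coefficient"]), 0.936, tolerance = 2e-3)
  expect_equal(unname(r2["closeness"]), 0.690, tolerance = 2e-3)
  expect_equal(unname(r2["betweenness"]), 0.688, tolerance = 2e-3)

  rep_deg <- fitness_report(net, mode = "per_degree")
  expect_equal(rep_deg$fits$r_squared[1], rep_node$fits$r_squared[1])  # same series
  expect_false(isTRUE(all.equal(rep_deg$fits$r_squared[2], rep_node$fits$r_squared[2])))
})

test_that("degenerate series are reported per-metric, not fatal", {
  s <- fitness_report(star(5))
  expect_true(is.na(s$fits$r_squared[s$fits$metric == "degree_distribution"]))

  set.seed(99)
  pa <- igraph::sample_pa(200, m = 2, directed = FALSE)
  r <- fitness_report(pa)
  expect_gt(r$fits$r_squared[r$fits$metric == "degree_distribution"], 0.5)
})

test_that("tripartite ceRNA graphs never link mRNA to lncRNA directly", {
  g <- cerna_graph(load_table2_fixture())
  cls <- igraph::V(g)$rna_class
  el <- igraph::as_edgelist(g)
  c1 <- cls[match(el[, 1], igraph::V(g)$name)]
  c2 <- cls[match(el[, 2], igraph::V(g)$name)]
  expect_true(all(c1 == "miRNA" | c2 == "miRNA"))
})
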