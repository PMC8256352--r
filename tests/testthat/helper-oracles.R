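# Independent oracles, deliberately written with different algorithms
# than the package implementations they check.

# exact hypergeometric upper tail by direct binomial summation;
# integer-valued binomials are exact in doubles for M <= 25
hyper_oracle <- function(K, N, M, x, inclusive = TRUE) {
  lo <- if (inclusive) x else x + 1
  hi <- min(K, N)
  if (lo > hi) return(0)
  tot <- 0
  for (t in lo:hi) {
    if (N - t > M - K || N - t < 0) next
    tot <- tot + choose(K, t) * choose(M - K, N - t)
  }
  tot / choose(M, N)
}

# all-pairs shortest distances by Floyd-Warshall on an adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

closeness_oracle <- function(A) {
  D <- fw_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1))
}

# shortest-path counts from walk counts: a walk of length d(s,t) cannot
# revisit a node, so (A^d)[s,t] counts shortest s-t paths exactly
betweenness_oracle <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  pow <- vector("list", max(1, n))
  pow[[1]] <- A
  if (n > 1) for (d in 2:n) pow[[d]] <- pow[[d - 1]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(if (s == t) 1 else 0)
    pow[[d]][s, t]
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) && D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma(s, v) * sigma(v, t) / sigma(s, t)
    }
    b[v] <- tot
  }
  if (n < 3) rep(0, n) else b / ((n - 1) * (n - 2) / 2)
}

topological_coefficient_oracle <- function(A) {
  n <- nrow(A)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  vapply(seq_len(n), function(i) {
    if (length(nb[[i]]) <= 1) return(0)
    J <- c()
    for (m in seq_len(n)) {
      if (m == i) next
      sh <- length(intersect(nb[[i]], nb[[m]]))
      if (sh > 0) J <- c(J, sh + (A[i, m] == 1))
    }
    if (!length(J)) 0 else mean(J) / length(nb[[i]])
  }, numeric(1))
}

# step-by-step weighted-KS running sum walked with an explicit loop
es_oracle <- function(metric, is_hit, weight_p = 1) {
  nh <- sum(is_hit)
  nm <- sum(!is_hit)
  denom_hit <- sum(abs(metric[is_hit])^weight_p)
  rs <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_along(metric)) {
    rs <- rs + if (is_hit[i]) abs(metric[i])^weight_p / denom_hit else -1 / nm
    if (rs > hi) hi <- rs
    if (rs < lo) lo <- rs
  }
  tol <- 1e-9 * max(abs(hi), abs(lo), 1)
  if (hi + lo >= -tol) hi else lo
}

# random connected-ish simple undirected graph as an adjacency matrix
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}
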