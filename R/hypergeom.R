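#' Shared-miRNA hypergeometric test
#'
#' Significance of the overlap between the miRNA regulator sets of an
#' mRNA and a lncRNA. Out of `M` miRNAs in the genome, `K` interact with
#' the mRNA and `N` with the lncRNA; `x` is the number shared. Under the
#' null of independent regulator draws the shared count follows a
#' hypergeometric distribution, and the reported p-value is its upper
#' tail.
#'
#' Two tail conventions are supported. `"upper_inclusive"` (default) is
#' the standard ceRNA convention P(X >= x) = 1 - sum_{t=0}^{x-1} of the
#' hypergeometric pmf. `"as_printed"` sums t = 0..x, i.e. the strict
#' P(X > x); it assigns p < 1 to a zero overlap and is provided only for
#' comparison.
#'
#' Probabilities are accumulated in log-gamma arithmetic
#' (via [lchoose()] and a log-sum-exp), stable for M up to at least 1e5.
#'
#' @param K Number of miRNAs interacting with the mRNA.
#' @param N Number of miRNAs interacting with the lncRNA.
#' @param M Number of miRNAs in the genome (universe).
#' @param x Observed shared-miRNA count, `0 <= x <= min(K, N)`.
#' @param tail Tail convention, see Details.
#' @return Upper-tail p-value in \[0, 1\].
#' @examples
#' shared_mirna_test(K = 2, N = 2, M = 4, x = 2)   # 1/6
#' shared_mirna_test(K = 5, N = 5, M = 20, x = 3)  # 1126/15504
#' @export
shared_mirna_test <- function(K, N, M, x, tail = c("upper_inclusive", "as_printed")) {
  tail <- match.arg(tail)
  stopifnot(length(K) == 1, length(N) == 1, length(M) == 1, length(x) == 1)
  if (anyNA(c(K, N, M, x)) || any(c(K, N, M, x) != floor(c(K, N, M, x))))
    stop("K, N, M, x must be non-negative integers")
  if (K > M || N > M) stop("K and N cannot exceed M")
  if (x < 0 || x > min(K, N)) stop("x must satisfy 0 <= x <= min(K, N)")
  lo <- if (tail == "upper_inclusive") x else x + 1L
  hi <- min(K, N)
  if (lo > hi) return(0)
  t <- seq.int(lo, hi)
  lt <- lchoose(K, t) + lchoose(M - K, N - t) - lchoose(M, N)
  lt <- lt[is.finite(lt)]  # terms outside the support contribute 0
  if (!length(lt)) return(0)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}
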