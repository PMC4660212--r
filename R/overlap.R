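## Hypergeometric gene-set overlap testing (enrichment of an observed
## intersection against random draws from a finite gene universe).

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts the overlap between a fixed set of K genes and
#' a random draw of n genes from a universe of N: the probability of seeing
#' at least the observed overlap by chance. The tail includes k itself (the
#' standard enrichment convention) and is evaluated in log space via
#' [stats::phyper()] for numerical stability at extreme tails.
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set (the draw).
#' @param k observed overlap; must satisfy
#'   `max(0, K + n - N) <= k <= min(K, n)`.
#' @return the upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  for (v in c(N = N, K = K, n = n, k = k))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("N, K, n, k must be single non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop("set sizes cannot exceed the universe size", call. = FALSE)
  if (k > min(K, n) || k < max(0, K + n - N))
    stop(sprintf("infeasible overlap k=%d for N=%d, K=%d, n=%d", k, N, K, n),
         call. = FALSE)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Gene-set overlap analysis
#'
#' Computes the overlap between two gene sets within an explicit universe
#' (the genes measured on the platform — never silently defaulted to the
#' union of the sets), the overlap fraction relative to set A, and the
#' upper-tail hypergeometric enrichment probability. Duplicates are removed
#' before counting.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe character vector containing every gene either set could
#'   have drawn from.
#' @return an object of class `overlap_test` with N, K (= |A|), n (= |B|),
#'   k (= |A intersect B|), `fraction` (k / K) and `p_value`.
#' @export
overlap_analysis <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  stray <- setdiff(c(set_a, set_b), universe)
  if (length(stray))
    stop("set members outside the universe: ", paste(stray, collapse = ", "),
         call. = FALSE)
  K <- length(set_a); n <- length(set_b); N <- length(universe)
  k <- length(intersect(set_a, set_b))
  structure(list(N = N, K = K, n = n, k = k,
                 fraction = if (K > 0) k / K else NA_real_,
                 p_value = hypergeometric_upper_tail(N, K, n, k),
                 overlap = sort(intersect(set_a, set_b))),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Gene-set overlap: |A|=%d, |B|=%d, universe %d\n", x$K, x$n, x$N))
  cat(sprintf("  overlap k=%d (%.1f%% of A); upper-tail hypergeometric P = %.3g\n",
              x$k, 100 * x$fraction, x$p_value))
  invisible(x)
}
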