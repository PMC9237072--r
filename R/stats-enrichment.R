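#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least `k` reference-set
#' genes in a query of size `n`, when the universe of `N` genes contains `K`
#' reference genes. The tail is accumulated in log space so the extreme
#' probabilities typical of cell-cycle gene-set overlaps (e.g. P ~ 1e-96) remain
#' representable. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param k Overlap count.
#' @param n Query-set size.
#' @param K Reference-set size.
#' @param N Universe size.
#' @return A list of class `enrichment_result` with fields `k_overlap`,
#'   `n_query`, `K_reference`, `N_universe`, `fold_enrichment`, `p_value`.
#' @export
hypergeom_enrich <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("k, n, K, N must be non-negative integers")
  }
  if (n > N || K > N) stop("query and reference sets cannot exceed the universe")
  if (k > min(n, K)) stop("overlap k cannot exceed min(n, K)")
  if (k < max(0, n + K - N)) stop("overlap k below the feasible minimum")
  if (n == 0) stop("query set is empty")
  i <- k:min(n, K)
  logtail <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logtail)
  p <- exp(mx + log(sum(exp(logtail - mx))))
  structure(
    list(
      k_overlap = as.integer(k), n_query = as.integer(n),
      K_reference = as.integer(K), N_universe = as.integer(N),
      fold_enrichment = (k / n) / (K / N),
      p_value = min(p, 1)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%d of %d query genes in reference set (%d of %d): %.2f-fold enrichment, hypergeometric P = %.3g\n",
    x$k_overlap, x$n_query, x$K_reference, x$N_universe,
    x$fold_enrichment, x$p_value
  ))
  invisible(x)
}
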