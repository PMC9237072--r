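#' Trimmed mean of M-values scaling factors
#'
#' Between-sample normalization for count data. Each column is compared to a
#' reference column (the one whose upper-quartile count proportion is closest to
#' the mean upper quartile); per-gene log2 ratios of count proportions (M-values)
#' are trimmed on both M (30% each side by default) and average abundance A (5%
#' each side), and their precision-weighted mean gives the column's log2 scaling
#' factor. Precision weights follow the delta method on the detection
#' proportions, `(1 - p_k)/p_k + (1 - p_r)/p_r`, with the sequencing depths
#' cancelled so that -- like the M-values themselves -- the weights depend
#' only on proportions and the factors are exactly invariant to rescaling any
#' column. Genes with a zero in either column are excluded. Factors are
#' rescaled so their product is 1.
#'
#' @param counts A `count_matrix` or plain genes-x-units matrix with >= 2 units.
#' @param logratio_trim Fraction trimmed from each tail of M (default 0.3).
#' @param sum_trim Fraction trimmed from each tail of A (default 0.05).
#' @return Named positive numeric vector of per-unit scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2) stop("TMM needs at least 2 units")
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("unit(s) with all-zero counts: ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  }
  uq <- apply(m, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  pr <- m[, ref] / lib[ref]
  nref <- lib[ref]
  logf <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) return(0)
    pk <- m[, k] / lib[k]
    keep <- m[, k] > 0 & m[, ref] > 0
    yk <- m[keep, k]
    yr <- m[keep, ref]
    M <- log2((yk / lib[k]) / (yr / nref))
    A <- 0.5 * log2((yk / lib[k]) * (yr / nref))
    qk <- yk / lib[k]
    qr <- yr / nref
    w <- (1 - qk) / qk + (1 - qr) / qr
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n - floor(n * logratio_trim)
    loA <- floor(n * sum_trim) + 1
    hiA <- n - floor(n * sum_trim)
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel) || sum(w[sel]) == 0) return(0)
    f <- sum(w[sel] * M[sel]) / sum(w[sel])
    if (abs(f) < 1e-6) 0 else f
  }, numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' Counts per million
#'
#' `cpm[g, u] = counts[g, u] / (library_size[u] * factor[u]) * 1e6`. With all
#' factors 1 this is plain library-size normalization.
#'
#' @param counts A `count_matrix` or genes-x-units matrix.
#' @param factors Optional per-unit scaling factors (e.g. from [tmm_factors()]).
#' @return Matrix of CPM values with the input dimnames.
#' @export
cpm <- function(counts, factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop("unit(s) with zero library size")
  if (is.null(factors)) factors <- rep(1, ncol(m))
  stopifnot(length(factors) == ncol(m), all(factors > 0))
  t(t(m) / (lib * factors)) * 1e6
}

#' log2(CPM + 1) expression
#'
#' The modeled expression scale used throughout the single-cell pipeline and the
#' bulk decomposition; the pseudocount guards zeros.
#'
#' @inheritParams cpm
#' @param prior Pseudocount added before the log (default 1).
#' @return Matrix of log2(CPM + prior).
#' @export
log2_cpm <- function(counts, factors = NULL, prior = 1) {
  log2(cpm(counts, factors) + prior)
}
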