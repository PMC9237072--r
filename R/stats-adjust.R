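#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: for p-values sorted increasingly,
#' `adj_p(i) = min over j >= i of m * p(j) / j`, capped at 1, returned in the
#' input order. Callers strip missing values and reinsert them afterwards.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, no missing values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("bh_adjust does not accept missing values")
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  back <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[back]
}
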