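#' Phase preference of per-cell activity scores
#'
#' Two-sample two-sided Kolmogorov-Smirnov comparison of an activity score
#' (e.g. a per-cell regulon activity) between G1 and G2/M cells. A score is
#' called phase-specific when the KS p-value falls below `threshold`
#' (default 1e-12). The exact p-value is used where `stats::ks.test` provides
#' it (small samples without ties), the asymptotic one otherwise; with very few
#' cells per phase the discrete p-value floor makes the threshold unreachable
#' regardless of separation.
#'
#' @param scores Numeric per-unit activity scores.
#' @param phases Per-unit phase labels (`G1`/`G2M`, any accepted spelling).
#' @param threshold Significance threshold for the phase-specific call.
#' @return List with `D`, `p_value`, `phase_specific`.
#' @export
ks_phase_preference <- function(scores, phases, threshold = 1e-12) {
  phases <- normalize_phase(phases)
  if (length(scores) != length(phases)) stop("scores and phases lengths differ")
  g1 <- scores[phases == "G1"]
  g2 <- scores[phases == "G2M"]
  if (length(g1) < 2 || length(g2) < 2) stop("need at least 2 units per phase")
  ks <- suppressWarnings(stats::ks.test(g1, g2, alternative = "two.sided"))
  list(
    D = unname(ks$statistic),
    p_value = ks$p.value,
    phase_specific = ks$p.value < threshold
  )
}
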