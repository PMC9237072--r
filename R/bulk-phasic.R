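#' Bulk expression filter
#'
#' Keeps genes whose CPM exceeds `min_cpm` in every member of at least one
#' replicate set, where a replicate set is the group of samples sharing a stage
#' and phase (e.g. the two E7.5 G1 replicates). CPM here is plain library-size
#' normalization (no TMM), since the filter precedes normalization.
#'
#' @param counts A `count_matrix` of bulk counts.
#' @param annotations Per-sample annotations with `phase` and optionally
#'   `stage` defining the replicate sets.
#' @param min_cpm CPM threshold (default 5).
#' @return The filtered `count_matrix`; an error if no gene survives.
#' @export
filter_expressed_bulk <- function(counts, annotations, min_cpm = 5) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[match(counts$unit_ids, annotations$unit_id), , drop = FALSE]
  grp_cols <- intersect(c("stage", "phase"), names(ann))
  key <- interaction(ann[grp_cols], drop = TRUE, sep = "|")
  x <- cpm(counts)
  keep <- rep(FALSE, nrow(x))
  for (g in levels(key)) {
    in_g <- key == g
    keep <- keep | apply(x[, in_g, drop = FALSE] > min_cpm, 1, all)
  }
  if (!any(keep)) stop("no gene passes the CPM filter; review min_cpm")
  subset_counts(counts, genes = which(keep))
}

#' Bulk G1 vs G2/M differential test
#'
#' The bulk phasic pipeline at one stage: CPM expression filter (replicate-set
#' rule plus mean CPM above `min_cpm` across the tested samples), TMM
#' normalization, per-gene negative binomial Wald test of phase, BH adjustment,
#' and the phasic call at `alpha` (default 0.1).
#'
#' @param counts A `count_matrix` of bulk (exonic) counts.
#' @param annotations Per-sample annotations with `phase`, optionally `stage`.
#' @param stage Optional stage to subset to; `NULL` uses all samples.
#' @param alpha Adjusted-p threshold.
#' @param min_cpm CPM expression threshold.
#' @return data.frame with `gene_id`, `log2fc`, `standard_error`, `wald_stat`,
#'   `p_value`, `adj_p`, `phasic_call` for the tested genes.
#' @export
bulk_phasic_test <- function(counts, annotations, stage = NULL, alpha = 0.1,
                             min_cpm = 5) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[match(counts$unit_ids, annotations$unit_id), , drop = FALSE]
  if (!is.null(stage)) {
    sel <- ann$stage == stage
    if (!any(sel)) stop("stage '", stage, "' absent from annotations")
    counts <- subset_counts(counts, units = which(sel))
    ann <- ann[sel, , drop = FALSE]
  }
  phase <- normalize_phase(ann$phase)
  if (nlevels(droplevels(phase)) < 2) stop("both phases required for testing")
  filtered <- filter_expressed_bulk(counts, ann, min_cpm = min_cpm)
  mean_ok <- rowMeans(cpm(filtered)) > min_cpm
  filtered <- subset_counts(filtered, genes = which(mean_ok))
  factors <- tmm_factors(filtered)
  res <- nb_wald_test(filtered, phase, size_factors = factors)
  adj <- rep(NA_real_, nrow(res))
  ok <- !is.na(res$p_value)
  adj[ok] <- bh_adjust(res$p_value[ok])
  res$adj_p <- adj
  res$phasic_call <- !is.na(adj) & adj < alpha
  res
}

#' Exon/intron decomposition into transcription- and stability-driven classes
#'
#' Because introns turn over rapidly, intronic abundance tracks transcription
#' while exonic abundance reflects transcription times transcript stability.
#' Three empirical-Bayes moderated t tests of phase are run on log2(CPM + 1):
#' exonic (expression), intronic (transcription), and the per-sample
#' exon-minus-intron difference (stability), each BH-adjusted -- the
#' expression test across all filtered genes, the two component tests within
#' the classification family (expression-phasic genes with adequate intronic
#' coverage), where the classification decision is actually made. Among
#' expression-phasic genes (exonic adjusted p < `alpha`): both components
#' significant gives BOTH; one component significant gives that single class
#' (TRANSCRIPTION or STABILITY) provided the other component shows no trend at
#' all (adjusted p >= `ambiguity_p`); configurations with one significant and
#' one intermediate component, with neither significant, or with inadequate
#' intronic coverage (intron CPM not above `min_cpm` in any replicate set) are
#' UNRESOLVED. Non-phasic genes are NOT_PHASIC. The indeterminacy band
#' (`alpha <= p < ambiguity_p`) exists because a pure-driver call asserts the
#' absence of the other mechanism, and absence of significance alone is weak
#' evidence of absence with few replicates; setting `ambiguity_p = alpha`
#' disables the band and classifies purely by significance.
#'
#' @param exon,intron `count_matrix` layers sharing gene and unit labels.
#' @param annotations Per-sample annotations with `phase`, optionally `stage`.
#' @param alpha Adjusted-p threshold for all three component tests.
#' @param ambiguity_p Adjusted-p floor the non-driving component must reach
#'   before a single-driver class is assigned (default 0.5).
#' @param min_cpm Intronic-coverage and expression filter threshold.
#' @return data.frame with `gene_id`, `class`, `p_expression`,
#'   `p_transcription`, `p_stability` (BH-adjusted values; `NA` where intronic
#'   coverage is inadequate), `log2fc_expression`.
#' @export
decompose_transcription_stability <- function(exon, intron, annotations,
                                              alpha = 0.1, ambiguity_p = 0.5,
                                              min_cpm = 5) {
  stopifnot(inherits(exon, "count_matrix"), inherits(intron, "count_matrix"))
  if (!identical(exon$gene_ids, intron$gene_ids) ||
      !identical(exon$unit_ids, intron$unit_ids)) {
    stop("exon and intron layers must share gene and unit labels in order")
  }
  ann <- annotations[match(exon$unit_ids, annotations$unit_id), , drop = FALSE]
  phase <- normalize_phase(ann$phase)
  design <- cbind(intercept = 1, phaseG2M = as.numeric(phase == "G2M"))

  expr_keep <- filter_expressed_bulk(exon, ann, min_cpm = min_cpm)$gene_ids
  exon_f <- subset_counts(exon, genes = match(expr_keep, exon$gene_ids))
  intron_f <- subset_counts(intron, genes = match(expr_keep, intron$gene_ids))

  log_exon <- log2(cpm(exon_f, tmm_factors(exon_f)) + 1)
  intron_lib_ok <- colSums(intron_f$counts) > 0
  if (!all(intron_lib_ok)) stop("intron layer has all-zero sample(s)")
  log_intron <- log2(cpm(intron_f, tmm_factors(intron_f)) + 1)

  expr_fit <- moderated_t_test(log_exon, design, coef = "phaseG2M")$table
  p_expr <- bh_adjust(expr_fit$p_value)
  fc_expr <- expr_fit$effect

  # intronic-coverage rule: intron CPM above threshold across one replicate set
  resolved <- rep(FALSE, length(expr_keep))
  grp_cols <- intersect(c("stage", "phase"), names(ann))
  key <- interaction(ann[grp_cols], drop = TRUE, sep = "|")
  icpm <- cpm(intron_f)
  for (g in levels(key)) {
    in_g <- key == g
    resolved <- resolved | apply(icpm[, in_g, drop = FALSE] > min_cpm, 1, all)
  }

  phasic <- p_expr < alpha
  p_trans <- p_stab <- rep(NA_real_, length(expr_keep))
  fam <- phasic & resolved
  if (sum(fam) >= 2) {
    p_trans[fam] <- bh_adjust(
      moderated_t_test(log_intron[fam, , drop = FALSE], design,
                       coef = "phaseG2M")$table$p_value
    )
    stab <- log_exon - log_intron
    p_stab[fam] <- bh_adjust(
      moderated_t_test(stab[fam, , drop = FALSE], design,
                       coef = "phaseG2M")$table$p_value
    )
  }
  sig_t <- !is.na(p_trans) & p_trans < alpha
  sig_s <- !is.na(p_stab) & p_stab < alpha
  flat_t <- !is.na(p_trans) & p_trans >= ambiguity_p
  flat_s <- !is.na(p_stab) & p_stab >= ambiguity_p
  cls <- ifelse(
    !phasic, "NOT_PHASIC",
    ifelse(!resolved, "UNRESOLVED",
      ifelse(sig_t & sig_s, "BOTH",
        ifelse(sig_t & flat_s, "TRANSCRIPTION",
          ifelse(sig_s & flat_t, "STABILITY", "UNRESOLVED")
        )
      )
    )
  )
  data.frame(
    gene_id = expr_keep,
    class = cls,
    p_expression = p_expr,
    p_transcription = p_trans,
    p_stability = p_stab,
    log2fc_expression = fc_expr,
    stringsAsFactors = FALSE
  )
}
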