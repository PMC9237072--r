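#' Permutation-median phasic expression caller
#'
#' The single-cell phasic caller. For each of `n_permutations` draws the
#' pseudobulk blocks are re-randomized, expression is taken as log2(CPM + 1) of
#' the pseudobulk counts, the hurdle likelihood-ratio test of the phase term
#' (with the detection-fraction covariate) is run per gene, and p-values are
#' Benjamini-Hochberg adjusted within the permutation. Per gene the median
#' adjusted p and the median phase difference of mean log2(CPM + 1) (G2M minus
#' G1) are taken across permutations; a gene is called phasic when the median
#' adjusted p falls below `alpha` AND the absolute median log2 difference
#' exceeds `log2(fc_threshold)`. A gene untestable in more than half of the
#' permutations gets an `NA` call.
#'
#' @param counts A QC- and gene-filtered `count_matrix`.
#' @param annotations Matching per-cell annotations (`unit_id`, `phase`,
#'   optionally `lineage`).
#' @param alpha Median adjusted-p threshold (default 0.05).
#' @param n_permutations Number of pseudobulk randomizations (default 100).
#' @param fc_threshold Fold-change gate as a ratio (default 1.1, i.e. a gate of
#'   log2(1.1) ~ 0.138 on the log2 scale).
#' @param pseudobulk_size Cells per pseudobulk sample (default 10).
#' @param seed Seed controlling every randomization in the call.
#' @param group_by Pseudobulk grouping columns (default phase, plus lineage
#'   when present).
#' @param keep_raw Attach per-permutation raw p-value and adjusted-p matrices
#'   as attributes `raw_p` / `adj_p` (for calibration diagnostics).
#' @return data.frame with `gene_id`, `median_adj_p`, `median_log2fc`,
#'   `passes_fc`, `phasic_call`, `n_permutations_used`.
#' @export
permuted_phasic_test <- function(counts, annotations, alpha = 0.05,
                                 n_permutations = 100, fc_threshold = 1.1,
                                 pseudobulk_size = 10, seed = 1,
                                 group_by = NULL, keep_raw = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  G <- nrow(counts$counts)
  genes <- counts$gene_ids
  adjp <- matrix(NA_real_, G, n_permutations, dimnames = list(genes, NULL))
  rawp <- matrix(NA_real_, G, n_permutations, dimnames = list(genes, NULL))
  lfc <- matrix(NA_real_, G, n_permutations, dimnames = list(genes, NULL))
  with_seed(seed, {
    for (perm in seq_len(n_permutations)) {
      pb <- make_pseudobulk(counts, annotations, group_by = group_by,
                            size = pseudobulk_size, seed = NULL)
      res <- pseudobulk_phase_pass(pb)
      rawp[, perm] <- res$p
      adjp[, perm] <- res$adj_p
      lfc[, perm] <- res$log2fc
    }
  })
  out <- summarize_permutations(genes, adjp, lfc, alpha, fc_threshold,
                                n_permutations)
  if (keep_raw) {
    attr(out, "raw_p") <- rawp
    attr(out, "adj_p") <- adjp
  }
  out
}

# One pseudobulk pass: hurdle LRT of phase with detection covariate,
# BH within the pass, and the phase difference of mean log2(CPM+1).
pseudobulk_phase_pass <- function(pb) {
  expr <- log2_cpm(pb$counts)
  ann <- pb$annotations
  ann$detection_fraction <- colSums(pb$counts > 0) /
    max(colSums(pb$counts > 0))
  design <- hurdle_design(
    ann, terms = c("cell_cycle_phase", "fraction_of_detected_genes")
  )
  fit <- hurdle_lrt(expr, design, terms = "cell_cycle_phase")
  p <- fit$p_value[, 1]
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- bh_adjust(p[ok])
  is_g2m <- ann$phase == "G2M"
  list(
    p = p,
    adj_p = adj,
    log2fc = rowMeans(expr[, is_g2m, drop = FALSE]) -
      rowMeans(expr[, !is_g2m, drop = FALSE]),
    model_log2fc = fit$effect[, 1]
  )
}

summarize_permutations <- function(genes, adjp, lfc, alpha, fc_threshold,
                                   n_permutations) {
  n_na <- rowSums(is.na(adjp))
  med_p <- ifelse(
    n_na > n_permutations / 2, NA_real_,
    apply(adjp, 1, stats::median, na.rm = TRUE)
  )
  med_fc <- ifelse(
    n_na > n_permutations / 2, NA_real_,
    apply(lfc, 1, stats::median, na.rm = TRUE)
  )
  passes_fc <- abs(med_fc) > log2(fc_threshold)
  data.frame(
    gene_id = genes,
    median_adj_p = med_p,
    median_log2fc = med_fc,
    passes_fc = passes_fc,
    phasic_call = med_p < alpha & passes_fc,
    n_permutations_used = n_permutations - n_na,
    stringsAsFactors = FALSE
  )
}

#' Phase-by-lineage interaction caller with scrambled-lineage control
#'
#' Tests, per gene and per non-reference lineage, whether the phase effect
#' differs from the reference lineage, using the hurdle model
#' `~ phase + lineage + phase:lineage + detection` on permuted pseudobulk.
#' Cells are first down-sampled so both phases contribute equally within each
#' lineage. Per permutation, each lineage's interaction contrast is tested by
#' a single-column likelihood-ratio deletion and BH-adjusted across genes
#' within that lineage; medians are taken across permutations. With
#' `scrambled = TRUE` the pseudobulk is built from same-phase cells of mixed
#' lineages with matched per-(phase, lineage) sample counts -- the empirical
#' negative control under which lineage-linked phasic signal must vanish.
#'
#' @inheritParams permuted_phasic_test
#' @param reference_lineage The lineage other lineages are contrasted against.
#' @param scrambled Build the scrambled-lineage null instead of matched
#'   pseudobulk.
#' @param balance_phases Down-sample to equal phase sizes per lineage first.
#' @return data.frame in long form: `gene_id`, `lineage`, `median_adj_p`,
#'   `median_log2fc` (interaction effect on the log2 scale), `passes_fc`,
#'   `phasic_call`, `n_permutations_used`.
#' @export
interaction_phasic_test <- function(counts, annotations, reference_lineage,
                                    alpha = 0.05, n_permutations = 100,
                                    fc_threshold = 1.1, pseudobulk_size = 10,
                                    seed = 1, scrambled = FALSE,
                                    balance_phases = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!"lineage" %in% names(annotations)) stop("annotations lack a lineage column")
  lineages <- unique(as.character(annotations$lineage))
  if (length(lineages) < 2) stop("interaction testing needs >= 2 lineages")
  if (!reference_lineage %in% lineages) {
    stop("reference lineage '", reference_lineage, "' absent from the data")
  }
  genes <- counts$gene_ids
  G <- length(genes)
  others <- setdiff(lineages, reference_lineage)
  with_seed(seed, {
    if (balance_phases) {
      keep <- downsample_equal_phase(annotations, seed = NULL)
      counts <- subset_counts(counts, units = match(keep, counts$unit_ids))
      annotations <- annotations[match(keep, annotations$unit_id), , drop = FALSE]
    }
    adjp <- lapply(others, function(l) matrix(NA_real_, G, n_permutations))
    lfc <- lapply(others, function(l) matrix(NA_real_, G, n_permutations))
    names(adjp) <- names(lfc) <- others
    for (perm in seq_len(n_permutations)) {
      pb <- if (scrambled) {
        scramble_lineage_pseudobulk(counts, annotations,
                                    size = pseudobulk_size, seed = NULL)
      } else {
        make_pseudobulk(counts, annotations, group_by = c("phase", "lineage"),
                        size = pseudobulk_size, seed = NULL)
      }
      expr <- log2_cpm(pb$counts)
      ann <- pb$annotations
      ann$detection_fraction <- colSums(pb$counts > 0) /
        max(colSums(pb$counts > 0))
      design <- hurdle_design(
        ann,
        terms = c("cell_cycle_phase", "lineage", "cell_cycle_phase:lineage",
                  "fraction_of_detected_genes"),
        reference_lineage = reference_lineage
      )
      fit <- hurdle_lrt(expr, design,
                        terms = paste0("contrast:", others))
      phase_diff <- lineage_phase_differences(expr, ann)
      for (i in seq_along(others)) {
        p <- fit$p_value[, i]
        ok <- !is.na(p)
        adjp[[i]][ok, perm] <- bh_adjust(p[ok])
        lfc[[i]][, perm] <- phase_diff[, others[i]] -
          phase_diff[, reference_lineage]
      }
    }
    out <- lapply(others, function(l) {
      tab <- summarize_permutations(genes, adjp[[l]], lfc[[l]], alpha,
                                    fc_threshold, n_permutations)
      cbind(tab[, "gene_id", drop = FALSE], lineage = l,
            tab[, -1, drop = FALSE])
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# Per-lineage phase difference of mean log2(CPM+1): genes x lineages.
lineage_phase_differences <- function(expr, ann) {
  lineages <- unique(as.character(ann$lineage))
  out <- sapply(lineages, function(l) {
    in_l <- ann$lineage == l
    g2 <- in_l & ann$phase == "G2M"
    g1 <- in_l & ann$phase == "G1"
    if (!any(g2) || !any(g1)) return(rep(NA_real_, nrow(expr)))
    rowMeans(expr[, g2, drop = FALSE]) - rowMeans(expr[, g1, drop = FALSE])
  })
  colnames(out) <- lineages
  out
}

#' Genotype comparison of phasic gene counts
#'
#' Within one lineage, compares how many genes are phasically expressed in a
#' control versus a mutant genotype on an equal footing: for each of
#' `n_resamples` draws, the same number of cells per phase is sampled from each
#' genotype, one pseudobulk pass (hurdle test of phase, BH within draw) is run
#' per genotype, and per-gene adjusted p-values are collected. Phasic calls use
#' the median adjusted p across resamples at `alpha` (default 0.1) with the
#' fold-change gate.
#'
#' @param control,mutant Lists with elements `counts` (`count_matrix`) and
#'   `annotations`, already QC- and gene-filtered, sharing a gene universe.
#' @param lineage Optional lineage to restrict both genotypes to.
#' @param n_resamples Number of equal-cell draws (default 100).
#' @param alpha Median adjusted-p threshold (default 0.1).
#' @inheritParams permuted_phasic_test
#' @return A list with per-genotype call tables (`control`, `mutant`), the call
#'   counts `n_control_calls` / `n_mutant_calls`, and `n_per_phase`, the common
#'   number of cells drawn per phase per genotype.
#' @export
compare_genotype_phasic <- function(control, mutant, lineage = NULL,
                                    n_resamples = 100, alpha = 0.1,
                                    fc_threshold = 1.1, pseudobulk_size = 10,
                                    seed = 1) {
  sets <- list(control = control, mutant = mutant)
  sets <- lapply(sets, function(s) {
    stopifnot(inherits(s$counts, "count_matrix"))
    if (!is.null(lineage)) {
      keep <- s$annotations$unit_id[s$annotations$lineage == lineage]
      if (length(keep) == 0) stop("lineage '", lineage, "' absent in a genotype")
      s$counts <- subset_counts(s$counts, units = match(keep, s$counts$unit_ids))
      s$annotations <- s$annotations[match(keep, s$annotations$unit_id), ,
                                     drop = FALSE]
    }
    s$phase <- normalize_phase(s$annotations$phase)
    s
  })
  if (!identical(sets$control$counts$gene_ids, sets$mutant$counts$gene_ids)) {
    stop("control and mutant must share an identical gene universe")
  }
  n_per_phase <- min(vapply(sets, function(s) min(table(s$phase)), numeric(1)))
  if (n_per_phase < 2 * pseudobulk_size) {
    warning("fewer than 2 pseudobulk samples per phase; comparison skipped")
    return(NULL)
  }
  genes <- sets$control$counts$gene_ids
  G <- length(genes)
  adjp <- lapply(sets, function(s) matrix(NA_real_, G, n_resamples))
  lfc <- lapply(sets, function(s) matrix(NA_real_, G, n_resamples))
  # each resample uses one derived seed shared by both genotypes, so the
  # comparison follows the same randomization path in control and mutant
  resample_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                               n_resamples))
  for (r in seq_len(n_resamples)) {
    for (nm in names(sets)) {
      s <- sets[[nm]]
      with_seed(resample_seeds[r], {
        draw <- unlist(lapply(c("G1", "G2M"), function(ph) {
          sample(s$annotations$unit_id[s$phase == ph], n_per_phase)
        }))
        cc <- subset_counts(s$counts, units = match(draw, s$counts$unit_ids))
        aa <- s$annotations[match(draw, s$annotations$unit_id), , drop = FALSE]
        pb <- make_pseudobulk(cc, aa, group_by = "phase",
                              size = pseudobulk_size, seed = NULL)
        res <- pseudobulk_phase_pass(pb)
        adjp[[nm]][, r] <- res$adj_p
        lfc[[nm]][, r] <- res$log2fc
      })
    }
  }
  tabs <- lapply(names(sets), function(nm) {
    summarize_permutations(genes, adjp[[nm]], lfc[[nm]], alpha, fc_threshold,
                           n_resamples)
  })
  names(tabs) <- names(sets)
  list(
    control = tabs$control,
    mutant = tabs$mutant,
    n_control_calls = sum(tabs$control$phasic_call, na.rm = TRUE),
    n_mutant_calls = sum(tabs$mutant$phasic_call, na.rm = TRUE),
    n_per_phase = n_per_phase
  )
}

#' Agreement between expression-based clustering and sorted phase
#'
#' 2-means clustering of cells on log2(CPM + 1) over a phasic gene panel,
#' scored as the fraction of cells whose cluster matches their DNA-content
#' phase under the better of the two cluster-to-phase mappings.
#'
#' @param counts A `count_matrix`.
#' @param annotations Per-cell annotations with `phase`.
#' @param phasic_genes Non-empty character vector of panel genes.
#' @param seed Seed for the k-means starts.
#' @return Agreement fraction in `[0.5, 1]`.
#' @export
panel_phase_clustering_check <- function(counts, annotations, phasic_genes,
                                         seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  phase <- normalize_phase(
    annotations$phase[match(counts$unit_ids, annotations$unit_id)]
  )
  if (any(table(phase) < 2)) stop("need at least 2 cells per phase")
  present <- intersect(phasic_genes, counts$gene_ids)
  if (length(present) == 0) stop("no panel gene present in the matrix")
  expr <- t(log2_cpm(counts)[present, , drop = FALSE])
  km <- with_seed(seed, stats::kmeans(expr, centers = 2, nstart = 10))
  match1 <- mean((km$cluster == 1) == (phase == "G1"))
  max(match1, 1 - match1)
}
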