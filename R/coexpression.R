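#' Canonical G1/S and G2/M phase gene panels
#'
#' The classic cell-cycle-regulated gene panels used to score phasic
#' co-expression structure in unsorted populations: 9 G1/S-transition genes and
#' 15 G2/M-transition genes (mouse symbols). Shipped as a TSV resource under
#' `extdata/phase_panels.tsv`.
#'
#' @return Named list with character vectors `G1S` and `G2M`.
#' @export
phase_panels <- function() {
  path <- system.file("extdata", "phase_panels.tsv", package = "phasic",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab$gene, factor(tab$panel, levels = c("G1S", "G2M")))
}

#' Pairwise co-expression of panel genes in one random cell cohort
#'
#' Draws `cohort_size` cells without replacement from one stage/group, computes
#' pairwise Pearson correlations of log2(CPM + 1) over the panel genes, and
#' summarizes the mean off-diagonal correlation within the G1/S panel, within
#' the G2/M panel, and between panels. In a population cycling asynchronously
#' with phasic expression, genes of the same transition correlate positively
#' and the two panels correlate negatively; without phasic structure all three
#' summaries sit near zero. Genes with zero variance within the cohort are
#' excluded from the summaries and flagged.
#'
#' @param counts A `count_matrix`.
#' @param annotations Per-cell annotations (`unit_id`, optionally `stage`,
#'   grouping column).
#' @param stage Optional stage label to subset to.
#' @param group Optional group label (e.g. germ layer) to subset to.
#' @param group_col Annotation column holding the group (default `"lineage"`).
#' @param panels Panel list as from [phase_panels()].
#' @param cohort_size Cells per cohort (default 50).
#' @param seed Seed for the draw; `NULL` uses the current stream.
#' @return A list of class `cohort_correlation`: `stage`, `group`,
#'   `cohort_cells`, `corr` (symmetric matrix over present panel genes),
#'   `mean_within_G1S`, `mean_within_G2M`, `mean_between`, `constant_genes`.
#' @export
cohort_correlation <- function(counts, annotations, stage = NULL, group = NULL,
                               group_col = "lineage", panels = phase_panels(),
                               cohort_size = 50, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[match(counts$unit_ids, annotations$unit_id), , drop = FALSE]
  sel <- rep(TRUE, nrow(ann))
  if (!is.null(stage)) sel <- sel & ann$stage == stage
  if (!is.null(group)) sel <- sel & ann[[group_col]] == group
  ids <- ann$unit_id[sel]
  if (length(ids) < cohort_size) {
    stop(sprintf("group '%s' (stage %s) has %d cells, fewer than cohort_size %d",
                 group %||% "all", stage %||% "all", length(ids), cohort_size))
  }
  with_seed(seed, {
    cohort <- sample(ids, cohort_size)
    panel_genes <- unique(unlist(panels))
    present <- intersect(panel_genes, counts$gene_ids)
    if (length(setdiff(panel_genes, present))) {
      warning("panel gene(s) absent from matrix: ",
              paste(setdiff(panel_genes, present), collapse = ", "))
    }
    sub <- subset_counts(counts, units = match(cohort, counts$unit_ids))
    expr <- log2_cpm(sub)[present, , drop = FALSE]
    sds <- apply(expr, 1, stats::sd)
    constant <- rownames(expr)[sds == 0]
    corr <- suppressWarnings(stats::cor(t(expr)))
    usable <- setdiff(present, constant)
    mean_block <- function(a, b) {
      a <- intersect(a, usable)
      b <- intersect(b, usable)
      if (length(a) == 0 || length(b) == 0) return(NA_real_)
      blk <- corr[a, b, drop = FALSE]
      if (identical(a, b)) {
        if (length(a) < 2) return(NA_real_)
        mean(blk[upper.tri(blk)])
      } else {
        mean(blk)
      }
    }
    structure(
      list(
        stage = stage, group = group, cohort_cells = cohort, corr = corr,
        mean_within_G1S = mean_block(panels$G1S, panels$G1S),
        mean_within_G2M = mean_block(panels$G2M, panels$G2M),
        mean_between = mean_block(panels$G1S, panels$G2M),
        constant_genes = constant
      ),
      class = "cohort_correlation"
    )
  })
}

#' Co-expression summaries across developmental stages
#'
#' Repeats [cohort_correlation()] `n_cohorts` times per stage (within an
#' optional group) and returns the summary correlations in long form, enabling
#' comparison of how within-panel co-expression strengthens across stages.
#'
#' @inheritParams cohort_correlation
#' @param stages Ordered character vector of stage labels.
#' @param n_cohorts Cohorts drawn per stage (default 20).
#' @param seed Seed controlling all draws.
#' @return data.frame with `stage`, `cohort`, `mean_within_G1S`,
#'   `mean_within_G2M`, `mean_between`.
#' @export
coexpression_trend <- function(counts, annotations, stages, group = NULL,
                               group_col = "lineage", panels = phase_panels(),
                               n_cohorts = 20, cohort_size = 50, seed = 1) {
  with_seed(seed, {
    out <- list()
    for (st in stages) {
      for (i in seq_len(n_cohorts)) {
        cc <- cohort_correlation(counts, annotations, stage = st,
                                 group = group, group_col = group_col,
                                 panels = panels, cohort_size = cohort_size,
                                 seed = NULL)
        out[[length(out) + 1L]] <- data.frame(
          stage = st, cohort = i,
          mean_within_G1S = cc$mean_within_G1S,
          mean_within_G2M = cc$mean_within_G2M,
          mean_between = cc$mean_between,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
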