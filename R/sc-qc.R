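#' Quality-control filter for single cells
#'
#' Applies the three cell-level rules in order: (1) total UMI >= `min_umi`
#' (default 5000), (2) mitochondrial read fraction < `max_mito_fraction`
#' (default 5%), (3) detected-gene count at least `min_rel_detection` (default
#' 40%) of the most gene-rich cell among cells surviving the first two rules.
#' The detection fraction in the returned annotations is recomputed on the
#' survivors.
#'
#' @param counts A `count_matrix` of UMI counts.
#' @param annotations Per-cell annotations with `unit_id` (QC fields are
#'   recomputed here, so they need not be present).
#' @param config A `pipeline_config` supplying the thresholds.
#' @return List with the filtered `counts`, the filtered/updated `annotations`,
#'   and `removed` (data.frame of removed cell ids and the rule that removed
#'   them).
#' @export
qc_filter_cells <- function(counts, annotations, config = pipeline_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotate_qc(annotations, counts, mito_prefix = config$mito_prefix)
  fail_umi <- ann$total_umi < config$min_umi
  fail_mito <- !fail_umi & ann$mito_fraction >= config$max_mito_fraction
  surv12 <- !(fail_umi | fail_mito)
  rel <- ann$n_detected_genes / max(ann$n_detected_genes[surv12], 1)
  fail_det <- surv12 & rel < config$min_rel_detection
  keep <- surv12 & !fail_det
  if (!any(keep)) stop("no cells survive QC; review thresholds")
  removed <- data.frame(
    unit_id = ann$unit_id[!keep],
    rule = c("min_umi", "max_mito_fraction", "min_rel_detection")[
      max.col(cbind(fail_umi, fail_mito, fail_det)[!keep, , drop = FALSE],
              ties.method = "first")
    ],
    stringsAsFactors = FALSE
  )
  out_counts <- subset_counts(counts, units = which(keep))
  out_ann <- annotate_qc(ann[keep, setdiff(names(ann), c(
    "total_umi", "n_detected_genes", "mito_fraction", "detection_fraction"
  )), drop = FALSE], out_counts, mito_prefix = config$mito_prefix)
  list(counts = out_counts, annotations = out_ann, removed = removed)
}

#' Gene detection filter for single-cell matrices
#'
#' Retains genes detected (count > 0) in at least `min_cell_fraction` of all
#' cells (default 20%); genes expressed in fewer cells are removed.
#'
#' @param counts A `count_matrix` (cells already QC-filtered).
#' @param min_cell_fraction Minimum detection fraction across cells.
#' @return The filtered `count_matrix`.
#' @export
filter_genes_sc <- function(counts, min_cell_fraction = 0.20) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- rowMeans(counts$counts > 0) >= min_cell_fraction
  subset_counts(counts, genes = which(keep))
}

#' Down-sample to equal phase sizes within each lineage
#'
#' Within every lineage, a random subset of the larger phase is taken so both
#' phases contribute the same number of cells. A lineage missing one phase is
#' dropped with a warning.
#'
#' @param annotations Per-cell annotations with `unit_id`, `phase` and
#'   optionally `lineage` (absent: all cells form one lineage).
#' @param seed Seed for the subsetting; `NULL` uses the current RNG stream.
#' @return Character vector of retained cell ids.
#' @export
downsample_equal_phase <- function(annotations, seed = NULL) {
  with_seed(seed, {
    lin <- if ("lineage" %in% names(annotations)) {
      as.character(annotations$lineage)
    } else {
      rep("all", nrow(annotations))
    }
    phase <- normalize_phase(annotations$phase)
    keep <- character(0)
    for (l in unique(lin)) {
      in_l <- lin == l
      g1 <- annotations$unit_id[in_l & phase == "G1"]
      g2 <- annotations$unit_id[in_l & phase == "G2M"]
      if (length(g1) == 0 || length(g2) == 0) {
        warning("lineage '", l, "' lacks one phase; dropped")
        next
      }
      k <- min(length(g1), length(g2))
      keep <- c(keep,
                if (length(g1) > k) sample(g1, k) else g1,
                if (length(g2) > k) sample(g2, k) else g2)
    }
    if (length(keep) == 0) stop("no lineage retains both phases")
    keep
  })
}
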