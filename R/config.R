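#' Pipeline configuration
#'
#' Bundles every tunable threshold of the bulk and single-cell pipelines with its
#' default. Defaults follow the published analysis: a 5000-UMI floor per cell, a 5%
#' mitochondrial ceiling, a 40% relative-detection floor, a 20% gene detection
#' floor, pseudobulk samples of 10 same-phase cells, 100 pseudobulk permutations,
#' a 1.1 fold-change gate on log2 expression, a 5 CPM bulk expression filter,
#' adjusted-p thresholds of 0.1 (bulk, genotype comparisons) and 0.05 (within-
#' lineage single-cell calls), 100 genotype resamples, 50-cell co-expression
#' cohorts, and a 1e-12 KS threshold for phase-specific activity.
#'
#' @param min_umi Minimum UMI per retained cell.
#' @param max_mito_fraction Maximum mitochondrial read fraction per cell.
#' @param min_rel_detection Minimum detected-gene fraction relative to the cell
#'   with the most detected genes.
#' @param min_gene_cell_fraction Minimum fraction of cells a retained gene must be
#'   detected in.
#' @param pseudobulk_size Cells summed per pseudobulk sample.
#' @param n_permutations Pseudobulk permutations per call.
#' @param fc_threshold Fold-change gate (ratio > 1) applied on the log2 scale as
#'   `|log2fc| > log2(fc_threshold)`.
#' @param bulk_min_cpm Bulk CPM expression filter.
#' @param alpha_bulk Adjusted-p threshold for bulk calls.
#' @param alpha_sc Adjusted-p threshold for single-cell within-lineage calls.
#' @param genotype_resamples Equal-cell resamples per genotype comparison.
#' @param cohort_size Cells per co-expression cohort.
#' @param ks_threshold p-value threshold for phase-specific activity scores.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @param rng_seed Seed used by stochastic operations unless overridden.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_umi = 5000,
                            max_mito_fraction = 0.05,
                            min_rel_detection = 0.40,
                            min_gene_cell_fraction = 0.20,
                            pseudobulk_size = 10,
                            n_permutations = 100,
                            fc_threshold = 1.1,
                            bulk_min_cpm = 5,
                            alpha_bulk = 0.1,
                            alpha_sc = 0.05,
                            genotype_resamples = 100,
                            cohort_size = 50,
                            ks_threshold = 1e-12,
                            mito_prefix = "mt-",
                            rng_seed = 1) {
  cfg <- list(
    min_umi = min_umi, max_mito_fraction = max_mito_fraction,
    min_rel_detection = min_rel_detection,
    min_gene_cell_fraction = min_gene_cell_fraction,
    pseudobulk_size = pseudobulk_size, n_permutations = n_permutations,
    fc_threshold = fc_threshold, bulk_min_cpm = bulk_min_cpm,
    alpha_bulk = alpha_bulk, alpha_sc = alpha_sc,
    genotype_resamples = genotype_resamples, cohort_size = cohort_size,
    ks_threshold = ks_threshold, mito_prefix = mito_prefix,
    rng_seed = as.integer(rng_seed)
  )
  for (nm in c("min_umi", "pseudobulk_size", "n_permutations", "bulk_min_cpm",
               "genotype_resamples", "cohort_size", "ks_threshold",
               "alpha_bulk", "alpha_sc")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be strictly positive")
  }
  for (nm in c("max_mito_fraction", "min_rel_detection", "min_gene_cell_fraction")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) stop(nm, " must be in (0, 1)")
  }
  if (cfg$fc_threshold <= 1) stop("fc_threshold must be > 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror [pipeline_config()] argument names exactly; unknown keys
#' are an error, absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Evaluate code under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
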