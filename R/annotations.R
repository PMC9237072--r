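#' Normalize cell-cycle phase labels
#'
#' Phase-sorted data arrive with either spelling of the second phase; `"G2/M"`,
#' `"G2M"` and case variants all normalize to `"G2M"`, `"G1"` variants to `"G1"`.
#'
#' @param x Character vector of phase labels.
#' @return Factor with levels `c("G1", "G2M")`.
#' @export
normalize_phase <- function(x) {
  key <- gsub("[/ _-]", "", tolower(as.character(x)))
  out <- ifelse(key == "g1", "G1", ifelse(key %in% c("g2m", "g2"), "G2M", NA))
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf(
      "unknown phase label(s) %s at row(s) %s; expected G1 or G2/M",
      paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  factor(out, levels = c("G1", "G2M"))
}

#' Read per-unit annotations
#'
#' Reads a TSV of per-cell or per-sample metadata. `unit_id` and `phase` are
#' required; `lineage`, `genotype`, `stage` and `replicate` are kept when present.
#' Phase labels are normalized via [normalize_phase()]. QC-derived fields
#' (`total_umi`, `n_detected_genes`, `mito_fraction`, `detection_fraction`) are not
#' computed here; see [annotate_qc()].
#'
#' @param path TSV path with a header row.
#' @return A data.frame of annotations, one row per unit.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("unit_id", "phase")) {
    if (!col %in% names(tab)) stop("annotations missing required column: ", col)
  }
  tab$unit_id <- as.character(tab$unit_id)
  if (anyDuplicated(tab$unit_id)) stop("duplicated unit_id values in ", path)
  tab$phase <- normalize_phase(tab$phase)
  tab
}

#' Write per-unit annotations
#'
#' @param annotations Annotation data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute QC fields against a count matrix
#'
#' Adds the derived per-unit fields used by the single-cell QC rules: total UMI,
#' number of detected genes, mitochondrial fraction (over genes matching
#' `mito_prefix`), and the detection fraction relative to the unit with the most
#' detected genes.
#'
#' @param annotations Annotation data.frame with `unit_id`.
#' @param counts A `count_matrix` covering the same units.
#' @param mito_prefix Prefix identifying mitochondrial genes (default `"mt-"`).
#' @return The annotation data.frame with QC columns added, ordered as the count
#'   matrix columns.
#' @export
annotate_qc <- function(annotations, counts, mito_prefix = "mt-") {
  stopifnot(inherits(counts, "count_matrix"))
  idx <- match(counts$unit_ids, annotations$unit_id)
  if (anyNA(idx)) {
    stop("annotations missing unit(s): ",
         paste(utils::head(counts$unit_ids[is.na(idx)], 5), collapse = ", "))
  }
  ann <- annotations[idx, , drop = FALSE]
  m <- counts$counts
  ann$total_umi <- colSums(m)
  ann$n_detected_genes <- colSums(m > 0)
  mito <- startsWith(counts$gene_ids, mito_prefix)
  ann$mito_fraction <- if (any(mito)) {
    colSums(m[mito, , drop = FALSE]) / pmax(ann$total_umi, 1)
  } else {
    rep(0, ncol(m))
  }
  ann$detection_fraction <- ann$n_detected_genes / max(ann$n_detected_genes)
  rownames(ann) <- NULL
  ann
}
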