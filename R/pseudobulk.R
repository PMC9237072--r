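#' Aggregate cells into pseudobulk samples
#'
#' Within each group (by default phase and, when present, lineage), cells are
#' shuffled and partitioned into disjoint blocks of exactly `size` cells whose
#' UMI counts are summed; leftover cells (fewer than `size`) are dropped for
#' this draw and recorded. Summing ten same-phase, same-lineage cells mitigates
#' droplet dropout while preserving exact count conservation: per gene, the
#' pseudobulk totals plus the dropped cells' counts equal the input totals.
#'
#' @param counts A `count_matrix` of UMI counts.
#' @param annotations Per-cell annotations with `unit_id`, `phase`, optionally
#'   `lineage`.
#' @param group_by Columns defining aggregation groups (default `"phase"` plus
#'   `"lineage"` when available).
#' @param size Cells per pseudobulk sample.
#' @param seed Seed for the shuffle; `NULL` draws from the current RNG stream
#'   (used by the permutation loops).
#' @return A list of class `pseudobulk_set`: `counts` (genes x samples matrix),
#'   `annotations` (per-sample phase/lineage/`n_cells`), `members` (list of
#'   member cell ids per sample), `dropped` (cell ids unused this draw),
#'   `size`.
#' @export
make_pseudobulk <- function(counts, annotations, group_by = NULL, size = 10,
                            seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[match(counts$unit_ids, annotations$unit_id), , drop = FALSE]
  if (anyNA(ann$unit_id)) stop("annotations missing cells present in counts")
  if (is.null(group_by)) {
    group_by <- c("phase", if ("lineage" %in% names(ann) &&
                               length(unique(ann$lineage)) >= 1) "lineage")
  }
  with_seed(seed, {
    assign_tab <- pseudobulk_blocks(ann, group_by, size)
    build_pseudobulk(counts, ann, assign_tab, size)
  })
}

# Partition cells into blocks within each group; returns a data.frame
# (unit_id, sample_id, phase[, lineage]) for assigned cells.
pseudobulk_blocks <- function(ann, group_by, size) {
  key <- interaction(ann[group_by], drop = TRUE, sep = "|")
  out <- list()
  for (g in levels(key)) {
    ids <- ann$unit_id[key == g]
    n_blocks <- floor(length(ids) / size)
    if (n_blocks == 0) {
      warning("group '", g, "' has fewer than ", size, " cells; skipped")
      next
    }
    ids <- sample(ids)
    used <- ids[seq_len(n_blocks * size)]
    out[[g]] <- data.frame(
      unit_id = used,
      sample_id = paste0(g, "|pb", rep(seq_len(n_blocks), each = size)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) stop("no group reaches the pseudobulk size")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

build_pseudobulk <- function(counts, ann, assign_tab, size) {
  cell_idx <- match(assign_tab$unit_id, counts$unit_ids)
  sample_ids <- unique(assign_tab$sample_id)
  M <- Matrix::sparseMatrix(
    i = cell_idx,
    j = match(assign_tab$sample_id, sample_ids),
    x = 1,
    dims = c(ncol(counts$counts), length(sample_ids))
  )
  pb <- as.matrix(counts$counts %*% M)
  dimnames(pb) <- list(counts$gene_ids, sample_ids)
  first <- assign_tab[!duplicated(assign_tab$sample_id), , drop = FALSE]
  ann_first <- ann[match(first$unit_id, ann$unit_id), , drop = FALSE]
  pb_ann <- data.frame(
    unit_id = sample_ids,
    phase = normalize_phase(ann_first$phase),
    stringsAsFactors = FALSE
  )
  if ("pb_lineage" %in% names(assign_tab)) {
    pb_ann$lineage <- first$pb_lineage
  } else if ("lineage" %in% names(ann)) {
    pb_ann$lineage <- as.character(ann_first$lineage)
  }
  pb_ann$n_cells <- size
  structure(
    list(
      counts = pb,
      annotations = pb_ann,
      members = split(assign_tab$unit_id, assign_tab$sample_id)[sample_ids],
      dropped = setdiff(counts$unit_ids, assign_tab$unit_id),
      size = size
    ),
    class = "pseudobulk_set"
  )
}

#' Scrambled-lineage pseudobulk (empirical negative control)
#'
#' Blocks are drawn within phase but ignoring lineage, so each pseudobulk
#' sample mixes cells of different lineages; lineage labels are then assigned
#' so that the number of pseudobulk samples per (phase, lineage) exactly
#' matches the matched-lineage construction, keeping statistical power equal
#' between the actual and scrambled analyses. With a single lineage this
#' reduces to [make_pseudobulk()] in distribution.
#'
#' @inheritParams make_pseudobulk
#' @return A `pseudobulk_set` (see [make_pseudobulk()]).
#' @export
scramble_lineage_pseudobulk <- function(counts, annotations, size = 10,
                                        seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[match(counts$unit_ids, annotations$unit_id), , drop = FALSE]
  if (!"lineage" %in% names(ann)) stop("annotations lack a lineage column")
  with_seed(seed, {
    phase <- normalize_phase(ann$phase)
    out <- list()
    for (ph in levels(droplevels(phase))) {
      in_ph <- phase == ph
      # matched-construction sample counts per lineage
      tab <- table(as.character(ann$lineage[in_ph]))
      n_blocks <- floor(tab / size)
      n_blocks <- n_blocks[n_blocks > 0]
      if (length(n_blocks) == 0) next
      total <- sum(n_blocks)
      ids <- sample(ann$unit_id[in_ph])
      used <- ids[seq_len(total * size)]
      lin_lab <- rep(rep(names(n_blocks), n_blocks), each = size)
      out[[ph]] <- data.frame(
        unit_id = used,
        sample_id = paste0(ph, "|", rep(rep(names(n_blocks), n_blocks),
                                        each = size), "|spb",
                           rep(seq_len(total), each = size)),
        pb_lineage = lin_lab,
        stringsAsFactors = FALSE
      )
    }
    if (length(out) == 0) stop("no group reaches the pseudobulk size")
    assign_tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    build_pseudobulk(counts, ann, assign_tab, size)
  })
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf(
    "pseudobulk_set: %d samples of %d cells (%d genes, %d cells dropped)\n",
    ncol(x$counts), x$size, nrow(x$counts), length(x$dropped)
  ))
  invisible(x)
}
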