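#' Write a phasic call table
#'
#' Serializes a per-gene result table as TSV with a stable column order:
#' `gene_id` first, then the remaining columns in their existing order. Missing
#' values are written as literal `NA` so the file round-trips.
#'
#' @param table Non-empty data.frame with a `gene_id` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) stop("result table is empty")
  if (!"gene_id" %in% names(table)) stop("result table must have a gene_id column")
  table <- table[, c("gene_id", setdiff(names(table), "gene_id")), drop = FALSE]
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a phasic call table written by [write_results()]
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab$gene_id <- as.character(tab$gene_id)
  tab
}
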