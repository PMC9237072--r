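#' Construct a validated count matrix
#'
#' The package stores expression counts as genes-in-rows regardless of on-disk
#' orientation. A `count_matrix` wraps a base integer matrix with unique gene and
#' unit (cell or sample) labels and a layer tag distinguishing UMI, exonic and
#' intronic counts.
#'
#' @param counts Numeric matrix of non-negative integers, genes x units, with
#'   rownames (gene ids) and colnames (unit ids).
#' @param layer_name One of `"umi"`, `"exon"`, `"intron"`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `unit_ids`, `layer_name`.
#' @export
count_matrix <- function(counts, layer_name = c("umi", "exon", "intron")) {
  layer_name <- match.arg(layer_name)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and unit ids as colnames")
  }
  x <- structure(
    list(
      counts = counts,
      gene_ids = rownames(counts),
      unit_ids = colnames(counts),
      layer_name = layer_name
    ),
    class = "count_matrix"
  )
  validate_count_matrix(x)
  canonicalize_counts(x)
}

#' Validate a count matrix
#'
#' Enforces the container invariants: no negative or fractional entries, unique
#' labels matching the matrix dimensions.
#'
#' @param x A `count_matrix`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_count_matrix <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.numeric(m)) stop("counts must be numeric")
  if (anyNA(m)) stop("counts contain missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative count at gene '%s', unit '%s'",
      x$gene_ids[bad[1]], x$unit_ids[bad[2]]
    ))
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-integer count at gene '%s', unit '%s'",
      x$gene_ids[bad[1]], x$unit_ids[bad[2]]
    ))
  }
  if (anyDuplicated(x$gene_ids)) stop("duplicated gene ids")
  if (anyDuplicated(x$unit_ids)) stop("duplicated unit ids")
  if (length(x$gene_ids) != nrow(m) || length(x$unit_ids) != ncol(m)) {
    stop("label lengths do not match matrix dimensions")
  }
  invisible(x)
}

# canonical integer storage once validated (keeps round-trips bit-identical)
canonicalize_counts <- function(x) {
  if (is.double(x$counts) && max(x$counts) < .Machine$integer.max) {
    storage.mode(x$counts) <- "integer"
  }
  x
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix [%s]: %d genes x %d units, %s total counts\n",
    x$layer_name, nrow(x$counts), ncol(x$counts),
    format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param genes,units Character, logical or integer index vectors; `NULL` keeps all.
#' @return The subsetted `count_matrix`.
#' @export
subset_counts <- function(x, genes = NULL, units = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(units)) m <- m[, units, drop = FALSE]
  count_matrix(m, x$layer_name)
}

mtx_companions <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(genes = paste0(base, "-genes.txt"), units = paste0(base, "-units.txt"))
}

#' Read a count matrix from disk
#'
#' Two on-disk formats are supported. `"tsv"` is a dense tab-separated table whose
#' first column holds gene ids and whose header row holds unit ids. `"mtx"` is a
#' Matrix Market coordinate file with two companion one-label-per-line files
#' (`<base>-genes.txt`, `<base>-units.txt` by default). MTX files stored in either
#' orientation are accepted: the companion label files disambiguate, and matrices
#' arriving units-x-genes are transposed so genes are always rows in memory.
#'
#' @param path File path (for `"mtx"`, the `.mtx` file).
#' @param format `"tsv"` or `"mtx"`.
#' @param layer_name Layer tag, see [count_matrix()].
#' @param genes_file,units_file Optional explicit label-file paths for MTX input.
#' @return A validated `count_matrix`.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              layer_name = "umi",
                              genes_file = NULL, units_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed TSV (need gene id column plus >=1 unit): ", path)
    gene_ids <- as.character(tab[[1]])
    if (anyDuplicated(gene_ids)) stop("duplicated gene ids in ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                   arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric entry near line %d of %s", bad[1] + 1L, path))
    }
    rownames(m) <- gene_ids
    return(count_matrix(m, layer_name))
  }
  comp <- mtx_companions(path)
  genes_file <- genes_file %||% comp$genes
  units_file <- units_file %||% comp$units
  for (f in c(genes_file, units_file)) {
    if (!file.exists(f)) stop("missing MTX companion label file: ", f)
  }
  gene_ids <- readLines(genes_file)
  unit_ids <- readLines(units_file)
  m <- as.matrix(Matrix::readMM(path))
  if (nrow(m) == length(gene_ids) && ncol(m) == length(unit_ids)) {
    # genes x units as stored
  } else if (nrow(m) == length(unit_ids) && ncol(m) == length(gene_ids)) {
    m <- t(m)
  } else {
    stop(sprintf(
      "MTX dimensions %dx%d match neither %d genes x %d units nor the transpose",
      nrow(m), ncol(m), length(gene_ids), length(unit_ids)
    ))
  }
  dimnames(m) <- list(gene_ids, unit_ids)
  count_matrix(m, layer_name)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]; TSV output has the gene id column named
#' `gene_id`, MTX output is written genes-x-units with the two companion label
#' files alongside.
#'
#' @param x A `count_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_count_matrix(x)
  if (format == "tsv") {
    tab <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    comp <- mtx_companions(path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, comp$genes)
    writeLines(x$unit_ids, comp$units)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
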