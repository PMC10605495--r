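#' Expression dataset container
#'
#' Bundles a cells x genes count (or normalized) matrix with per-cell
#' metadata (cell type, sample of origin) and per-sample binary disease
#' labels. Disease state lives on samples — patients are labeled, their
#' cells inherit the label.
#'
#' @param dataset_id short label, e.g. "D1".
#' @param counts cells x genes matrix (dense or `Matrix` sparse),
#'   non-negative; rows cells, columns genes.
#' @param gene_ids,cell_ids ordered unique identifiers matching the matrix
#'   dimensions.
#' @param cell_type,sample_id per-cell character vectors.
#' @param disease_state named binary vector (1 = disease, 0 = healthy),
#'   names = sample ids.
#' @param normalized logical; `TRUE` only after [normalize_log1p()].
#' @return an `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, counts, gene_ids, cell_ids,
                               cell_type, sample_id, disease_state,
                               normalized = FALSE) {
  counts <- to_csparse(counts)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop_classed("sigtransfer_validation",
                 "matrix is %d x %d but there are %d cells and %d genes",
                 nrow(counts), ncol(counts),
                 length(cell_ids), length(gene_ids))
  if (nrow(counts) == 0)
    stop_classed("sigtransfer_validation", "dataset has no cells")
  if (anyDuplicated(gene_ids))
    stop_classed("sigtransfer_validation", "duplicate gene id: %s",
                 gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(cell_ids))
    stop_classed("sigtransfer_validation", "duplicate cell id: %s",
                 cell_ids[duplicated(cell_ids)][1])
  if (length(cell_type) != length(cell_ids) ||
      length(sample_id) != length(cell_ids))
    stop_classed("sigtransfer_validation",
                 "cell metadata length disagrees with the cell count")
  if (min(counts@x, 0) < 0)
    stop_classed("sigtransfer_validation", "negative matrix entries")
  unknown <- setdiff(unique(sample_id), names(disease_state))
  if (length(unknown))
    stop_classed("sigtransfer_validation",
                 "cell references unknown sample: %s", unknown[1])
  if (!all(disease_state %in% c(0, 1)))
    stop_classed("sigtransfer_validation",
                 "disease_state must be binary 0/1")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(dataset_id = dataset_id,
                 counts = counts,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 cell_type = as.character(cell_type),
                 sample_id = as.character(sample_id),
                 disease_state = disease_state,
                 normalized = isTRUE(normalized)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d cells x %d genes, %d samples%s\n",
              x$dataset_id, length(x$cell_ids), length(x$gene_ids),
              length(x$disease_state),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

read_tsv_strict <- function(path, cols) {
  if (!file.exists(path))
    stop_classed("sigtransfer_validation", "missing file: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "%", stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_classed("sigtransfer_validation", "%s lacks column(s): %s",
                 basename(path), paste(miss, collapse = ", "))
  df
}

#' Read an expression dataset from a directory
#'
#' Expects `matrix.mtx` (Matrix Market coordinate, genes x cells as written
#' by [write_dataset()]), `genes.tsv` (`gene_id`), `cells.tsv` (`cell_id`,
#' `cell_type`, `sample_id`) and `samples.tsv` (`sample_id`,
#' `disease_state`). Matrix Market 1-based indices are handled by the
#' reader; readers tolerate CRLF line ends and '%' comment lines.
#'
#' @param path directory holding the four files.
#' @param dataset_id label for the dataset; defaults to the directory name.
#' @return an `expression_dataset` (raw counts, not normalized).
#' @export
read_dataset <- function(path, dataset_id = basename(normalizePath(path))) {
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx))
    stop_classed("sigtransfer_validation", "missing file: %s", mtx)
  m <- Matrix::readMM(mtx)               # genes x cells on disk
  genes <- read_tsv_strict(file.path(path, "genes.tsv"), "gene_id")
  cells <- read_tsv_strict(file.path(path, "cells.tsv"),
                           c("cell_id", "cell_type", "sample_id"))
  samples <- read_tsv_strict(file.path(path, "samples.tsv"),
                             c("sample_id", "disease_state"))
  if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells))
    stop_classed("sigtransfer_validation",
                 "matrix.mtx is %d x %d but genes.tsv has %d rows and cells.tsv %d",
                 nrow(m), ncol(m), nrow(genes), nrow(cells))
  ds <- stats::setNames(as.numeric(samples$disease_state),
                        as.character(samples$sample_id))
  expression_dataset(dataset_id,
                     counts = Matrix::t(m),
                     gene_ids = genes$gene_id,
                     cell_ids = cells$cell_id,
                     cell_type = cells$cell_type,
                     sample_id = cells$sample_id,
                     disease_state = ds)
}

#' Write an expression dataset to a directory
#'
#' Inverse of [read_dataset()]; lossless for integer counts. The matrix is
#' stored genes x cells in Matrix Market coordinate format (the common
#' on-disk convention for single-cell counts), with TSV sidecars for genes,
#' cells and samples.
#'
#' @param ds an `expression_dataset`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop_classed("sigtransfer_io", "cannot create directory: %s", path)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = ds$gene_ids),
                     file.path(path, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(cell_id = ds$cell_ids,
                                cell_type = ds$cell_type,
                                sample_id = ds$sample_id),
                     file.path(path, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample_id = names(ds$disease_state),
                                disease_state = as.integer(ds$disease_state)),
                     file.path(path, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Library-size normalization followed by log1p
#'
#' Scales each cell's counts to a common total (`target_sum`, default 1e4),
#' then applies `log(1 + x)`. Cells with zero total counts are left as
#' all-zero rows. This is the standard single-cell preprocessing applied
#' identically to all datasets so that cross-dataset feature scales stay
#' comparable — a requirement of the transfer design.
#'
#' @param ds an `expression_dataset` with raw counts.
#' @param target_sum per-cell total after scaling.
#' @return a normalized `expression_dataset`.
#' @export
normalize_log1p <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$normalized)
    stop_classed("sigtransfer_contract", "dataset is already normalized")
  totals <- Matrix::rowSums(ds$counts)
  sf <- ifelse(totals > 0, target_sum / totals, 0)
  m <- to_csparse(Matrix::Diagonal(x = sf) %*% ds$counts)
  m@x <- log1p(m@x)
  out <- ds
  out$counts <- m
  dimnames(out$counts) <- list(ds$cell_ids, ds$gene_ids)
  out$normalized <- TRUE
  out
}

#' Cell-type slice of a dataset
#'
#' Extracts the cells of one type together with their inherited binary
#' disease labels, as the feature matrix a per-cell-type classifier is
#' trained or tested on.
#'
#' @param ds a normalized `expression_dataset`.
#' @param cell_type cell-type label to extract.
#' @param positive_class which sample label is scored as the positive
#'   class: `"disease"` (default; labels pass through) or `"healthy"`
#'   (labels are flipped).
#' @return a `cell_type_slice`: `dataset_id`, `cell_type`, `X` (cells x
#'   genes dense-compatible sparse matrix), `labels`, `gene_ids`.
#' @export
slice_cell_type <- function(ds, cell_type,
                            positive_class = c("disease", "healthy")) {
  stopifnot(inherits(ds, "expression_dataset"))
  positive_class <- match.arg(positive_class)
  if (!ds$normalized)
    stop_classed("sigtransfer_contract",
                 "normalize the dataset before slicing")
  idx <- which(ds$cell_type == cell_type)
  if (!length(idx))
    stop_classed("sigtransfer_lookup",
                 "cell type '%s' absent; available: %s", cell_type,
                 paste(sort(unique(ds$cell_type)), collapse = ", "))
  labels <- as.numeric(ds$disease_state[ds$sample_id[idx]])
  if (positive_class == "healthy") labels <- 1 - labels
  structure(list(dataset_id = ds$dataset_id,
                 cell_type = cell_type,
                 X = ds$counts[idx, , drop = FALSE],
                 labels = labels,
                 gene_ids = ds$gene_ids),
            class = "cell_type_slice")
}
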