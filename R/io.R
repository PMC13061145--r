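#' Construct a validated count matrix
#'
#' The pipeline's main carrier is a plain numeric matrix of non-negative
#' integer counts with genes as rows and samples as columns. This helper
#' enforces the container invariants once, so downstream code can assume
#' them.
#'
#' @param values numeric matrix, genes x samples, non-negative integers.
#' @param gene_ids unique gene symbols (defaults to `rownames(values)`).
#' @param sample_ids unique sample identifiers (defaults to `colnames(values)`).
#' @return the matrix with validated dimnames.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames inconsistent with matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (any(values < 0)) stop("counts must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read / write a count matrix as TSV
#'
#' Genes are rows; the first column (`gene_id`) holds gene symbols and the
#' header carries sample identifiers.
#'
#' @param counts count matrix (see [count_matrix()]).
#' @param path file path.
#' @return `read_counts_tsv` returns a validated count matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(m, gene_ids = df[[1]], sample_ids = colnames(df)[-1])
}

#' Read / write a count matrix as MatrixMarket
#'
#' Writes `<path>` (MTX), plus sidecar files `<path>.genes.txt` and
#' `<path>.samples.txt` holding the row and column identifiers, one per line.
#'
#' @inheritParams write_counts_tsv
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".genes.txt"))
  writeLines(colnames(counts), paste0(path, ".samples.txt"))
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  count_matrix(m,
               gene_ids = readLines(paste0(path, ".genes.txt")),
               sample_ids = readLines(paste0(path, ".samples.txt")))
}

#' Read / write sample metadata as CSV
#'
#' @param metadata data.frame with at least a `sample_id` column.
#' @param path file path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must contain sample_id")
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  df
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param gene_sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector parallel to `gene_sets`.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT lines (need name, description, >=1 gene): ",
         paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write an interaction edge list as 3-column TSV
#'
#' Columns are `node1`, `node2`, `combined_score` (STRING-style).
#'
#' @param edges data.frame with columns node1, node2, combined_score.
#' @param path file path.
#' @export
write_string_edges <- function(edges, path) {
  utils::write.table(edges[, c("node1", "node2", "combined_score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cell-type reference expression matrix as TSV
#'
#' Cell types are rows (first column `cell_type`), genes are columns.
#'
#' @param reference numeric matrix, cell types x genes.
#' @param path file path.
#' @export
write_reference_tsv <- function(reference, path) {
  df <- data.frame(cell_type = rownames(reference), reference,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_tsv
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("reference expression must be non-negative")
  m
}

#' Read / write a qPCR Ct table as CSV
#'
#' Long format: `sample_id`, `gene`, `ct`.
#'
#' @param ct_table data.frame with columns sample_id, gene, ct.
#' @param path file path.
#' @export
write_ct_csv <- function(ct_table, path) {
  utils::write.csv(ct_table[, c("sample_id", "gene", "ct")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(df))) stop("Ct table needs sample_id, gene, ct")
  df
}
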