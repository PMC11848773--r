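# Readers/writers for the plain-text interchange formats: TSV counts, CSV
# sample metadata, MatrixMarket single-cell references, gene-set files and
# qPCR Ct tables.

#' Read a gene-by-sample count matrix from TSV
#'
#' First column = gene identifier, remaining columns = samples. Validates
#' uniqueness, integrality and non-negativity.
#'
#' @param path TSV file path.
#' @return integer matrix genes x samples.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fib("count TSV needs a gene column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  check_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#' @param counts genes x samples matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Expected header: sample, disease, stage, scheme, sex (optional
#' fibrosis_category, true_size_factor). The fibrosis category is derived
#' from stage and scheme (Desmet 0-4: early 0-2 / advanced 3-4; Ishak 0-6:
#' early 0-3 / advanced 4-6) and validated against any supplied column.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_meta <- function(path) {
  check_sample_meta(read.csv(path, stringsAsFactors = FALSE))
}

#' Write sample metadata as CSV
#' @param meta metadata data frame.
#' @param path output path.
#' @export
write_meta <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a single-cell reference as MatrixMarket + sidecars
#'
#' Writes \code{matrix.mtx} (genes x cells), \code{features.tsv},
#' \code{barcodes.tsv} and \code{cell_types.csv} into a directory.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param dir output directory (created if needed).
#' @export
write_sc_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "sc_ref"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ref$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ref$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(ref$counts), file.path(dir, "barcodes.tsv"))
  write.csv(data.frame(barcode = colnames(ref$counts),
                       cell_type = as.character(ref$cell_type)),
            file.path(dir, "cell_types.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a single-cell reference from MatrixMarket + sidecars
#'
#' @param dir directory holding matrix.mtx, features.tsv, barcodes.tsv and
#'   cell_types.csv (as written by \code{\link{write_sc_reference}}).
#' @return an \code{\link{sc_reference}}.
#' @export
read_sc_reference <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  ann <- read.csv(file.path(dir, "cell_types.csv"), stringsAsFactors = FALSE)
  if (!setequal(ann$barcode, colnames(m)))
    stop_fib("cell_types.csv barcodes do not match the matrix")
  sc_reference(m, ann$cell_type[match(colnames(m), ann$barcode)])
}

#' Read gene sets from newline-delimited text or GMT
#'
#' A \code{.gmt} file yields a named list (one set per line: name, comment,
#' genes); any other file yields a single character vector (one gene per
#' line, blanks dropped).
#'
#' @param path file path.
#' @return character vector, or named list for GMT.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    setNames(lapply(parts, function(p) p[-(1:2)]),
             vapply(parts, `[`, character(1), 1L))
  } else {
    lines <- trimws(readLines(path))
    lines[nzchar(lines)]
  }
}

#' Read a qPCR Ct table from CSV
#'
#' Expected header: sample, group, gene, ct, is_housekeeping.
#'
#' @param path CSV file path.
#' @return validated Ct data frame.
#' @export
read_ct <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$is_housekeeping <- as.logical(df$is_housekeeping)
  check_ct_table(df)
}
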