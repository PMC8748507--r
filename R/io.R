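#' Write and read fragment files (BED-like TSV)
#'
#' Columns: chrom, start, end, barcode; 0-based half-open coordinates; no
#' header, tab-separated.
#'
#' @param fragments data.frame of fragments.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments[, c("chrom", "start", "end", "barcode")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "barcode"))
  as.data.frame(df)
}

#' Write and read BED interval files
#'
#' @param bed data.frame with chrom, start, end (extra columns appended).
#' @param path File path.
#' @return `path` / data.frame.
#' @export
write_bed <- function(bed, path) {
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write and read a sparse count matrix as MatrixMarket with label sidecars
#'
#' Writes `<stem>.mtx` (1-based indices), `<stem>.features.tsv` and
#' `<stem>.barcodes.tsv`.
#'
#' @param mat Matrix (sparse or dense) with dimnames.
#' @param stem Path stem.
#' @return The stem / the matrix with dimnames restored.
#' @export
write_mtx <- function(mat, stem) {
  sp <- methods::as(methods::as(Matrix::Matrix(as.matrix(mat), sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, paste0(stem, ".mtx"))
  writeLines(rownames(mat), paste0(stem, ".features.tsv"))
  writeLines(colnames(mat), paste0(stem, ".barcodes.tsv"))
  invisible(stem)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(stem) {
  mat <- Matrix::readMM(paste0(stem, ".mtx"))
  rownames(mat) <- readLines(paste0(stem, ".features.tsv"))
  colnames(mat) <- readLines(paste0(stem, ".barcodes.tsv"))
  methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix")
}
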