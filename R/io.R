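# Plain-text readers/writers for the pipeline's external formats.

#' Write an SPNExperiment as MTX + TSV
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv`
#' into a directory.
#'
#' @param spe an [SPNExperiment].
#' @param dir output directory (created if needed).
#' @export
writeAtlasMTX <- function(spe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(spe, "counts")
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(spe), file.path(dir, "genes.tsv"))
  writeLines(colnames(spe), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(SummarizedExperiment::colData(spe)),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(dir)
}

#' Read an SPNExperiment from MTX + TSV
#'
#' @param dir directory written by [writeAtlasMTX()].
#' @return an [SPNExperiment].
#' @export
readAtlasMTX <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, row.names = 1,
                            stringsAsFactors = FALSE)
  extra <- meta[, setdiff(colnames(meta), .spn_required_cols), drop = FALSE]
  SPNExperiment(counts, roi_label = meta$roi_label,
                sort_channel = meta$sort_channel,
                xfp_count = meta$xfp_count,
                extra_coldata = if (ncol(extra)) extra else NULL)
}

#' Write / read a trace as two-column delimited text
#'
#' Columns are time (s) and value (mV or pA).
#'
#' @param trace numeric vector.
#' @param sampling_rate Hz.
#' @param file path.
#' @export
writeTrace <- function(trace, sampling_rate, file) {
  utils::write.table(
    data.frame(time_s = (seq_along(trace) - 1) / sampling_rate,
               value = trace),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrace
#' @return `readTrace`: list with `trace` and `sampling_rate` (inferred
#'   from the time column).
#' @export
readTrace <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE)
  dt <- stats::median(diff(d$time_s))
  list(trace = d$value, sampling_rate = 1 / dt)
}

#' Write / read an 8-bit grayscale image as TIFF
#'
#' @param img numeric matrix in \[0, 255\] (or a list of matrices for a
#'   multi-page file).
#' @param file path.
#' @export
writeImageTIFF <- function(img, file) {
  if (is.list(img)) {
    arr <- EBImage::Image(
      array(unlist(img), dim = c(dim(img[[1]]), length(img))) / 255)
  } else arr <- EBImage::Image(img / 255)
  EBImage::writeImage(arr, file, type = "tiff", bits.per.sample = 8L)
  invisible(file)
}

#' @rdname writeImageTIFF
#' @return `readImageTIFF`: numeric matrix (or list of matrices) in
#'   \[0, 255\].
#' @export
readImageTIFF <- function(file) {
  x <- EBImage::imageData(EBImage::readImage(file)) * 255
  if (length(dim(x)) == 2) return(round(x))
  lapply(seq_len(dim(x)[3]), function(i) round(x[, , i]))
}
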