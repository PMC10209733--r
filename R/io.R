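#' Write a multiome dataset to plain-text files
#'
#' Emits the on-disk layout the pipeline readers consume:
#' `fragments.tsv` (chrom, start, end, barcode, count; 0-based half-open,
#' coordinate-sorted, no header), `peaks.bed` (BED3+name), `genes.tsv`,
#' `genome.tsv`, `cell_meta.tsv`, and MatrixMarket matrices with TSV sidecars
#' under `rna/` (genes x cells), `atac/` (peaks x cells) and `motifs/`
#' (TFs x peaks). Planted truth is an in-memory record and is not written.
#'
#' @param dataset a `multiome_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest of written files.
#' @seealso [read_multiome_dataset()]
#' @export
write_multiome_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiome_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- character()
  wr <- function(x, f, ...) {
    p <- file.path(dir, f)
    fwrite(x, p, sep = "\t", ...)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  if (!is.null(dataset$fragments))
    wr(dataset$fragments, "fragments.tsv", col.names = FALSE)
  wr(dataset$peaks[, c("chrom", "start", "end", "name")], "peaks.bed",
     col.names = FALSE)
  wr(dataset$genes, "genes.tsv")
  wr(dataset$genome, "genome.tsv")
  wr(dataset$cell_meta, "cell_meta.tsv")

  paths <- c(paths, .write_mtx(dataset$expression, file.path(dir, "rna")))
  paths <- c(paths, .write_mtx(dataset$accessibility, file.path(dir, "atac")))
  paths <- c(paths, .write_mtx(dataset$motif_hits, file.path(dir, "motifs")))
  invisible(paths)
}

#' Read a multiome dataset written by [write_multiome_dataset()]
#'
#' @param dir directory containing the layout.
#' @return a `multiome_dataset` (with `truth = NULL`).
#' @export
read_multiome_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  frag_path <- file.path(dir, "fragments.tsv")
  frags <- if (file.exists(frag_path)) read_fragments(frag_path) else NULL
  peaks <- read_peaks_bed(file.path(dir, "peaks.bed"))
  genes <- as.data.frame(fread(file.path(dir, "genes.tsv")))
  genome <- as.data.frame(fread(file.path(dir, "genome.tsv")))
  meta <- as.data.frame(fread(file.path(dir, "cell_meta.tsv")))
  structure(list(
    expression = .read_mtx(file.path(dir, "rna")),
    accessibility = .read_mtx(file.path(dir, "atac")),
    fragments = frags,
    peaks = peaks,
    genes = genes,
    genome = genome,
    cell_meta = meta,
    motif_hits = .read_mtx(file.path(dir, "motifs")),
    truth = NULL,
    config = NULL
  ), class = "multiome_dataset")
}

#' Read a fragments file
#'
#' Five tab-separated columns (chrom, start, end, barcode, count), 0-based
#' half-open coordinates, no header. Malformed rows raise an error naming the
#' first offending line.
#'
#' @param path fragments.tsv path.
#' @return a data.table with those five columns.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fr <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(fr) != 5L)
    stop("fragments file must have 5 columns, found ", ncol(fr))
  data.table::setnames(fr, c("chrom", "start", "end", "barcode", "count"))
  bad <- which(is.na(fr$start) | is.na(fr$end) | is.na(fr$count) |
                 !is.numeric(fr$start) | !is.numeric(fr$end) |
                 fr$start < 0 | fr$end <= fr$start | fr$count < 1)
  if (length(bad) > 0L)
    stop("malformed fragment record at line ", bad[1L],
         " of ", path)
  fr$count <- as.integer(fr$count)
  fr[]
}

#' Read a BED3+name peak file
#'
#' @param path BED path (0-based half-open).
#' @return data.frame with chrom, start, end, name.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 4L) stop("peaks BED needs at least 4 columns")
  bed <- bed[, 1:4]
  data.table::setnames(bed, c("chrom", "start", "end", "name"))
  if (any(bed$start >= bed$end)) stop("peaks BED has start >= end")
  if (anyDuplicated(bed$name) > 0L) stop("duplicate peak names in BED")
  as.data.frame(bed)
}

## ---- MatrixMarket + sidecars ------------------------------------------

.write_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  storage.mode(m) <- "double"  # force a real-valued (not pattern) MTX
  sp <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(sp, mtx)
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  writeLines(rownames(m), feat)
  writeLines(colnames(m), bc)
  c(mtx, feat, bc)
}

.read_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  # writeMM stores an all-0/1 matrix as a pattern MTX; restore numeric form
  if (is.logical(m)) storage.mode(m) <- "double"
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
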