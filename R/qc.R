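#' Promoter windows around transcription start sites
#'
#' One 500-bp window per gene, symmetric about the TSS (TSS - 250, TSS + 250),
#' clipped at chromosome bounds when a genome declaration is supplied. Strand
#' does not shift the window.
#'
#' @param genes gene models: data.frame with gene, chrom, strand, tss.
#' @param genome optional data.frame (chrom, length) used to clip windows.
#' @param half_width half window width in bp (default 250).
#' @return data.frame with gene, chrom, start, end (0-based half-open).
#' @export
promoter_windows <- function(genes, genome = NULL, half_width = 250L) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(genes)))
  out <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = pmax(genes$tss - half_width, 0L),
                    end = genes$tss + half_width,
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    len <- genome$length[match(out$chrom, genome$chrom)]
    if (anyNA(len)) stop("promoter chromosome missing from genome declaration")
    out$end <- pmin(out$end, len)
  }
  out
}

#' Per-cell scATAC quality-control metrics
#'
#' Tallies, per barcode: usable fragments (all records, weighted by their
#' count column), fragments overlapping promoters, and fragments overlapping
#' peaks. A fragment counts toward a region when the two intervals overlap by
#' at least 1 bp; a record with count c contributes c to every tally it
#' enters.
#'
#' @param fragments fragment records (chrom, start, end, barcode, count),
#'   e.g. from [read_fragments()].
#' @param peaks peak intervals: data.frame with chrom, start, end (0-based
#'   half-open).
#' @param promoters promoter intervals, e.g. from [promoter_windows()].
#' @return data.frame, one row per distinct barcode: barcode,
#'   usable_fragments, promoter_fragments, promoter_fraction,
#'   in_peak_fragments, frip.
#' @export
compute_qc <- function(fragments, peaks, promoters) {
  fr <- as.data.table(fragments)
  if (nrow(fr) == 0L)
    return(data.frame(barcode = character(), usable_fragments = integer(),
                      promoter_fragments = integer(),
                      promoter_fraction = numeric(),
                      in_peak_fragments = integer(), frip = numeric()))
  if (!"count" %in% names(fr)) fr$count <- 1L
  fr_gr <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  in_prom <- .overlaps_any(fr_gr, promoters)
  in_peak <- .overlaps_any(fr_gr, peaks)

  fr$.in_prom <- in_prom
  fr$.in_peak <- in_peak
  tal <- fr[, .(usable_fragments = sum(count),
                promoter_fragments = sum(count * .in_prom),
                in_peak_fragments = sum(count * .in_peak)),
            by = barcode]
  out <- as.data.frame(tal)
  out$promoter_fraction <- ifelse(out$usable_fragments > 0,
                                  out$promoter_fragments / out$usable_fragments, 0)
  out$frip <- ifelse(out$usable_fragments > 0,
                     out$in_peak_fragments / out$usable_fragments, 0)
  out[, c("barcode", "usable_fragments", "promoter_fragments",
          "promoter_fraction", "in_peak_fragments", "frip")]
}

.overlaps_any <- function(query_gr, regions) {
  if (is.null(regions) || nrow(regions) == 0L)
    return(rep(FALSE, length(query_gr)))
  reg_gr <- GRanges(regions$chrom, IRanges(regions$start + 1L, regions$end))
  res <- rep(FALSE, length(query_gr))
  res[unique(queryHits(findOverlaps(query_gr, reg_gr)))] <- TRUE
  res
}

#' Filter ATAC cells on fragment count and promoter fraction
#'
#' Keeps barcodes with usable fragments strictly above `min_fragments` and
#' promoter fraction strictly above `min_promoter_fraction` (the
#' ">10,000 fragments, >10% promoter ratio" rule).
#'
#' @param qc per-cell metrics from [compute_qc()].
#' @param min_fragments usable-fragment threshold (exclusive; default 10000).
#' @param min_promoter_fraction promoter-fraction threshold (exclusive;
#'   default 0.10).
#' @return character vector of kept barcodes.
#' @export
filter_cells <- function(qc, min_fragments = 10000, min_promoter_fraction = 0.10) {
  stopifnot(all(c("barcode", "usable_fragments", "promoter_fraction") %in% names(qc)))
  keep <- qc$usable_fragments > min_fragments &
    qc$promoter_fraction > min_promoter_fraction
  qc$barcode[keep]
}

#' Filter RNA cells on mapped reads and detected genes
#'
#' Removes cells with mapped reads below `min_reads` or with at most
#' `min_genes` genes detected above `tpm_threshold` (the "<1 million reads,
#' <=2,000 genes with TPM > 1" rule; a cell with exactly `min_genes` detected
#' genes is removed).
#'
#' @param expression genes x cells matrix in TPM-like units.
#' @param mapped_reads named (or matrix-ordered) per-cell mapped-read totals.
#' @param min_reads mapped-read threshold (default 1e6).
#' @param min_genes detected-gene threshold (default 2000; removal at <=).
#' @param tpm_threshold detection cutoff on the expression value (default 1).
#' @return character vector of kept cell names.
#' @export
filter_rna_cells <- function(expression, mapped_reads, min_reads = 1e6,
                             min_genes = 2000, tpm_threshold = 1) {
  if (ncol(expression) == 0L) return(character())
  if (is.null(mapped_reads))
    stop("per-cell mapped-read totals are required")
  if (!is.null(names(mapped_reads))) {
    if (!all(colnames(expression) %in% names(mapped_reads)))
      stop("mapped_reads missing for some cells")
    mapped_reads <- mapped_reads[colnames(expression)]
  } else if (length(mapped_reads) != ncol(expression)) {
    stop("mapped_reads length does not match cell count")
  }
  n_detected <- colSums(expression > tpm_threshold)
  keep <- mapped_reads >= min_reads & n_detected > min_genes
  colnames(expression)[keep]
}
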