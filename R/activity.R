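#' Gene activity scores from fragments
#'
#' Counts, per gene and cell, the fragments overlapping the gene body plus a
#' 2-kb upstream extension: `[body_start - upstream, body_end)` for + strand
#' genes and `[body_start, body_end + upstream)` for - strand genes, clipped
#' at zero. Overlap means >= 1 bp; a record with count c contributes c.
#'
#' @param fragments fragment records (chrom, start, end, barcode, count).
#' @param genes gene models with gene, chrom, strand, body_start, body_end.
#' @param barcodes cell universe defining the column set and order; defaults
#'   to the distinct barcodes present in `fragments`.
#' @param upstream upstream extension in bp (default 2000).
#' @return genes x cells matrix of fragment counts.
#' @export
gene_activity <- function(fragments, genes, barcodes = NULL, upstream = 2000L) {
  stopifnot(all(c("gene", "chrom", "strand", "body_start", "body_end") %in%
                  names(genes)))
  if (any(!genes$strand %in% c("+", "-")))
    stop("every gene model needs strand '+' or '-'")
  fr <- as.data.table(fragments)
  if (!"count" %in% names(fr)) fr$count <- 1L
  if (is.null(barcodes)) barcodes <- sort(unique(fr$barcode))

  win_start <- ifelse(genes$strand == "+",
                      pmax(genes$body_start - upstream, 0L), genes$body_start)
  win_end <- ifelse(genes$strand == "+",
                    genes$body_end, genes$body_end + upstream)
  act <- matrix(0, nrow(genes), length(barcodes),
                dimnames = list(genes$gene, barcodes))
  if (nrow(fr) == 0L) return(act)

  fr_gr <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  g_gr <- GRanges(genes$chrom, IRanges(win_start + 1L, win_end))
  ov <- findOverlaps(fr_gr, g_gr)
  if (length(ov) == 0L) return(act)
  hits <- data.table(gene_i = subjectHits(ov),
                     cell = fr$barcode[queryHits(ov)],
                     count = fr$count[queryHits(ov)])
  hits <- hits[hits$cell %in% barcodes, ]
  agg <- hits[, .(n = sum(count)), by = .(gene_i, cell)]
  act[cbind(agg$gene_i, match(agg$cell, barcodes))] <- agg$n
  act
}
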