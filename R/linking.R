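#' Library-size normalize and log-transform a count matrix
#'
#' Divides each cell (column) by its total scaled to the median total, then
#' applies log1p. Zero-total cells are left at zero.
#'
#' @param m features x cells nonnegative matrix.
#' @return transformed matrix of the same shape.
#' @export
normalize_log1p <- function(m) {
  tot <- colSums(m)
  sf <- tot / stats::median(tot[tot > 0])
  sf[sf == 0] <- 1
  log1p(sweep(m, 2L, sf, `/`))
}

#' Link cis peaks to genes against a trans-chromosome null
#'
#' For every gene, candidate peaks are those whose interval has any part
#' within `window` bp of the TSS. The Pearson correlation r between peak
#' accessibility and gene expression is computed across (meta)cells on
#' library-size-normalized, log1p-transformed values (set
#' `normalize = "none"` to correlate the matrices as given). Each gene's null
#' is the set of its correlations with `n_null` peaks sampled (seeded) from
#' other chromosomes; significance is a two-sided normal test of
#' `z = (r - mean(null)) / sd(null)`.
#'
#' Cells can be pooled into metacells of `aggregate_k` cells drawn within
#' lineage x stage groups (seeded); the default `aggregate_k = 1` keeps cells
#' as they are, which suits synthetic data where cells are intrinsically
#' paired.
#'
#' @param accessibility peaks x cells count matrix.
#' @param expression genes x cells matrix, same cells in the same order.
#' @param genes gene models (gene, chrom, strand, tss).
#' @param peaks peak table (chrom, start, end, name).
#' @param window cis half-window around the TSS in bp (default 25000).
#' @param n_null trans peaks sampled per gene for the null (default 100).
#' @param alpha significance level on the null-calibrated p (default 0.05).
#' @param aggregate_k metacell size (default 1 = no pooling).
#' @param cell_meta needed when `aggregate_k > 1` (barcode, lineage, stage).
#' @param normalize `"log1p"` (default) or `"none"`.
#' @param seed seed for null sampling and metacell grouping.
#' @return data.frame of links: gene, peak, distance_to_tss (signed bp,
#'   positive downstream of the TSS), r, z, p, significant. Genes or peaks
#'   with zero variance are skipped; their names are in
#'   `attr(links, "skipped")`.
#' @export
link_peaks_to_genes <- function(accessibility, expression, genes, peaks,
                                window = 25000L, n_null = 100L, alpha = 0.05,
                                aggregate_k = 1L, cell_meta = NULL,
                                normalize = c("log1p", "none"), seed = 1L) {
  normalize <- match.arg(normalize)
  stopifnot(ncol(accessibility) == ncol(expression))
  if (!identical(colnames(accessibility), colnames(expression)))
    stop("modalities must share one cell ordering")
  if (length(unique(peaks$chrom)) < 2L)
    stop("trans null needs peaks on at least 2 chromosomes")
  if (anyDuplicated(peaks$name) > 0L) stop("duplicate peak names")

  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  if (aggregate_k > 1L) {
    grp <- .metacell_groups(colnames(accessibility), cell_meta, aggregate_k)
    accessibility <- .pool_columns(accessibility, grp)
    expression <- .pool_columns(expression, grp)
  }
  n_cells <- ncol(accessibility)
  if (n_cells < 20L) stop("need at least 20 (meta)cells to correlate")

  if (normalize == "log1p") {
    accessibility <- normalize_log1p(accessibility)
    expression <- normalize_log1p(expression)
  }

  genes <- genes[genes$gene %in% rownames(expression), , drop = FALSE]
  Zg <- .std_rows(expression[genes$gene, , drop = FALSE])
  Za <- .std_rows(accessibility[peaks$name, , drop = FALSE])
  ok_g <- !attr(Zg, "degenerate")
  ok_p <- !attr(Za, "degenerate")
  skipped <- c(genes$gene[!ok_g], peaks$name[!ok_p])

  # candidate pairs: peak interval intersecting [tss - window, tss + window]
  tss_gr <- GRanges(genes$chrom, IRanges(pmax(genes$tss - window, 0L) + 1L,
                                         genes$tss + window))
  pk_gr <- GRanges(peaks$chrom, IRanges(peaks$start + 1L, peaks$end))
  ov <- findOverlaps(tss_gr, pk_gr)
  gi <- queryHits(ov)
  pi <- subjectHits(ov)
  keep <- ok_g[gi] & ok_p[pi]
  gi <- gi[keep]; pi <- pi[keep]
  if (length(gi) == 0L) {
    out <- data.frame(gene = character(), peak = character(),
                      distance_to_tss = integer(), r = numeric(),
                      z = numeric(), p = numeric(), significant = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }

  R <- tcrossprod(Zg, Za)  # genes x peaks Pearson correlations

  # per-gene trans null moments
  need <- sort(unique(gi))
  mu <- sig <- rep(NA_real_, nrow(genes))
  for (g in need) {
    pool <- which(peaks$chrom != genes$chrom[g] & ok_p)
    if (length(pool) == 0L) stop("no trans peaks available for gene ",
                                 genes$gene[g])
    idx <- if (length(pool) <= n_null) pool else sample(pool, n_null)
    nulls <- R[g, idx]
    mu[g] <- mean(nulls)
    sig[g] <- stats::sd(nulls)
    if (!is.finite(sig[g]) || sig[g] == 0) sig[g] <- .Machine$double.eps
  }

  # signed distance from the TSS to the nearest base of the peak (0 when the
  # peak covers the TSS); positive downstream, i.e. strand-flipped for -
  tssv <- genes$tss[gi]
  dist_raw <- ifelse(tssv < peaks$start[pi], peaks$start[pi] - tssv,
                     ifelse(tssv >= peaks$end[pi], peaks$end[pi] - 1L - tssv, 0L))
  dist <- as.integer(ifelse(genes$strand[gi] == "-", -dist_raw, dist_raw))
  r <- R[cbind(gi, pi)]
  z <- (r - mu[gi]) / sig[gi]
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(gene = genes$gene[gi], peak = peaks$name[pi],
                    distance_to_tss = dist, r = r, z = z, p = p,
                    significant = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$peak), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "params") <- list(window = window, n_null = n_null, alpha = alpha,
                              aggregate_k = aggregate_k,
                              normalize = normalize,
                              null_form = "normal moments, two-sided",
                              seed = seed)
  out
}

#' Call domains of regulatory chromatin (DORCs)
#'
#' A gene is a DORC when it has strictly more than `dorc_min` significant
#' peak-gene links (default: > 10 significant associations).
#'
#' @param links link table from [link_peaks_to_genes()].
#' @param dorc_min threshold on the number of significant links (exclusive).
#' @return data.frame: gene, n_significant_links, is_dorc, for every gene
#'   present in `links`.
#' @export
call_dorcs <- function(links, dorc_min = 10L) {
  if (nrow(links) == 0L)
    return(data.frame(gene = character(), n_significant_links = integer(),
                      is_dorc = logical()))
  n_sig <- tapply(links$significant, links$gene, sum)
  out <- data.frame(gene = names(n_sig),
                    n_significant_links = as.integer(n_sig),
                    stringsAsFactors = FALSE)
  out$is_dorc <- out$n_significant_links > dorc_min
  rownames(out) <- NULL
  out[order(out$gene), ]
}

## ---- internals ---------------------------------------------------------

# rows centred and scaled so tcrossprod gives Pearson correlations;
# zero-variance rows flagged degenerate and zeroed
.std_rows <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  ss <- sqrt(rowSums(cen^2))
  degen <- ss == 0 | !is.finite(ss)
  ss[degen] <- 1
  z <- cen / ss
  z[degen, ] <- 0
  attr(z, "degenerate") <- degen
  z
}

.metacell_groups <- function(cells, cell_meta, k) {
  if (is.null(cell_meta))
    stop("aggregate_k > 1 needs cell_meta with lineage and stage")
  meta <- cell_meta[match(cells, cell_meta$barcode), ]
  if (anyNA(meta$barcode)) stop("cell_meta missing some cells")
  key <- paste(meta$lineage, meta$stage, sep = "|")
  grp <- integer(length(cells))
  nxt <- 0L
  for (kk in unique(key)) {
    idx <- sample(which(key == kk))  # seeded upstream
    g <- ceiling(seq_along(idx) / k)
    grp[idx] <- nxt + g
    nxt <- nxt + max(g)
  }
  grp
}

.pool_columns <- function(m, grp) {
  pooled <- vapply(sort(unique(grp)), function(g)
    rowSums(m[, grp == g, drop = FALSE]), numeric(nrow(m)))
  colnames(pooled) <- paste0("meta_", sort(unique(grp)))
  pooled
}
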