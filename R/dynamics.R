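#' Accessible peak sets per stage
#'
#' A peak is accessible in a stage when strictly more than `frac` of the
#' stage's cells have a nonzero count for it (the "> 0.25 of cells" rule).
#'
#' @param accessibility peaks x cells count matrix.
#' @param cell_meta data.frame with barcode and stage for every column.
#' @param frac cell-fraction threshold (exclusive; default 0.25).
#' @param stages stage labels to evaluate (default: those present); a
#'   requested stage with zero cells is an error.
#' @return named list of character vectors: accessible peaks per stage.
#' @export
accessible_by_stage <- function(accessibility, cell_meta, frac = 0.25,
                                stages = NULL) {
  meta <- cell_meta[match(colnames(accessibility), cell_meta$barcode), ]
  if (anyNA(meta$barcode)) stop("cell_meta missing some cells")
  if (is.null(stages)) stages <- unique(meta$stage)
  out <- list()
  for (s in stages) {
    cells <- which(meta$stage == s)
    if (length(cells) == 0L) stop("stage '", s, "' has no cells")
    fr <- rowMeans(accessibility[, cells, drop = FALSE] > 0)
    out[[s]] <- rownames(accessibility)[fr > frac]
  }
  out
}

#' Gained and lost peaks across ordered stage transitions
#'
#' For each ordered (from, to) pair: gained = accessible(to) not accessible
#' in from; lost = accessible(from) not accessible in to. Changed peaks are
#' assigned to every gene whose +-`window` TSS window overlaps them, and
#' per-gene change counts are bucketed 1 / 2 / >=3.
#'
#' @param stage_sets output of [accessible_by_stage()].
#' @param transitions data.frame with columns from, to (stage labels).
#' @param genes optional gene models (gene, chrom, tss) for the per-gene
#'   counts.
#' @param peaks peak table (chrom, start, end, name); required with `genes`.
#' @param window peak-to-gene assignment window in bp (default 25000).
#' @return list with `transitions` (one element per pair: from, to, gained,
#'   lost) and `per_gene_counts` (data.frame: from, to, gene, n_gained,
#'   n_lost, bucket_gained, bucket_lost) when genes are supplied.
#' @export
gained_lost <- function(stage_sets, transitions, genes = NULL, peaks = NULL,
                        window = 25000L) {
  transitions <- as.data.frame(transitions)
  stopifnot(all(c("from", "to") %in% names(transitions)))
  unknown <- setdiff(c(transitions$from, transitions$to), names(stage_sets))
  if (length(unknown) > 0L)
    stop("unknown stage label: ", paste(unknown, collapse = ", "))
  trans <- lapply(seq_len(nrow(transitions)), function(i) {
    a <- stage_sets[[transitions$from[i]]]
    b <- stage_sets[[transitions$to[i]]]
    list(from = transitions$from[i], to = transitions$to[i],
         gained = setdiff(b, a), lost = setdiff(a, b))
  })
  out <- list(transitions = trans)
  if (!is.null(genes)) {
    if (is.null(peaks)) stop("per-gene counts need the peak table")
    assign_map <- .peak_gene_assignment(peaks, genes, window)
    pg <- lapply(trans, function(tr) {
      ng <- .count_by_gene(tr$gained, assign_map)
      nl <- .count_by_gene(tr$lost, assign_map)
      all_genes <- union(names(ng), names(nl))
      if (length(all_genes) == 0L) return(NULL)
      data.frame(from = tr$from, to = tr$to, gene = all_genes,
                 n_gained = as.integer(ng[all_genes] %|0|% 0L),
                 n_lost = as.integer(nl[all_genes] %|0|% 0L),
                 stringsAsFactors = FALSE)
    })
    pg <- do.call(rbind, pg)
    if (!is.null(pg)) {
      pg$bucket_gained <- .change_bucket(pg$n_gained)
      pg$bucket_lost <- .change_bucket(pg$n_lost)
      rownames(pg) <- NULL
    }
    out$per_gene_counts <- pg
  }
  out
}

`%|0|%` <- function(x, default) { x[is.na(x)] <- default; x }

.peak_gene_assignment <- function(peaks, genes, window) {
  tss_gr <- GRanges(genes$chrom, IRanges(pmax(genes$tss - window, 0L) + 1L,
                                         genes$tss + window))
  pk_gr <- GRanges(peaks$chrom, IRanges(peaks$start + 1L, peaks$end))
  ov <- findOverlaps(pk_gr, tss_gr)
  data.frame(peak = peaks$name[queryHits(ov)],
             gene = genes$gene[subjectHits(ov)], stringsAsFactors = FALSE)
}

.count_by_gene <- function(changed, assign_map) {
  hit <- assign_map[assign_map$peak %in% changed, , drop = FALSE]
  if (nrow(hit) == 0L) return(integer())
  table(hit$gene)
}

.change_bucket <- function(n) {
  ifelse(n >= 3L, ">=3", ifelse(n == 2L, "2", ifelse(n == 1L, "1", "0")))
}

#' Min-max normalize a vector to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros by
#' convention (reported with a message).
#'
#' @param x numeric vector, length >= 1.
#' @return numeric vector in [0, 1].
#' @export
minmax_normalize <- function(x) {
  stopifnot(length(x) >= 1L)
  rng <- max(x) - min(x)
  if (rng == 0) {
    message("minmax_normalize: constant vector mapped to zeros")
    return(rep(0, length(x)))
  }
  (x - min(x)) / rng
}

#' Mean curve over pseudotime bins
#'
#' Bins cells into `n_bins` equal-width pseudotime intervals and averages a
#' per-cell signal within each bin (empty bins are linearly interpolated from
#' neighbours).
#'
#' @param values per-cell signal.
#' @param pseudotime per-cell pseudotime, same length.
#' @param n_bins number of bins (default 50).
#' @return list with `curve` (length `n_bins`) and `centers` (bin midpoints).
#' @export
pseudotime_curve <- function(values, pseudotime, n_bins = 50L) {
  stopifnot(length(values) == length(pseudotime))
  rng <- range(pseudotime)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(pseudotime, brk, rightmost.closed = TRUE), 1L),
              n_bins)
  curve <- as.numeric(tapply(values, factor(bin, levels = seq_len(n_bins)), mean))
  if (anyNA(curve)) {
    ok <- which(!is.na(curve))
    curve <- stats::approx(ok, curve[ok], xout = seq_len(n_bins), rule = 2)$y
  }
  list(curve = curve, centers = (brk[-1] + brk[-length(brk)]) / 2)
}

#' Classify chromatin-priming pattern from paired pseudotime curves
#'
#' Both curves are min-max normalized and smoothed with a centered moving
#' average (window 3); the half-activation point is the first bin where the
#' smoothed curve crosses 0.5 from below (curves already starting at or above
#' 0.5, or never reaching it, have no up-crossing). The lag is the half-activation bin of the
#' accessibility curve minus that of the expression curve (negative =
#' accessibility leads). Pattern 1 (chromatin precedes expression) is called
#' when `lag < -lag_tol`; otherwise pattern 2 (concurrent). A curve that
#' never reaches 0.5 makes the gene unclassifiable.
#'
#' @param activity accessibility curve over pseudotime bins (length >= 10).
#' @param expression expression curve on the identical bins.
#' @param lag_tol tolerance in bins for calling a lead (default 1).
#' @param bin_width optional pseudotime width of one bin; when given, `lag`
#'   is also reported in pseudotime units.
#' @return list: pattern (1, 2 or NA), lag_bins, lag (pseudotime units or
#'   NA), half_activity, half_expression, unclassifiable flag.
#' @export
classify_priming <- function(activity, expression, lag_tol = 1,
                             bin_width = NULL) {
  if (length(activity) != length(expression))
    stop("curves must share the pseudotime bins")
  if (length(activity) < 10L) stop("need at least 10 pseudotime bins")
  half <- function(x) {
    s <- .smooth3(suppressMessages(minmax_normalize(x)))
    # first up-crossing of 0.5: the curve must come from below
    up <- which(s[-1L] >= 0.5 & s[-length(s)] < 0.5) + 1L
    if (s[1L] < 0.5 && length(up) > 0L) up[1L] else NA_integer_
  }
  ha <- half(activity)
  he <- half(expression)
  if (is.na(ha) || is.na(he))
    return(list(pattern = NA_integer_, lag_bins = NA_real_, lag = NA_real_,
                half_activity = ha, half_expression = he,
                unclassifiable = TRUE))
  lag_bins <- ha - he
  list(pattern = if (lag_bins < -lag_tol) 1L else 2L,
       lag_bins = lag_bins,
       lag = if (is.null(bin_width)) NA_real_ else lag_bins * bin_width,
       half_activity = ha, half_expression = he, unclassifiable = FALSE)
}

.smooth3 <- function(x) {
  n <- length(x)
  out <- x
  if (n >= 3L) out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out[1L] <- mean(x[1:min(2L, n)])
  out[n] <- mean(x[max(n - 1L, 1L):n])
  out
}
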