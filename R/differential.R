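#' One-vs-rest differential features with a detection prefilter
#'
#' For each group, features detected (value > 0) in fewer than `min_pct` of
#' cells on both sides are excluded before testing; the rest are tested
#' one-vs-rest with a Wilcoxon rank-sum test (normal approximation) and
#' BH-corrected within each group's tested set. Log fold changes are natural
#' logs of pseudocounted (plus 1) means of library-size-normalized values.
#'
#' @param m features x cells matrix (counts or normalized values).
#' @param groups per-cell group labels, aligned with columns.
#' @param min_pct detection-fraction prefilter (default 0.2).
#' @param min_cells groups with fewer cells are skipped with a warning.
#' @return data.frame: feature, group, log_fc, pct_in, pct_out, p, p_adj.
#' @export
differential_features <- function(m, groups, min_pct = 0.2, min_cells = 3L) {
  stopifnot(ncol(m) == length(groups))
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  norm <- sweep(m, 2L, pmax(colSums(m), .Machine$double.eps), `/`) *
    stats::median(colSums(m))
  res <- list()
  for (g in lev) {
    ing <- groups == g
    if (sum(ing) < min_cells || sum(!ing) < min_cells) {
      warning("group '", g, "' skipped: fewer than ", min_cells,
              " cells on one side")
      next
    }
    pct_in <- rowMeans(m[, ing, drop = FALSE] > 0)
    pct_out <- rowMeans(m[, !ing, drop = FALSE] > 0)
    tested <- which(pmax(pct_in, pct_out) >= min_pct)
    if (length(tested) == 0L) next
    lfc <- log1p(rowMeans(norm[tested, ing, drop = FALSE])) -
      log1p(rowMeans(norm[tested, !ing, drop = FALSE]))
    p <- vapply(tested, function(i)
      stats::wilcox.test(m[i, ing], m[i, !ing], exact = FALSE)$p.value,
      numeric(1L))
    p[is.na(p)] <- 1
    res[[g]] <- data.frame(feature = rownames(m)[tested], group = g,
                           log_fc = lfc, pct_in = pct_in[tested],
                           pct_out = pct_out[tested], p = p,
                           p_adj = p.adjust(p, "BH"),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(feature = character(), group = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), p_adj = numeric())
  rownames(out) <- NULL
  out
}

#' Pairwise differential test between two cell sets
#'
#' Convenience wrapper used to build stage-pair DEG tables (e.g. EPI vs TE at
#' one stage): Wilcoxon rank-sum per feature, log fold change with the same
#' convention as [differential_features()] (positive = higher in `cells_a`).
#'
#' @param m features x cells matrix.
#' @param cells_a,cells_b column names of the two cell sets.
#' @return data.frame: feature, log_fc, p.
#' @export
pairwise_diff <- function(m, cells_a, cells_b) {
  stopifnot(all(cells_a %in% colnames(m)), all(cells_b %in% colnames(m)))
  norm <- sweep(m, 2L, pmax(colSums(m), .Machine$double.eps), `/`) *
    stats::median(colSums(m))
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  lfc <- log1p(rowMeans(a)) - log1p(rowMeans(b))
  p <- vapply(seq_len(nrow(m)), function(i)
    stats::wilcox.test(m[i, cells_a], m[i, cells_b], exact = FALSE)$p.value,
    numeric(1L))
  p[is.na(p)] <- 1
  data.frame(feature = rownames(m), log_fc = lfc, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Motif enrichment of a foreground peak set
#'
#' Hypergeometric upper-tail test per TF: drawing `n_fg` peaks from the
#' `n_fg + n_bg` universe containing all hit peaks, the p-value is
#' `P[X >= n_fg_hits]`. Fold enrichment is the ratio of hit rates.
#'
#' @param foreground_peaks peak names in the foreground set.
#' @param background_peaks peak names in the background (disjoint from the
#'   foreground by construction; overlaps are removed with a warning).
#' @param motif_hits TFs x peaks binary matrix.
#' @return data.frame: tf, n_fg_hits, n_fg, n_bg_hits, n_bg, fold_enrichment,
#'   p.
#' @export
motif_enrichment <- function(foreground_peaks, background_peaks, motif_hits) {
  if (length(foreground_peaks) == 0L) stop("empty foreground peak set")
  if (any(foreground_peaks %in% background_peaks)) {
    warning("removing foreground peaks from background")
    background_peaks <- setdiff(background_peaks, foreground_peaks)
  }
  univ <- colnames(motif_hits)
  if (!all(foreground_peaks %in% univ) || !all(background_peaks %in% univ))
    stop("peaks missing from the motif-hit matrix")
  fg <- motif_hits[, foreground_peaks, drop = FALSE]
  bg <- motif_hits[, background_peaks, drop = FALSE]
  n_fg <- length(foreground_peaks)
  n_bg <- length(background_peaks)
  k_fg <- rowSums(fg > 0)
  k_bg <- rowSums(bg > 0)
  fold <- ifelse(k_fg == 0, 0,
                 (k_fg / n_fg) / ifelse(k_bg == 0, NA, k_bg / n_bg))
  fold[k_fg > 0 & k_bg == 0] <- Inf
  p <- phyper(k_fg - 1, k_fg + k_bg, n_fg + n_bg - k_fg - k_bg, n_fg,
              lower.tail = FALSE)
  p[k_fg == 0] <- 1
  data.frame(tf = rownames(motif_hits), n_fg_hits = as.integer(k_fg),
             n_fg = n_fg, n_bg_hits = as.integer(k_bg), n_bg = n_bg,
             fold_enrichment = fold, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}
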