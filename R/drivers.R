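#' Select lineage-divergent genes from ordered stage-pair DEG tables
#'
#' A gene qualifies within a dataset when its log fold change (EPI minus TE
#' sign convention) keeps a constant nonzero sign and strictly increases in
#' magnitude across the ordered stage-pair comparisons — expression
#' divergence that amplifies from peri- to post-implantation. Genes absent
#' from an ordinal are treated as log fold change 0 (and therefore never
#' qualify). Optionally the p-value can additionally be required to be
#' nonincreasing.
#'
#' @param degs data.frame: dataset, ordinal (1 = earliest pair), gene,
#'   log_fc, p.
#' @param require_p_nonincreasing also require p-values nonincreasing across
#'   ordinals (default FALSE).
#' @return data.frame: dataset, gene, side ("EPI" for positive log fold
#'   changes, "TE" for negative).
#' @export
select_divergent_genes <- function(degs, require_p_nonincreasing = FALSE) {
  degs <- as.data.frame(degs)
  stopifnot(all(c("dataset", "ordinal", "gene", "log_fc", "p") %in% names(degs)))
  res <- list()
  for (ds in unique(degs$dataset)) {
    d <- degs[degs$dataset == ds, ]
    ords <- sort(unique(d$ordinal))
    if (length(ords) < 2L)
      stop("dataset '", ds, "' has a single stage pair")
    genes <- unique(d$gene)
    lfc <- matrix(0, length(genes), length(ords),
                  dimnames = list(genes, as.character(ords)))
    pv <- matrix(1, length(genes), length(ords),
                 dimnames = list(genes, as.character(ords)))
    lfc[cbind(match(d$gene, genes), match(d$ordinal, ords))] <- d$log_fc
    pv[cbind(match(d$gene, genes), match(d$ordinal, ords))] <- d$p
    sign_ok <- apply(lfc, 1L, function(x) all(x > 0) || all(x < 0))
    inc_ok <- apply(abs(lfc), 1L, function(x) all(diff(x) > 0))
    keep <- sign_ok & inc_ok
    if (require_p_nonincreasing)
      keep <- keep & apply(pv, 1L, function(x) all(diff(x) <= 0))
    if (!any(keep)) next
    res[[ds]] <- data.frame(dataset = ds, gene = genes[keep],
                            side = ifelse(lfc[keep, 1L] > 0, "EPI", "TE"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(dataset = character(), gene = character(),
                      side = character())
  rownames(out) <- NULL
  out
}

#' Side-respecting intersection of two divergent-gene sets
#'
#' A gene is a driver only when it qualifies on the same side (EPI or TE) in
#' both datasets.
#'
#' @param set_a,set_b data.frames with gene and side columns.
#' @return data.frame: gene, side.
#' @export
overlap_drivers <- function(set_a, set_b) {
  m <- merge(set_a[, c("gene", "side")], set_b[, c("gene", "side")],
             by = c("gene", "side"))
  m <- unique(m[, c("gene", "side")])
  m <- m[order(m$gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Expression and activity difference ratios for driver genes
#'
#' For each driver gene, the absolute log fold change between EPI and TE
#' cells is computed at the pre-implantation phase and at the
#' post-implantation phase, on expression and on gene activity; the reported
#' ratio is `log(|post| / |pre|)` (positive = the lineage difference grows
#' after implantation). The number of TFs potentially regulating the gene is
#' the count of TFs with a motif hit on at least one of the gene's
#' significantly linked peaks.
#'
#' @param drivers data.frame with gene and side (from [overlap_drivers()]).
#' @param expression genes x cells matrix.
#' @param activity genes x cells gene-activity matrix (same cells).
#' @param cell_meta data.frame with barcode, lineage, stage.
#' @param epi_lineage,te_lineage lineage labels of the two sides.
#' @param pre_stages,post_stages stage labels making up the pre- and
#'   post-implantation phases (a required mapping, not inferred).
#' @param links optional link table for the regulating-TF counts.
#' @param motif_hits optional TFs x peaks matrix for the same.
#' @return data.frame: gene, side, expr_ratio, activity_ratio,
#'   n_regulating_tfs (NA without links/motifs). Genes with a zero
#'   pre-phase log fold change are excluded with a message.
#' @export
difference_ratios <- function(drivers, expression, activity, cell_meta,
                              epi_lineage = "EPI", te_lineage = "TE",
                              pre_stages, post_stages,
                              links = NULL, motif_hits = NULL) {
  stopifnot(identical(colnames(expression), colnames(activity)))
  meta <- cell_meta[match(colnames(expression), cell_meta$barcode), ]
  pick <- function(lin, stg) meta$barcode[meta$lineage == lin & meta$stage %in% stg]
  cells <- list(pre_epi = pick(epi_lineage, pre_stages),
                pre_te = pick(te_lineage, pre_stages),
                post_epi = pick(epi_lineage, post_stages),
                post_te = pick(te_lineage, post_stages))
  if (any(lengths(cells) == 0L)) stop("a phase/lineage group has no cells")

  lfc_abs <- function(m, g, a, b) {
    norm <- sweep(m, 2L, pmax(colSums(m), .Machine$double.eps), `/`) *
      stats::median(colSums(m))
    abs(log1p(rowMeans(norm[g, a, drop = FALSE])) -
          log1p(rowMeans(norm[g, b, drop = FALSE])))
  }
  g <- drivers$gene
  pre_e <- lfc_abs(expression, g, cells$pre_epi, cells$pre_te)
  post_e <- lfc_abs(expression, g, cells$post_epi, cells$post_te)
  pre_a <- lfc_abs(activity, g, cells$pre_epi, cells$pre_te)
  post_a <- lfc_abs(activity, g, cells$post_epi, cells$post_te)

  bad <- pre_e == 0 | pre_a == 0
  if (any(bad)) {
    message("difference_ratios: excluding ", sum(bad),
            " gene(s) with zero pre-phase log fold change")
    g <- g[!bad]
  }
  out <- data.frame(gene = g, side = drivers$side[!bad],
                    expr_ratio = log(post_e[!bad] / pre_e[!bad]),
                    activity_ratio = log(post_a[!bad] / pre_a[!bad]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_regulating_tfs <- if (!is.null(links) && !is.null(motif_hits)) {
    vapply(out$gene, count_regulating_tfs, integer(1L),
           links = links, motif_hits = motif_hits)
  } else NA_integer_
  out
}

#' Count TFs with a motif hit on a gene's significantly linked peaks
#'
#' @param gene gene name.
#' @param links link table from [link_peaks_to_genes()].
#' @param motif_hits TFs x peaks binary matrix.
#' @return integer count.
#' @export
count_regulating_tfs <- function(gene, links, motif_hits) {
  pk <- links$peak[links$gene == gene & links$significant]
  pk <- intersect(pk, colnames(motif_hits))
  if (length(pk) == 0L) return(0L)
  sum(rowSums(motif_hits[, pk, drop = FALSE] > 0) > 0)
}

#' Call lineage-specific TFs from paired motif enrichments
#'
#' A TF is called for the EPI side when its enrichment among peaks linked to
#' EPI-side drivers has p < 0.01, its enrichment on the TE side has p > 0.01,
#' and its EPI fold enrichment exceeds its TE fold enrichment; symmetrically
#' for TE. TFs satisfying neither rule are dropped. A TF missing from one
#' table is treated as p = 1, fold = 0 there (with a message).
#'
#' @param enrichment_epi,enrichment_te [motif_enrichment()] tables for peaks
#'   linked to EPI-side and TE-side driver genes.
#' @param p_in p-value threshold on the called side (default 0.01).
#' @param p_out p-value threshold the other side must exceed (default 0.01).
#' @return data.frame: tf, enriched_in, p_epi, p_te, fold_epi, fold_te.
#' @export
lineage_tf_filter <- function(enrichment_epi, enrichment_te,
                              p_in = 0.01, p_out = 0.01) {
  tfs <- union(enrichment_epi$tf, enrichment_te$tf)
  miss <- setdiff(tfs, intersect(enrichment_epi$tf, enrichment_te$tf))
  if (length(miss) > 0L)
    message("lineage_tf_filter: ", length(miss),
            " TF(s) missing from one table treated as p = 1, fold = 0")
  get <- function(tab, col) {
    v <- tab[[col]][match(tfs, tab$tf)]
    v[is.na(v)] <- if (col == "p") 1 else 0
    v
  }
  pe <- get(enrichment_epi, "p"); fe <- get(enrichment_epi, "fold_enrichment")
  pt <- get(enrichment_te, "p"); ft <- get(enrichment_te, "fold_enrichment")
  epi <- pe < p_in & pt > p_out & fe > ft
  te <- pt < p_in & pe > p_out & ft > fe
  out <- data.frame(tf = tfs,
                    enriched_in = ifelse(epi, "EPI", ifelse(te, "TE", NA)),
                    p_epi = pe, p_te = pt, fold_epi = fe, fold_te = ft,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[!is.na(out$enriched_in), , drop = FALSE]
  rownames(out) <- NULL
  out
}
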