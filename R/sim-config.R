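#' Configuration for the synthetic paired-multiome generator
#'
#' Builds and validates the configuration consumed by
#' [generate_multiome()]. The defaults describe a small post-implantation
#' embryo-like design: four lineages, three ordered stages per lineage, cis
#' peaks placed within 25 kb of each gene's TSS, and Poisson/lognormal count
#' noise calibrated so that planted peak-gene correlations survive count
#' sampling approximately at their nominal strength.
#'
#' Gene names are `g0001 ...`; each gene owns `peaks_per_gene` cis peaks named
#' `<gene>_pk1 ...` (`_pk1` is a 500-bp promoter peak centred on the TSS) and
#' background peaks are `bg_pk1 ...`. Planted structure refers to those names.
#'
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration, including this seed.
#' @param n_lineages number of lineages (>= 2 for lineage-contrast analyses).
#' @param lineages lineage labels; default `c("EPI","TE","VE","EXMC")` trimmed
#'   to `n_lineages`.
#' @param stages ordered stage labels shared by every lineage.
#' @param cells_per_group cells per (lineage, stage) group.
#' @param n_genes number of genes.
#' @param peaks_per_gene cis peaks per gene, all within `link_window` of the
#'   TSS.
#' @param n_extra_peaks gene-free background peaks appended to the peak set.
#' @param link_window cis window half-width in bp (default 25000).
#' @param planted_links `data.frame(gene, peak, rho)` of peak-gene pairs whose
#'   latent programs are correlated at `rho`; `peak = NA` targets the gene's
#'   promoter peak.
#' @param planted_tfs list of regulons, each
#'   `list(tf=, targets=, lineage=, peaks=)`. The TF and its targets are
#'   upregulated in `lineage` with a stage-amplifying effect; `peaks` (default:
#'   the targets' planted-link peaks) receive a motif hit for the TF.
#' @param tf_universe gene names treated as TFs in the motif matrix; defaults
#'   to the planted TFs plus `n_background_tfs` other genes.
#' @param n_background_tfs extra motif-only TFs when `tf_universe` is NULL.
#' @param gain_loss_plan `data.frame(stage, peak, action)` with action
#'   `"open"` (peak near-silent before `stage`, open from it on) or `"close"`
#'   (the reverse), applied within every lineage.
#' @param lag_plan `data.frame(gene, delta)`: the gene follows a sigmoidal
#'   activation along pseudotime and its promoter peak activates `delta`
#'   pseudotime units earlier (accessibility leads expression).
#' @param noise overrides for the noise/depth parameter list; see
#'   [sim_noise_defaults()].
#' @param fragments emit per-cell fragment records (needed for QC and gene
#'   activity); matrices are identical either way.
#' @return a validated `sim_config` object (a list).
#' @seealso [generate_multiome()]
#' @export
sim_config <- function(seed,
                       n_lineages = 4L,
                       lineages = NULL,
                       stages = c("A", "B", "C"),
                       cells_per_group = 50L,
                       n_genes = 200L,
                       peaks_per_gene = 4L,
                       n_extra_peaks = 50L,
                       link_window = 25000L,
                       planted_links = NULL,
                       planted_tfs = list(),
                       tf_universe = NULL,
                       n_background_tfs = 10L,
                       gain_loss_plan = NULL,
                       lag_plan = NULL,
                       noise = list(),
                       fragments = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_lineages < 2L) stop("need at least 2 lineages")
  if (length(stages) < 1L || anyDuplicated(stages) > 0L)
    stop("stages must be distinct ordered labels")
  if (is.null(lineages))
    lineages <- c("EPI", "TE", "VE", "EXMC", paste0("L", 5:26))[seq_len(n_lineages)]
  if (length(lineages) != n_lineages) stop("lineages must have length n_lineages")

  genes <- sprintf("g%04d", seq_len(n_genes))
  cis_peaks <- as.vector(t(outer(genes, paste0("_pk", seq_len(peaks_per_gene)),
                                 paste0)))
  bg_peaks <- if (n_extra_peaks > 0L) sprintf("bg_pk%04d", seq_len(n_extra_peaks)) else character()
  peak_universe <- c(cis_peaks, bg_peaks)

  if (!is.null(planted_links)) {
    planted_links <- as.data.frame(planted_links)
    stopifnot(all(c("gene", "peak", "rho") %in% names(planted_links)))
    miss <- is.na(planted_links$peak)
    planted_links$peak[miss] <- paste0(planted_links$gene[miss], "_pk1")
    if (!all(planted_links$gene %in% genes))
      stop("planted link gene outside gene universe")
    if (!all(planted_links$peak %in% peak_universe))
      stop("planted link peak outside peak universe")
    if (anyDuplicated(planted_links$peak) > 0L)
      stop("a peak may carry at most one planted link")
    if (any(abs(planted_links$rho) >= 1))
      stop("planted rho must lie in (-1, 1)")
  }

  planted_tfs <- lapply(planted_tfs, function(tfspec) {
    stopifnot(all(c("tf", "targets") %in% names(tfspec)))
    if (is.null(tfspec$lineage)) tfspec$lineage <- lineages[[1L]]
    if (!tfspec$tf %in% genes) stop("planted TF outside gene universe")
    if (!all(tfspec$targets %in% genes)) stop("planted TF target outside gene universe")
    if (!tfspec$lineage %in% lineages) stop("planted TF lineage unknown")
    if (is.null(tfspec$peaks)) {
      if (is.null(planted_links))
        stop("planted TF needs motif peaks: none given and no planted links to default to")
      tfspec$peaks <- planted_links$peak[planted_links$gene %in% tfspec$targets]
      if (length(tfspec$peaks) == 0L)
        stop("planted TF targets have no planted-link peaks to default motif hits to")
    }
    if (!all(tfspec$peaks %in% peak_universe))
      stop("planted TF motif peak outside peak universe")
    tfspec
  })

  if (is.null(tf_universe)) {
    planted <- vapply(planted_tfs, `[[`, character(1L), "tf")
    pool <- setdiff(genes, planted)
    tf_universe <- c(planted, utils::head(pool, n_background_tfs))
  }
  if (!all(tf_universe %in% genes)) stop("tf_universe outside gene universe")

  if (!is.null(gain_loss_plan)) {
    gain_loss_plan <- as.data.frame(gain_loss_plan)
    stopifnot(all(c("stage", "peak", "action") %in% names(gain_loss_plan)))
    if (!all(gain_loss_plan$stage %in% stages)) stop("gain/loss stage unknown")
    if (!all(gain_loss_plan$peak %in% peak_universe))
      stop("gain/loss peak outside peak universe")
    if (!all(gain_loss_plan$action %in% c("open", "close")))
      stop("gain/loss action must be 'open' or 'close'")
  }

  if (!is.null(lag_plan)) {
    lag_plan <- as.data.frame(lag_plan)
    stopifnot(all(c("gene", "delta") %in% names(lag_plan)))
    if (!all(lag_plan$gene %in% genes)) stop("lag plan gene outside gene universe")
    if (any(lag_plan$delta < 0)) stop("lag delta must be >= 0")
  }

  cfg <- list(
    seed = as.integer(seed),
    lineages = lineages,
    stages = as.character(stages),
    cells_per_group = as.integer(cells_per_group),
    n_genes = as.integer(n_genes),
    peaks_per_gene = as.integer(peaks_per_gene),
    n_extra_peaks = as.integer(n_extra_peaks),
    link_window = as.integer(link_window),
    genes = genes,
    peak_universe = peak_universe,
    planted_links = planted_links,
    planted_tfs = planted_tfs,
    tf_universe = tf_universe,
    gain_loss_plan = gain_loss_plan,
    lag_plan = lag_plan,
    noise = utils::modifyList(sim_noise_defaults(), noise),
    fragments = isTRUE(fragments)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default noise and depth parameters for the generator
#'
#' @return named list:
#' \describe{
#'   \item{peak_mean}{mean in-peak fragment count per cell and peak (25; with
#'     a few hundred peaks this puts typical cells well above 10,000 usable
#'     fragments).}
#'   \item{peak_mean_sdlog}{lognormal spread of per-peak means.}
#'   \item{peak_sig_sd}{sd of the latent log-accessibility signal.}
#'   \item{closed_mult}{rate multiplier for a not-yet-opened (or closed) peak.}
#'   \item{depth_cv}{lognormal coefficient of variation of per-cell depth.}
#'   \item{lowdepth_frac, lowdepth_mult}{fraction of cells planted at low
#'     sequencing depth and their depth multiplier, so the fragment-count QC
#'     filter has something to reject.}
#'   \item{expr_sig_sd, expr_noise_sd}{sd of the shared latent program and of
#'     the gene-specific lognormal noise in expression.}
#'   \item{expr_mean_log, expr_mean_sdlog}{log-scale location/spread of
#'     baseline expression.}
#'   \item{offpeak_frac}{fraction of usable fragments falling outside peaks
#'     (sets FRiP around 0.65).}
#'   \item{frag_len}{fragment length in bp.}
#'   \item{rna_reads_meanlog, rna_reads_sdlog}{per-cell mapped-read totals for
#'     the RNA modality.}
#'   \item{bg_hit_rate}{background motif hit probability per (TF, peak).}
#'   \item{tf_effect, tf_gain}{lineage effect of a planted regulon at the
#'     first stage, and its multiplicative amplification per stage.}
#'   \item{lag_k}{steepness of the sigmoidal activation used by lag-planted
#'     genes.}
#' }
#' @export
sim_noise_defaults <- function() {
  list(
    peak_mean = 25,
    peak_mean_sdlog = 0.25,
    peak_sig_sd = 1,
    closed_mult = 0.001,
    depth_cv = 0.3,
    lowdepth_frac = 0.05,
    lowdepth_mult = 0.3,
    expr_sig_sd = 1,
    expr_noise_sd = 0.15,
    expr_mean_log = log(50),
    expr_mean_sdlog = 1,
    offpeak_frac = 0.35,
    frag_len = 150,
    rna_reads_meanlog = log(2.5e6),
    rna_reads_sdlog = 0.3,
    bg_hit_rate = 0.05,
    tf_effect = 1.5,
    tf_gain = 1.6,
    lag_k = 4
  )
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      length(x$lineages), "lineages x", length(x$stages), "stages,",
      x$cells_per_group, "cells/group;",
      x$n_genes, "genes,", length(x$peak_universe), "peaks\n")
  cat("  planted links:", if (is.null(x$planted_links)) 0L else nrow(x$planted_links),
      "| planted TFs:", length(x$planted_tfs),
      "| gain/loss rows:", if (is.null(x$gain_loss_plan)) 0L else nrow(x$gain_loss_plan),
      "| lag genes:", if (is.null(x$lag_plan)) 0L else nrow(x$lag_plan), "\n")
  invisible(x)
}
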