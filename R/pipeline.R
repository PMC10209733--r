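#' Standard two-lineage driver-study configuration
#'
#' The configuration used by the end-to-end driver analysis: an EPI and a TE
#' lineage over three ordered stages, one dominant planted TF regulating
#' `n_dominant_targets` EPI-side genes and several minor TFs regulating
#' `n_minor_targets` genes each (alternating sides), every target carrying a
#' planted promoter-peak link. Lineage effects amplify across stages, so
#' target genes qualify as divergence-amplifying driver genes.
#'
#' @param seed integer seed.
#' @param cells_per_group cells per lineage x stage group (default 25).
#' @param n_genes gene universe size (default 120).
#' @param n_dominant_targets targets of the dominant TF (default 10).
#' @param n_minor_tfs number of minor TFs (default 4).
#' @param n_minor_targets targets per minor TF (default 2).
#' @param rho planted link strength (default 0.65).
#' @param fragments emit fragment records (default TRUE).
#' @return a [sim_config()]; the dominant TF's name is in
#'   `attr(cfg, "dominant_tf")`.
#' @export
driver_study_config <- function(seed, cells_per_group = 25L, n_genes = 120L,
                                n_dominant_targets = 10L, n_minor_tfs = 4L,
                                n_minor_targets = 2L, rho = 0.65,
                                fragments = TRUE) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_tf <- 1L + n_minor_tfs
  tf_names <- genes[seq_len(n_tf)]
  need <- n_dominant_targets + n_minor_tfs * n_minor_targets
  target_pool <- genes[(n_tf + 1L):(n_tf + need)]
  dom_targets <- target_pool[seq_len(n_dominant_targets)]
  minor_targets <- split(target_pool[-seq_len(n_dominant_targets)],
                         rep(seq_len(n_minor_tfs), each = n_minor_targets))
  sides <- rep(c("EPI", "TE"), length.out = n_minor_tfs)
  planted_tfs <- c(
    list(list(tf = tf_names[1L], targets = dom_targets, lineage = "EPI")),
    lapply(seq_len(n_minor_tfs), function(i)
      list(tf = tf_names[i + 1L], targets = minor_targets[[i]],
           lineage = sides[i])))
  planted_links <- data.frame(gene = target_pool, peak = NA, rho = rho)
  cfg <- sim_config(seed = seed, n_lineages = 2L, lineages = c("EPI", "TE"),
                    stages = c("A", "B", "C"),
                    cells_per_group = cells_per_group, n_genes = n_genes,
                    peaks_per_gene = 4L, n_extra_peaks = 30L,
                    planted_links = planted_links, planted_tfs = planted_tfs,
                    fragments = fragments)
  attr(cfg, "dominant_tf") <- tf_names[1L]
  cfg
}

#' Run the full lineage-driver analysis on a synthetic multiome
#'
#' Executes the complete chain on generated data: simulate (two replicate
#' datasets sharing the planted design), fragment QC and cell filtering,
#' cis peak-to-gene linking with the trans null, DORC calling, stage-pair
#' DEG tables for both replicates, divergence-amplifying driver selection
#' and side-respecting overlap, gene activity scoring, expression/activity
#' difference ratios, per-side motif enrichment with the lineage-TF filter,
#' TF-target network construction, and centrality-based driving-potential
#' ranking.
#'
#' @param config a [driver_study_config()] (or compatible two-lineage
#'   `sim_config` with planted TFs).
#' @param replicate_seed_offset seed offset of the second replicate dataset
#'   (default 1000).
#' @param link_alpha significance level for links (default 0.05).
#' @param pre_stages,post_stages phase mapping for the difference ratios
#'   (defaults: first stage vs last stage).
#' @return list: qc, kept_cells, links, dorcs, degs, drivers, ratios,
#'   lineage_tfs, network, centralities, driving, dominant_tf,
#'   dominant_rank_position (1 = top of the driving-potential table).
#' @export
run_driver_pipeline <- function(config, replicate_seed_offset = 1000L,
                                link_alpha = 0.05,
                                pre_stages = NULL, post_stages = NULL) {
  if (is.null(pre_stages)) pre_stages <- config$stages[1L]
  if (is.null(post_stages)) post_stages <- config$stages[length(config$stages)]
  ds <- generate_multiome(config)
  cfg2 <- config
  cfg2$seed <- config$seed + as.integer(replicate_seed_offset)
  cfg2$fragments <- FALSE
  ds2 <- generate_multiome(cfg2)

  # fragment QC on the primary replicate
  if (is.null(ds$fragments)) stop("driver pipeline needs fragment records")
  proms <- promoter_windows(ds$genes, ds$genome)
  qc <- compute_qc(ds$fragments, ds$peaks, proms)
  kept <- filter_cells(qc)
  kept <- intersect(colnames(ds$accessibility), kept)
  A <- ds$accessibility[, kept, drop = FALSE]
  X <- ds$expression[, kept, drop = FALSE]
  meta <- ds$cell_meta[match(kept, ds$cell_meta$barcode), ]

  links <- link_peaks_to_genes(A, X, ds$genes, ds$peaks,
                               alpha = link_alpha, seed = config$seed)
  dorcs <- call_dorcs(links)

  degs <- rbind(.stage_pair_degs(X, meta, "ds1", config$stages),
                .stage_pair_degs(ds2$expression, ds2$cell_meta, "ds2",
                                 config$stages))
  div <- select_divergent_genes(degs)
  drivers <- overlap_drivers(div[div$dataset == "ds1", , drop = FALSE],
                             div[div$dataset == "ds2", , drop = FALSE])

  activity <- gene_activity(ds$fragments, ds$genes, barcodes = kept)
  ratios <- if (nrow(drivers) > 0L) {
    difference_ratios(drivers, X, activity, meta,
                      pre_stages = pre_stages, post_stages = post_stages,
                      links = links, motif_hits = ds$motif_hits)
  } else NULL

  lineage_tfs <- .side_tf_calls(drivers, links, ds)

  network <- build_network(config$tf_universe, drivers$gene, links,
                           ds$motif_hits)
  driving <- NULL
  dom_pos <- NA_integer_
  if (nrow(network$edges) > 0L) {
    cent <- network_centralities(network)
    driving <- driving_potential(cent)
    dom <- attr(config, "dominant_tf")
    if (!is.null(dom) && dom %in% driving$tf)
      dom_pos <- match(dom, driving$tf)
  } else cent <- NULL

  list(qc = qc, kept_cells = kept, links = links, dorcs = dorcs, degs = degs,
       drivers = drivers, ratios = ratios, lineage_tfs = lineage_tfs,
       network = network, centralities = cent, driving = driving,
       dominant_tf = attr(config, "dominant_tf"),
       dominant_rank_position = dom_pos)
}

# EPI-vs-TE DEG table at every stage, ordinal = stage order
.stage_pair_degs <- function(expression, meta, dataset_id, stages) {
  res <- lapply(seq_along(stages), function(s) {
    a <- meta$barcode[meta$lineage == "EPI" & meta$stage == stages[s]]
    b <- meta$barcode[meta$lineage == "TE" & meta$stage == stages[s]]
    d <- pairwise_diff(expression, a, b)
    data.frame(dataset = dataset_id, ordinal = s, gene = d$feature,
               log_fc = d$log_fc, p = d$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# motif enrichment of peaks linked to each side's drivers + the P<0.01/>0.01
# lineage filter
.side_tf_calls <- function(drivers, links, ds) {
  if (nrow(drivers) == 0L) return(NULL)
  side_peaks <- function(side) {
    g <- drivers$gene[drivers$side == side]
    unique(links$peak[links$significant & links$gene %in% g])
  }
  fg_epi <- side_peaks("EPI")
  fg_te <- side_peaks("TE")
  if (length(fg_epi) == 0L || length(fg_te) == 0L) return(NULL)
  all_pk <- colnames(ds$motif_hits)
  enr_epi <- motif_enrichment(fg_epi, setdiff(all_pk, fg_epi), ds$motif_hits)
  enr_te <- motif_enrichment(fg_te, setdiff(all_pk, fg_te), ds$motif_hits)
  lineage_tf_filter(enr_epi, enr_te)
}
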