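#' Generate a synthetic paired single-cell multiome dataset
#'
#' Draws a paired accessibility (peaks x cells) and expression (genes x cells)
#' dataset from a planted-truth model. Cells are intrinsically paired: both
#' matrices share one cell ordering. The generative model is deliberately
#' simple so that every downstream statistic is identifiable:
#'
#' * each gene carries a latent per-cell program; expression is a lognormal
#'   function of that program (reported in TPM-like units);
#' * each peak carries a latent program and Poisson fragment counts whose rate
#'   mixes a cell depth factor, a per-peak mean, and the latent signal;
#' * a planted link (gene, peak, rho) sets the peak latent to
#'   `rho * program(gene) + sqrt(1 - rho^2) * noise`, so the count-level
#'   Pearson correlation lands close to `rho`;
#' * a planted regulon upregulates the TF and its targets in one lineage with
#'   a stage-amplifying effect and stamps the TF's motif onto the targets'
#'   linked peaks;
#' * a gain/loss plan multiplies a peak's rate by a near-zero factor on one
#'   side of a stage boundary;
#' * a lag plan gives a gene a sigmoidal activation along pseudotime whose
#'   promoter-peak accessibility activates `delta` pseudotime units earlier
#'   than expression.
#'
#' Fragment records are expanded from the in-peak count matrix (one record per
#' count unit, placed uniformly inside the peak) plus off-peak records sampled
#' outside peaks, so QC metrics (usable fragments, promoter fraction, FRiP)
#' are nontrivial. The genome is a synthetic declaration of 3 chromosomes of
#' 10 Mb; genes are spread across all chromosomes so trans-chromosome nulls
#' are always available.
#'
#' @param config a [sim_config()] object.
#' @return a `multiome_dataset` list with elements `expression`,
#'   `accessibility`, `fragments` (data.table or NULL), `peaks`, `genes`,
#'   `genome`, `cell_meta`, `motif_hits`, `truth`, `config`.
#' @examples
#' ds <- generate_multiome(sim_config(seed = 1, n_genes = 20,
#'                                    cells_per_group = 5, fragments = FALSE))
#' dim(ds$expression)
#' @export
generate_multiome <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  nz <- config$noise
  genome <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                       length = rep(10e6, 3), stringsAsFactors = FALSE)

  genes <- .place_genes(config, genome)
  peaks <- .place_peaks(config, genes, genome)
  meta <- .make_cells(config)
  n_cells <- nrow(meta)

  ## ---- latent gene programs -------------------------------------------
  U <- matrix(rnorm(config$n_genes * n_cells), config$n_genes, n_cells,
              dimnames = list(config$genes, meta$barcode))
  for (tfspec in config$planted_tfs) {
    eff <- nz$tf_effect * nz$tf_gain^(meta$stage_idx - 1)
    eff[meta$lineage != tfspec$lineage] <- 0
    members <- unique(c(tfspec$tf, tfspec$targets))
    U[members, ] <- sweep(U[members, , drop = FALSE], 2L, eff, `+`)
  }
  t0 <- length(config$stages) / 2
  lag_expr_act <- NULL
  if (!is.null(config$lag_plan)) {
    lag_expr_act <- matrix(0, nrow(config$lag_plan), n_cells,
                           dimnames = list(config$lag_plan$gene, NULL))
    for (i in seq_len(nrow(config$lag_plan))) {
      a <- plogis(nz$lag_k * (meta$pseudotime - t0))
      lag_expr_act[i, ] <- a
      U[config$lag_plan$gene[i], ] <- a + rnorm(n_cells, sd = 0.05)
    }
  }
  U <- (U - rowMeans(U)) / apply(U, 1L, stats::sd)  # per-gene standardized

  ## ---- expression (TPM-like) ------------------------------------------
  mu_g <- rnorm(config$n_genes, nz$expr_mean_log, nz$expr_mean_sdlog)
  X <- exp(mu_g + nz$expr_sig_sd * U +
             matrix(rnorm(config$n_genes * n_cells, sd = nz$expr_noise_sd),
                    config$n_genes, n_cells))
  if (!is.null(lag_expr_act)) {
    X[config$lag_plan$gene, ] <-
      100 * (0.05 + 0.95 * lag_expr_act) *
      exp(matrix(rnorm(nrow(config$lag_plan) * n_cells, sd = 0.1),
                 nrow(config$lag_plan), n_cells))
  }
  X <- sweep(X, 2L, colSums(X), `/`) * 1e6
  dimnames(X) <- list(config$genes, meta$barcode)

  ## ---- peak latents ----------------------------------------------------
  n_peaks <- nrow(peaks)
  V <- matrix(rnorm(n_peaks * n_cells), n_peaks, n_cells,
              dimnames = list(peaks$name, meta$barcode))
  if (!is.null(config$planted_links)) {
    for (i in seq_len(nrow(config$planted_links))) {
      rho <- config$planted_links$rho[i]
      V[config$planted_links$peak[i], ] <-
        rho * U[config$planted_links$gene[i], ] +
        sqrt(1 - rho^2) * rnorm(n_cells)
    }
  }

  ## ---- accessibility counts -------------------------------------------
  depth <- exp(rnorm(n_cells, -nz$depth_cv^2 / 2, nz$depth_cv))
  if (nz$lowdepth_frac > 0) {
    low <- runif(n_cells) < nz$lowdepth_frac
    depth[low] <- depth[low] * nz$lowdepth_mult
  } else {
    low <- rep(FALSE, n_cells)
  }
  m_p <- nz$peak_mean * exp(rnorm(n_peaks, -nz$peak_mean_sdlog^2 / 2,
                                  nz$peak_mean_sdlog))
  open_mult <- .open_multiplier(config, peaks, meta)
  rate <- (m_p * exp(nz$peak_sig_sd * V - nz$peak_sig_sd^2 / 2)) *
    open_mult * rep(depth, each = n_peaks)
  if (!is.null(config$lag_plan)) {
    for (i in seq_len(nrow(config$lag_plan))) {
      pk <- paste0(config$lag_plan$gene[i], "_pk1")
      a_atac <- plogis(nz$lag_k * (meta$pseudotime -
                                     (t0 - config$lag_plan$delta[i])))
      rate[pk, ] <- m_p[match(pk, peaks$name)] * (0.05 + 0.95 * a_atac) *
        depth * open_mult[pk, ]
    }
  }
  A <- matrix(rpois(length(rate), rate), n_peaks, n_cells,
              dimnames = list(peaks$name, meta$barcode))

  ## ---- motif hits ------------------------------------------------------
  tfs <- config$tf_universe
  M <- matrix(rbinom(length(tfs) * n_peaks, 1L, nz$bg_hit_rate),
              length(tfs), n_peaks, dimnames = list(tfs, peaks$name))
  for (tfspec in config$planted_tfs) M[tfspec$tf, tfspec$peaks] <- 1L

  meta$depth_factor <- depth
  meta$planted_lowdepth <- low
  meta$rna_mapped_reads <- round(rlnorm(n_cells, nz$rna_reads_meanlog,
                                        nz$rna_reads_sdlog))

  frags <- if (config$fragments) {
    .make_fragments(A, peaks, genome, nz)
  } else NULL

  truth <- list(
    true_links = config$planted_links,
    true_network = rbindlist(lapply(config$planted_tfs, function(s)
      data.table(tf = s$tf, target = s$targets, lineage = s$lineage))),
    true_gains = if (is.null(config$gain_loss_plan)) NULL else
      config$gain_loss_plan[config$gain_loss_plan$action == "open", ],
    true_losses = if (is.null(config$gain_loss_plan)) NULL else
      config$gain_loss_plan[config$gain_loss_plan$action == "close", ],
    true_lags = config$lag_plan
  )

  structure(list(
    expression = X,
    accessibility = A,
    fragments = frags,
    peaks = peaks,
    genes = genes,
    genome = genome,
    cell_meta = meta,
    motif_hits = M,
    truth = truth,
    config = config
  ), class = "multiome_dataset")
}

#' Planted ground truth of a synthetic dataset
#'
#' @param dataset a `multiome_dataset`.
#' @return the planted-truth record (links, regulons, gains/losses, lags).
#' @export
truth_report <- function(dataset) {
  stopifnot(inherits(dataset, "multiome_dataset"))
  if (is.null(dataset$truth))
    stop("dataset carries no planted truth (not synthetic?)")
  dataset$truth
}

#' @exportS3Method base::print
print.multiome_dataset <- function(x, ...) {
  cat("multiome_dataset:", nrow(x$expression), "genes x", ncol(x$expression),
      "cells;", nrow(x$accessibility), "peaks;",
      if (is.null(x$fragments)) "no fragments" else
        paste(nrow(x$fragments), "fragment records"), "\n")
  invisible(x)
}

## ---- internals ---------------------------------------------------------

.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# genes round-robin over chromosomes, 40-kb spacing (wide enough that the
# +-25 kb cis windows of neighbours never share a peak), 5-kb bodies,
# alternating strand; TSS at body start (+) / body end (-)
.place_genes <- function(config, genome) {
  n <- config$n_genes
  chrom <- genome$chrom[((seq_len(n) - 1L) %% nrow(genome)) + 1L]
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  anchor <- 1e5 + (idx_on_chrom - 1L) * 4e4
  if (max(anchor) + 3e4 > 7.9e6)
    stop("too many genes for the synthetic genome layout")
  strand <- rep(c("+", "-"), length.out = n)
  body_start <- anchor
  body_end <- anchor + 5000L
  tss <- ifelse(strand == "+", body_start, body_end)
  data.frame(gene = config$genes, chrom = chrom, strand = strand,
             tss = as.integer(tss), body_start = as.integer(body_start),
             body_end = as.integer(body_end), stringsAsFactors = FALSE)
}

# _pk1 is a 500-bp promoter peak on the TSS; later peaks alternate sides at
# +-3, 7, 11, ... kb, all within the link window (supports up to 13 cis
# peaks per gene)
.place_peaks <- function(config, genes, genome) {
  k <- config$peaks_per_gene
  if (k > 13L) stop("at most 13 cis peaks per gene fit inside the link window")
  offs <- c(0L, as.integer((-1L)^(2:k) *
                             (3000L + floor((2:k - 2L) / 2L) * 4000L)))[seq_len(k)]
  cis <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    centre <- genes$tss[i] + offs
    data.frame(chrom = genes$chrom[i], start = centre - 250L,
               end = centre + 250L,
               name = paste0(genes$gene[i], "_pk", seq_len(k)),
               anchor_gene = genes$gene[i], stringsAsFactors = FALSE)
  }))
  if (config$n_extra_peaks > 0L) {
    nb <- config$n_extra_peaks
    chrom <- genome$chrom[((seq_len(nb) - 1L) %% nrow(genome)) + 1L]
    idx <- stats::ave(seq_len(nb), chrom, FUN = seq_along)
    centre <- as.integer(8e6 + idx * 5e4)  # beyond the gene-bearing region
    bg <- data.frame(chrom = chrom, start = centre - 250L, end = centre + 250L,
                     name = sprintf("bg_pk%04d", seq_len(nb)),
                     anchor_gene = NA_character_, stringsAsFactors = FALSE)
    cis <- rbind(cis, bg)
  }
  stopifnot(all(cis$start >= 0), all(cis$end <= 10e6))
  rownames(cis) <- NULL
  cis
}

.make_cells <- function(config) {
  grid <- expand.grid(stage = config$stages, lineage = config$lineages,
                      stringsAsFactors = FALSE)
  meta <- grid[rep(seq_len(nrow(grid)), each = config$cells_per_group), ]
  meta$stage_idx <- match(meta$stage, config$stages)
  n <- nrow(meta)
  meta$barcode <- sprintf("cell_%04d_%s_%s", seq_len(n), meta$lineage, meta$stage)
  meta$pseudotime <- (meta$stage_idx - 1) + runif(n)
  rownames(meta) <- NULL
  meta[, c("barcode", "lineage", "stage", "stage_idx", "pseudotime")]
}

# peaks x cells multiplier implementing the stage-wise open/close plan
.open_multiplier <- function(config, peaks, meta) {
  mult <- matrix(1, nrow(peaks), nrow(meta),
                 dimnames = list(peaks$name, meta$barcode))
  plan <- config$gain_loss_plan
  if (is.null(plan)) return(mult)
  for (i in seq_len(nrow(plan))) {
    at <- match(plan$stage[i], config$stages)
    if (plan$action[i] == "open") {
      mult[plan$peak[i], meta$stage_idx < at] <- config$noise$closed_mult
    } else {
      mult[plan$peak[i], meta$stage_idx >= at] <- config$noise$closed_mult
    }
  }
  mult
}

# expand in-peak counts to one record per count unit, add off-peak records
# sampled outside peaks, coordinate-sort
.make_fragments <- function(A, peaks, genome, nz) {
  nzi <- which(A > 0L, arr.ind = TRUE)
  counts <- A[nzi]
  pk <- rep.int(nzi[, 1L], counts)
  cell <- rep.int(nzi[, 2L], counts)
  len <- as.integer(nz$frag_len)
  span <- peaks$end[pk] - peaks$start[pk] - len
  start <- peaks$start[pk] + as.integer(floor(runif(length(pk)) * pmax(span, 1L)))
  inpeak <- data.table(chrom = peaks$chrom[pk], start = start,
                       end = start + len, barcode = colnames(A)[cell],
                       count = 1L)

  total_in <- colSums(A)
  n_off <- rpois(ncol(A), total_in * nz$offpeak_frac / (1 - nz$offpeak_frac))
  off <- NULL
  if (sum(n_off) > 0L) {
    cell_off <- rep.int(seq_len(ncol(A)), n_off)
    m <- length(cell_off)
    ci <- sample.int(nrow(genome), m, replace = TRUE,
                     prob = genome$length / sum(genome$length))
    start <- as.integer(floor(runif(m) * (genome$length[ci] - len)))
    pk_gr <- GRanges(peaks$chrom, IRanges(peaks$start + 1L, peaks$end))
    for (round in 1:5) {
      fr_gr <- GRanges(genome$chrom[ci], IRanges(start + 1L, start + len))
      bad <- unique(queryHits(findOverlaps(fr_gr, pk_gr)))
      if (length(bad) == 0L) break
      ci[bad] <- sample.int(nrow(genome), length(bad), replace = TRUE,
                            prob = genome$length / sum(genome$length))
      start[bad] <- as.integer(floor(runif(length(bad)) *
                                       (genome$length[ci[bad]] - len)))
    }
    fr_gr <- GRanges(genome$chrom[ci], IRanges(start + 1L, start + len))
    bad <- unique(queryHits(findOverlaps(fr_gr, pk_gr)))
    keep <- setdiff(seq_len(m), bad)
    if (length(keep) > 0L)
      off <- data.table(chrom = genome$chrom[ci[keep]], start = start[keep],
                        end = start[keep] + len,
                        barcode = colnames(A)[cell_off[keep]], count = 1L)
  }
  frags <- rbindlist(list(inpeak, off))
  setorder(frags, chrom, start, end, barcode)
  frags[]
}
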