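# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (GRanges overlap machinery, tcrossprod
# correlations, igraph, phyper) so they can serve as cross-checks.

# 1-bp-overlap test on 0-based half-open intervals
ivl_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# exhaustive per-record QC recount: one pass over every fragment x region pair
recount_qc <- function(fragments, peaks, promoters) {
  bcs <- sort(unique(fragments$barcode))
  out <- data.frame(barcode = bcs, usable_fragments = 0, promoter_fragments = 0,
                    in_peak_fragments = 0)
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    j <- match(f$barcode, bcs)
    out$usable_fragments[j] <- out$usable_fragments[j] + f$count
    in_prom <- any(promoters$chrom == f$chrom &
                     ivl_overlaps(f$start, f$end, promoters$start, promoters$end))
    in_peak <- any(peaks$chrom == f$chrom &
                     ivl_overlaps(f$start, f$end, peaks$start, peaks$end))
    if (in_prom) out$promoter_fragments[j] <- out$promoter_fragments[j] + f$count
    if (in_peak) out$in_peak_fragments[j] <- out$in_peak_fragments[j] + f$count
  }
  out$promoter_fraction <- out$promoter_fragments / out$usable_fragments
  out$frip <- out$in_peak_fragments / out$usable_fragments
  out
}

# Pearson correlation from first principles
brute_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hypergeometric upper tail P[X >= k] by direct summation of choose() terms
hyper_tail_enum <- function(k, total, hits, draws) {
  xs <- k:min(hits, draws)
  xs <- xs[draws - xs <= total - hits]
  if (length(xs) == 0) return(0)
  sum(choose(hits, xs) * choose(total - hits, draws - xs)) /
    choose(total, draws)
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Wasserman-Faust closeness from a Floyd-Warshall distance matrix
closeness_oracle <- function(adj) {
  d <- fw_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(di[reach]))
  }, numeric(1))
}

# eigenvector centrality oracle: dense eigendecomposition per component,
# nonnegative unit-L2 dominant vector, scaled by spectral radius relative to
# the largest component
eigen_oracle <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    comp[is.finite(d[i, ])] <- cid
  }
  vec <- numeric(n)
  lam <- numeric(cid)
  for (ci in seq_len(cid)) {
    idx <- which(comp == ci)
    if (length(idx) == 1) { vec[idx] <- 1; lam[ci] <- 0; next }
    e <- eigen(adj[idx, idx], symmetric = TRUE)
    lam[ci] <- e$values[1]
    v <- abs(e$vectors[, 1])
    vec[idx] <- v / sqrt(sum(v^2))
  }
  scale_by <- if (max(lam) > 0) lam / max(lam) else rep(1, cid)
  vec * scale_by[comp]
}

# random undirected graph fixture on <= 12 nodes (adjacency + edge list)
random_graph_fixture <- function(seed, n = NULL, p = 0.3) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:12, 1)
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
  # avoid fully isolated vertices: tie each to its successor if degree 0
  for (i in which(rowSums(adj) == 0)) {
    j <- if (i < n) i + 1 else 1
    adj[i, j] <- adj[j, i] <- 1
  }
  nm <- paste0("v", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  list(adj = adj, edges = data.frame(from = nm[ut[, 1]], to = nm[ut[, 2]]))
}

# small synthetic multiome shortcuts used by several files
quick_config <- function(seed, ...) {
  sim_config(seed = seed, n_lineages = 2, cells_per_group = 10, n_genes = 20,
             n_extra_peaks = 10, fragments = FALSE, ...)
}
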