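#' Build a TF-target regulatory network from links and motif hits
#'
#' An edge (tf, gene) exists when at least one peak is both significantly
#' linked to the gene and carries the TF's motif; its linkage score is the
#' sum of squared link correlations (sum of r^2) over exactly those
#' supporting peaks. Intended inputs are TFs and marker genes called in the
#' same cell group, so the network describes one group's regulatory program.
#'
#' @param tfs candidate TF names (rows of `motif_hits`).
#' @param marker_genes candidate target gene names.
#' @param links link table from [link_peaks_to_genes()].
#' @param motif_hits TFs x peaks binary matrix.
#' @return a `regulatory_network`: list with `edges` (tf, target, n_peaks,
#'   linkage_score, supporting peak list) and `nodes` (name, type).
#' @export
build_network <- function(tfs, marker_genes, links, motif_hits) {
  if (is.null(links) || nrow(links) == 0L) stop("empty link table")
  if (is.null(motif_hits) || nrow(motif_hits) == 0L) stop("empty motif table")
  tfs <- intersect(tfs, rownames(motif_hits))
  sig <- links[links$significant & links$gene %in% marker_genes, , drop = FALSE]
  edges <- list()
  for (tf in tfs) {
    hitpk <- colnames(motif_hits)[motif_hits[tf, ] > 0]
    sup <- sig[sig$peak %in% hitpk, , drop = FALSE]
    if (nrow(sup) == 0L) next
    sc <- tapply(sup$r^2, sup$gene, sum)
    np <- tapply(sup$peak, sup$gene, length)
    pk <- tapply(sup$peak, sup$gene, function(x) paste(sort(x), collapse = ","))
    edges[[tf]] <- data.frame(tf = tf, target = names(sc),
                              n_peaks = as.integer(np),
                              linkage_score = as.numeric(sc),
                              supporting_peaks = as.character(pk),
                              stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character(),
                        n_peaks = integer(), linkage_score = numeric(),
                        supporting_peaks = character())
  rownames(edges) <- NULL
  nodes <- data.frame(
    name = c(unique(edges$tf), setdiff(unique(edges$target), unique(edges$tf))),
    stringsAsFactors = FALSE)
  nodes$type <- ifelse(nodes$name %in% edges$tf, "tf", "target")
  structure(list(edges = edges, nodes = nodes), class = "regulatory_network")
}

#' @exportS3Method base::print
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Degree, closeness and eigenvector centrality of a network
#'
#' Computed on the undirected, unweighted projection of the TF-target graph.
#' Degree centrality is degree / (n - 1). Closeness uses the
#' Wasserman-Faust component scaling: `(r / (n - 1)) * (r / sum d)` with `r`
#' the nodes reachable from the vertex. Eigenvector centrality is obtained by
#' power iteration per connected component on the adjacency plus identity
#' (the shift leaves eigenvectors unchanged and guarantees convergence on
#' bipartite components), tolerance 1e-8, at most 1000 iterations,
#' nonnegative and L2-normalized within each component; components are then
#' scaled by their spectral radius relative to the largest so the dominant
#' component keeps scale 1.
#'
#' @param network a `regulatory_network` or an edge data.frame with the first
#'   two columns naming the endpoints.
#' @return data.frame: node, type (if known), degree, closeness, eigenvector.
#' @export
network_centralities <- function(network) {
  edges <- if (inherits(network, "regulatory_network")) network$edges else network
  if (is.null(edges) || nrow(edges) == 0L) stop("empty network")
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, 1:2], directed = FALSE))
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g) / max(n - 1L, 1L)

  D <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / (n - 1L)) * (r / sum(d[reach]))
  }, numeric(1L))

  comp <- igraph::components(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  eig <- numeric(n)
  lambda <- numeric(comp$no)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1L) { eig[idx] <- 1; lambda[ci] <- 0; next }
    sub <- adj[idx, idx, drop = FALSE]
    pw <- .power_iteration(sub, tol = 1e-8, max_iter = 1000L, component = ci)
    eig[idx] <- pw$vector
    lambda[ci] <- pw$value
  }
  scale_by <- if (max(lambda) > 0) lambda / max(lambda) else rep(1, comp$no)
  eig <- eig * scale_by[comp$membership]

  out <- data.frame(node = nm, degree = as.numeric(deg),
                    closeness = clo, eigenvector = eig,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (inherits(network, "regulatory_network"))
    out$type <- network$nodes$type[match(out$node, network$nodes$name)]
  out
}

# dominant eigenpair of a nonnegative symmetric matrix via shifted power
# iteration; returns the L2-normalized nonnegative vector and the eigenvalue
# of the unshifted matrix
.power_iteration <- function(a, tol = 1e-8, max_iter = 1000L, component = NA) {
  nloc <- nrow(a)
  x <- rep(1 / sqrt(nloc), nloc)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + x  # (A + I) x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(list(vector = x, value = 0))
    y <- y / nrm
    if (sqrt(sum((y - x)^2)) < tol) {
      lam <- sum(y * as.numeric(a %*% y))
      return(list(vector = abs(y), value = lam))
    }
    x <- y
  }
  stop("eigenvector power iteration failed to converge on component ",
       component)
}

#' Rank TFs by driving potential
#'
#' Within the supplied TF subset, each centrality is ranked descending (most
#' central = rank 1, ties share the average rank); the comprehensive rank is
#' the sum of the three ranks and the output is sorted ascending on it
#' (smallest sum = strongest inferred driver), with ties broken by TF name.
#'
#' @param centralities output of [network_centralities()].
#' @param tfs TF names to rank; defaults to nodes typed `"tf"`.
#' @return data.frame: tf, degree, closeness, eigenvector, degree_rank,
#'   closeness_rank, eigenvector_rank, comprehensive_rank.
#' @export
driving_potential <- function(centralities, tfs = NULL) {
  if (is.null(tfs)) {
    if (!"type" %in% names(centralities))
      stop("supply tfs explicitly when centralities carry no node types")
    tfs <- centralities$node[centralities$type == "tf"]
  }
  sub <- centralities[centralities$node %in% tfs, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no TFs to rank")
  rk <- function(x) rank(-x, ties.method = "average")
  out <- data.frame(tf = sub$node, degree = sub$degree,
                    closeness = sub$closeness, eigenvector = sub$eigenvector,
                    degree_rank = rk(sub$degree),
                    closeness_rank = rk(sub$closeness),
                    eigenvector_rank = rk(sub$eigenvector),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$comprehensive_rank <- out$degree_rank + out$closeness_rank +
    out$eigenvector_rank
  out[order(out$comprehensive_rank, out$tf), ]
}
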