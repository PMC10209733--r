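toy_gene_models <- function(strand = c("+", "-")) {
  data.frame(gene = c("gPlus", "gMinus"), chrom = "chr1", strand = strand,
             tss = c(10000L, 42000L), body_start = c(10000L, 40000L),
             body_end = c(12000L, 42000L))
}

test_that("gene activity windows are strand-aware with a 2-kb upstream", {
  genes <- toy_gene_models()
  # fragment at [8500, 8600): within 2 kb upstream of gPlus (+ strand)
  fr <- data.frame(chrom = "chr1", start = 8500L, end = 8600L,
                   barcode = "bc1", count = 1L)
  act <- gene_activity(fr, genes)
  expect_equal(act["gPlus", "bc1"], 1)
  expect_equal(act["gMinus", "bc1"], 0)
  # the same offset upstream of a - strand gene sits downstream of its body
  fr2 <- data.frame(chrom = "chr1", start = 38500L, end = 38600L,
                    barcode = "bc1", count = 2L)
  act2 <- gene_activity(fr2, genes)
  expect_equal(act2["gMinus", "bc1"], 0)
  # - strand upstream extension is past body_end
  fr3 <- data.frame(chrom = "chr1", start = 43500L, end = 43600L,
                    barcode = "bc1", count = 2L)
  act3 <- gene_activity(fr3, genes)
  expect_equal(act3["gMinus", "bc1"], 2)
  expect_equal(act3["gPlus", "bc1"], 0)
})

test_that("gene activity handles empty input and missing strand", {
  genes <- toy_gene_models()
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), barcode = character(),
                      count = integer())
  act <- gene_activity(empty, genes, barcodes = c("a", "b"))
  expect_true(all(act == 0))
  expect_equal(dim(act), c(2L, 2L))
  genes$strand[1] <- "*"
  expect_error(gene_activity(empty, genes), "strand")
})

# a small fully controlled linking universe: 2 chromosomes, 3 genes with one
# cis peak each plus trans peaks for the null
linking_toy <- function(seed = 1, n_cells = 40) {
  set.seed(seed)
  genes <- data.frame(gene = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "chr2"), strand = "+",
                      tss = c(100000L, 300000L, 100000L))
  cis <- data.frame(chrom = genes$chrom, start = genes$tss - 250L,
                    end = genes$tss + 250L,
                    name = paste0(genes$gene, "_pk"))
  trans <- data.frame(chrom = rep(c("chr1", "chr2"), each = 100),
                      start = 1e6 + (1:200) * 2000L,
                      end = 1e6 + (1:200) * 2000L + 500L,
                      name = paste0("tp", 1:200))
  peaks <- rbind(cis, trans)
  X <- matrix(rlnorm(3 * n_cells), 3, n_cells,
              dimnames = list(genes$gene, paste0("c", 1:n_cells)))
  A <- matrix(rpois(nrow(peaks) * n_cells, 10), nrow(peaks), n_cells,
              dimnames = list(peaks$name, paste0("c", 1:n_cells)))
  # make gA's cis peak track gA's expression
  A["gA_pk", ] <- round(20 * X["gA", ] / mean(X["gA", ]))
  list(genes = genes, peaks = peaks, X = X, A = A)
}

test_that("link correlations equal a brute-force Pearson oracle", {
  toy <- linking_toy()
  lk <- link_peaks_to_genes(toy$A, toy$X, toy$genes, toy$peaks,
                            normalize = "none", seed = 5)
  expect_gt(nrow(lk), 0)
  for (i in seq_len(nrow(lk))) {
    expect_equal(lk$r[i],
                 brute_cor(toy$X[lk$gene[i], ], toy$A[lk$peak[i], ]),
                 tolerance = 1e-12)
  }
})

test_that("scaling a gene's expression leaves its links unchanged", {
  toy <- linking_toy()
  lk1 <- link_peaks_to_genes(toy$A, toy$X, toy$genes, toy$peaks,
                             normalize = "none", seed = 5)
  X2 <- toy$X
  X2["gA", ] <- X2["gA", ] * 17.3
  lk2 <- link_peaks_to_genes(toy$A, X2, toy$genes, toy$peaks,
                             normalize = "none", seed = 5)
  a1 <- lk1[lk1$gene == "gA", ]
  a2 <- lk2[lk2$gene == "gA", ]
  expect_equal(a1$r, a2$r, tolerance = 1e-12)
  expect_equal(a1$z, a2$z, tolerance = 1e-9)
  expect_identical(a1$significant, a2$significant)
})

test_that("the cis window is a hard candidate boundary", {
  toy <- linking_toy()
  # peak entirely beyond 25 kb of gB's TSS (nearest base at 25,001)
  far <- data.frame(chrom = "chr1", start = 325001L, end = 325501L,
                    name = "far_pk")
  near <- data.frame(chrom = "chr1", start = 324999L, end = 325499L,
                     name = "near_pk")
  peaks <- rbind(toy$peaks, far, near)
  A <- rbind(toy$A,
             matrix(rpois(2 * ncol(toy$A), 10), 2, ncol(toy$A),
                    dimnames = list(c("far_pk", "near_pk"), colnames(toy$A))))
  lk <- link_peaks_to_genes(A, toy$X, toy$genes, peaks, seed = 5)
  expect_false("far_pk" %in% lk$peak[lk$gene == "gB"])
  expect_true("near_pk" %in% lk$peak[lk$gene == "gB"])
  d <- lk$distance_to_tss[lk$gene == "gB" & lk$peak == "near_pk"]
  expect_equal(d, 24999)
})

test_that("self-correlation vanishes once cells are shuffled", {
  # a permuted pair is a null pair, so rejections occur at the nominal level;
  # alpha = 0.01 makes "almost never significant" a sharp, stable bound
  toy <- linking_toy(seed = 2, n_cells = 50)
  hits <- 0
  zs <- numeric(100)
  for (s in 1:100) {
    set.seed(1000 + s)
    A <- toy$A
    A["gA_pk", ] <- A["gA_pk", sample(ncol(A))]
    lk <- link_peaks_to_genes(A, toy$X, toy$genes, toy$peaks, alpha = 0.01,
                              seed = s)
    row <- lk[lk$gene == "gA" & lk$peak == "gA_pk", ]
    zs[s] <- row$z
    if (nrow(row) == 1 && row$significant) hits <- hits + 1
  }
  expect_lte(hits, 5)  # non-significant in >= 95% of seeded repeats
  expect_lt(median(abs(zs)), 1.5)  # |z| small throughout
})

test_that("degenerate linking inputs error or are skipped", {
  toy <- linking_toy()
  one_chr <- toy$peaks[toy$peaks$chrom == "chr1", ]
  expect_error(link_peaks_to_genes(toy$A[one_chr$name, ], toy$X, toy$genes,
                                   one_chr, seed = 1),
               "2 chromosomes")
  # a zero-variance peak (on the values being correlated) is skipped
  A <- toy$A
  A["gB_pk", ] <- 4
  lk <- link_peaks_to_genes(A, toy$X, toy$genes, toy$peaks,
                            normalize = "none", seed = 1)
  expect_false("gB_pk" %in% lk$peak)
  expect_true("gB_pk" %in% attr(lk, "skipped"))
  dup <- toy$peaks
  dup$name[2] <- dup$name[1]
  expect_error(link_peaks_to_genes(toy$A, toy$X, toy$genes, dup, seed = 1),
               "duplicate")
})

test_that("a planted strong link is recovered as significant", {
  cfg <- sim_config(seed = 31, n_lineages = 2, cells_per_group = 67,
                    n_genes = 40, n_extra_peaks = 10,
                    planted_links = data.frame(gene = "g0005", peak = NA,
                                               rho = 0.7),
                    fragments = FALSE)
  ds <- generate_multiome(cfg)
  lk <- link_peaks_to_genes(ds$accessibility, ds$expression, ds$genes,
                            ds$peaks, seed = 7)
  row <- lk[lk$gene == "g0005" & lk$peak == "g0005_pk1", ]
  expect_true(row$significant)
  expect_gt(row$r, 0.4)
})

test_that("metacell pooling preserves link recovery", {
  cfg <- sim_config(seed = 32, n_lineages = 2, cells_per_group = 67,
                    n_genes = 30, n_extra_peaks = 10,
                    planted_links = data.frame(gene = "g0005", peak = NA,
                                               rho = 0.7),
                    fragments = FALSE)
  ds <- generate_multiome(cfg)
  lk <- link_peaks_to_genes(ds$accessibility, ds$expression, ds$genes,
                            ds$peaks, aggregate_k = 3,
                            cell_meta = ds$cell_meta, seed = 7)
  row <- lk[lk$gene == "g0005" & lk$peak == "g0005_pk1", ]
  expect_true(row$significant)
})

test_that("DORC calling applies the strict >10 significant-links rule", {
  mk <- function(gene, n_sig, n_nonsig = 2) {
    data.frame(gene = gene, peak = paste0(gene, "_", seq_len(n_sig + n_nonsig)),
               distance_to_tss = 0L, r = 0.5, z = 3, p = 0.001,
               significant = rep(c(TRUE, FALSE), c(n_sig, n_nonsig)))
  }
  links <- rbind(mk("gEleven", 11), mk("gTen", 10))
  dorcs <- call_dorcs(links)
  expect_true(dorcs$is_dorc[dorcs$gene == "gEleven"])
  expect_false(dorcs$is_dorc[dorcs$gene == "gTen"])
  expect_equal(dorcs$n_significant_links, c(11L, 10L))
  empty <- links[0, ]
  expect_equal(nrow(call_dorcs(empty)), 0)
})
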