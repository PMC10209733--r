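mk_degs <- function(dataset, lfcs, genes = names(lfcs[[1]])) {
  do.call(rbind, lapply(seq_along(lfcs), function(o)
    data.frame(dataset = dataset, ordinal = o, gene = genes,
               log_fc = lfcs[[o]], p = 1e-3)))
}

test_that("divergent genes need growing magnitude and a constant sign", {
  lfcs <- list(c(up = 0.2, bump = 0.2, flip = 0.5),
               c(up = 0.8, bump = 1.5, flip = -1.0),
               c(up = 1.5, bump = 0.8, flip = -2.0))
  sel <- select_divergent_genes(mk_degs("d1", lfcs))
  expect_identical(sel$gene, "up")
  expect_identical(sel$side, "EPI")
  # TE side from negative log fold changes
  te <- select_divergent_genes(mk_degs("d1", list(c(g = -0.3), c(g = -0.9))))
  expect_identical(te$side, "TE")
  expect_error(select_divergent_genes(mk_degs("d1", list(c(g = 1)))),
               "single stage pair")
})

test_that("a gene absent from one ordinal never qualifies", {
  degs <- rbind(
    data.frame(dataset = "d1", ordinal = 1, gene = "gA", log_fc = 0.5, p = 0.01),
    data.frame(dataset = "d1", ordinal = 2, gene = c("gA", "gB"),
               log_fc = c(1.0, 0.8), p = 0.01),
    data.frame(dataset = "d1", ordinal = 3, gene = c("gA", "gB"),
               log_fc = c(1.5, 1.6), p = 0.01))
  sel <- select_divergent_genes(degs)
  expect_true("gA" %in% sel$gene)
  expect_false("gB" %in% sel$gene)  # ordinal-1 log fold change treated as 0
})

test_that("the optional p clause prunes non-sharpening genes", {
  degs <- rbind(mk_degs("d1", list(c(g1 = 0.2, g2 = 0.2),
                                   c(g1 = 0.8, g2 = 0.8))))
  degs$p[degs$gene == "g2" & degs$ordinal == 2] <- 0.9
  degs$p[degs$gene == "g2" & degs$ordinal == 1] <- 1e-4
  both <- select_divergent_genes(degs)
  pruned <- select_divergent_genes(degs, require_p_nonincreasing = TRUE)
  expect_setequal(both$gene, c("g1", "g2"))
  expect_identical(pruned$gene, "g1")
})

test_that("driver overlap respects sides and is commutative", {
  a <- data.frame(gene = c("g1", "g2"), side = c("EPI", "TE"))
  b <- data.frame(gene = c("g1", "g2"), side = c("EPI", "EPI"))
  expect_equal(overlap_drivers(a, b),
               data.frame(gene = "g1", side = "EPI"))
  expect_equal(overlap_drivers(a, b), overlap_drivers(b, a))
  expect_equal(nrow(overlap_drivers(a, data.frame(gene = "g9", side = "EPI"))),
               0)
  expect_equal(overlap_drivers(a, a), a[order(a$gene), ],
               ignore_attr = TRUE)
})

test_that("difference ratios are zero at identical phases and antisymmetric", {
  cfg <- driver_study_config(seed = 41, cells_per_group = 15, fragments = FALSE)
  ds <- generate_multiome(cfg)
  act <- ds$accessibility[paste0(rownames(ds$expression), "_pk1"), ]
  rownames(act) <- rownames(ds$expression)
  drv <- data.frame(gene = c("g0006", "g0010"), side = "EPI")
  same <- difference_ratios(drv, ds$expression, act, ds$cell_meta,
                            pre_stages = "A", post_stages = "A")
  expect_equal(same$expr_ratio, c(0, 0))
  fwd <- difference_ratios(drv, ds$expression, act, ds$cell_meta,
                           pre_stages = "A", post_stages = "C")
  rev <- difference_ratios(drv, ds$expression, act, ds$cell_meta,
                           pre_stages = "C", post_stages = "A")
  expect_equal(fwd$expr_ratio, -rev$expr_ratio, tolerance = 1e-12)
  expect_equal(fwd$activity_ratio, -rev$activity_ratio, tolerance = 1e-12)
})

test_that("planted amplifying divergence yields positive expression ratios", {
  pos <- sapply(1:5, function(s) {
    cfg <- driver_study_config(seed = 200 + s, cells_per_group = 15,
                               fragments = FALSE)
    ds <- generate_multiome(cfg)
    act <- ds$accessibility[paste0(rownames(ds$expression), "_pk1"), ]
    rownames(act) <- rownames(ds$expression)
    targets <- truth_report(ds)$true_network$target[1:4]
    dr <- difference_ratios(data.frame(gene = targets, side = "EPI"),
                            ds$expression, act, ds$cell_meta,
                            pre_stages = "A", post_stages = "C")
    mean(dr$expr_ratio > 0)
  })
  expect_gte(mean(pos), 0.9)
})

test_that("the lineage TF filter applies the three-condition rule", {
  epi <- data.frame(tf = c("t1", "t2", "t3"),
                    p = c(0.001, 0.001, 0.5),
                    fold_enrichment = c(3, 3, 1))
  te <- data.frame(tf = c("t1", "t2", "t3"),
                   p = c(0.5, 0.005, 0.001),
                   fold_enrichment = c(1, 1, 4))
  calls <- lineage_tf_filter(epi, te)
  expect_identical(calls$enriched_in[calls$tf == "t1"], "EPI")
  expect_false("t2" %in% calls$tf)  # TE p not > 0.01
  expect_identical(calls$enriched_in[calls$tf == "t3"], "TE")
  # identical tables satisfy nothing (fold_in > fold_out fails)
  expect_equal(nrow(lineage_tf_filter(epi, epi)), 0)
  # a TF absent from one table is treated as p = 1, fold = 0
  expect_message(calls2 <- lineage_tf_filter(epi, te[-1, ]), "missing")
  expect_identical(calls2$enriched_in[calls2$tf == "t1"], "EPI")
})

test_that("regulating-TF counts come from motif hits on significant links", {
  links <- data.frame(gene = c("g1", "g1", "g1"),
                      peak = c("p1", "p2", "p3"),
                      distance_to_tss = 0L, r = 0.5, z = 5,
                      p = c(1e-4, 1e-4, 0.5),
                      significant = c(TRUE, TRUE, FALSE))
  hits <- matrix(0, 3, 3, dimnames = list(c("t1", "t2", "t3"),
                                          c("p1", "p2", "p3")))
  hits["t1", "p1"] <- 1
  hits["t2", "p2"] <- 1
  hits["t3", "p3"] <- 1  # only on the non-significant link
  expect_equal(count_regulating_tfs("g1", links, hits), 2L)
  expect_equal(count_regulating_tfs("gX", links, hits), 0L)
})
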