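test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_lineages = 2, cells_per_group = 8,
                    n_genes = 15, n_extra_peaks = 5)
  ds1 <- generate_multiome(cfg)
  ds2 <- generate_multiome(cfg)
  expect_identical(ds1$expression, ds2$expression)
  expect_identical(ds1$accessibility, ds2$accessibility)
  expect_identical(ds1$fragments, ds2$fragments)
  expect_identical(ds1$motif_hits, ds2$motif_hits)
  # a different seed changes the data
  ds3 <- generate_multiome(sim_config(seed = 8, n_lineages = 2,
                                      cells_per_group = 8, n_genes = 15,
                                      n_extra_peaks = 5))
  expect_false(identical(ds1$expression, ds3$expression))
})

test_that("matrices are unchanged by skipping fragment emission", {
  cfg_f <- sim_config(seed = 3, n_lineages = 2, cells_per_group = 6,
                      n_genes = 12, n_extra_peaks = 4, fragments = TRUE)
  cfg_n <- sim_config(seed = 3, n_lineages = 2, cells_per_group = 6,
                      n_genes = 12, n_extra_peaks = 4, fragments = FALSE)
  expect_identical(generate_multiome(cfg_f)$accessibility,
                   generate_multiome(cfg_n)$accessibility)
})

test_that("modalities are cell-paired and fragments reconcile with counts", {
  cfg <- sim_config(seed = 11, n_lineages = 2, cells_per_group = 6,
                    n_genes = 12, n_extra_peaks = 4,
                    noise = list(peak_mean = 5, offpeak_frac = 0.2))
  ds <- generate_multiome(cfg)
  expect_identical(colnames(ds$expression), colnames(ds$accessibility))
  expect_identical(colnames(ds$expression), ds$cell_meta$barcode)
  # per-cell in-peak fragment totals equal accessibility column sums
  pk <- ds$peaks
  fr <- ds$fragments
  in_peak <- vapply(seq_len(nrow(fr)), function(i)
    any(pk$chrom == fr$chrom[i] &
          ivl_overlaps(fr$start[i], fr$end[i], pk$start, pk$end)),
    logical(1))
  tot <- tapply(fr$count[in_peak], fr$barcode[in_peak], sum)
  expect_equal(as.numeric(tot[colnames(ds$accessibility)]),
               unname(colSums(ds$accessibility)))
  # fragment coordinates are valid half-open intervals on declared chromosomes
  expect_true(all(fr$start >= 0 & fr$end > fr$start))
  expect_true(all(fr$chrom %in% ds$genome$chrom))
})

test_that("a planted rho = 0.7 link lands near its target correlation", {
  cfg <- sim_config(seed = 21, n_lineages = 2, cells_per_group = 67,
                    n_genes = 40, n_extra_peaks = 10,
                    planted_links = data.frame(gene = "g0010", peak = NA,
                                               rho = 0.7),
                    fragments = FALSE)
  ds <- generate_multiome(cfg)
  r <- cor(normalize_log1p(ds$expression)["g0010", ],
           normalize_log1p(ds$accessibility)["g0010_pk1", ])
  expect_gt(r, 0.55)
  expect_lt(r, 0.85)
})

test_that("a peak opened at stage B is silent before and open after", {
  cfg <- sim_config(seed = 5, n_lineages = 2, cells_per_group = 50,
                    n_genes = 20, n_extra_peaks = 10,
                    gain_loss_plan = data.frame(stage = "B", peak = "bg_pk0001",
                                                action = "open"),
                    fragments = FALSE)
  ds <- generate_multiome(cfg)
  meta <- ds$cell_meta
  nz <- ds$accessibility["bg_pk0001", ] > 0
  expect_gt(mean(nz[meta$stage == "B"]), 0.25)
  expect_lte(mean(nz[meta$stage == "A"]), 0.05)
})

test_that("planted cis structure respects the configured invariants", {
  cfg <- quick_config(1)
  ds <- generate_multiome(cfg)
  # every cis peak lies within the link window of its anchor gene's TSS
  cis <- ds$peaks[!is.na(ds$peaks$anchor_gene), ]
  tss <- ds$genes$tss[match(cis$anchor_gene, ds$genes$gene)]
  expect_true(all(cis$end > tss - cfg$link_window &
                    cis$start < tss + cfg$link_window))
  expect_true(all(ds$peaks$start < ds$peaks$end))
  # at least 2 chromosomes so trans nulls exist
  expect_gte(length(unique(ds$peaks$chrom)), 2)
})

test_that("truth_report passes the planted design through verbatim", {
  links <- data.frame(gene = sprintf("g%04d", 1:12), peak = NA, rho = 0.5)
  cfg <- sim_config(seed = 2, n_lineages = 2, cells_per_group = 5,
                    n_genes = 20, n_extra_peaks = 5, planted_links = links,
                    planted_tfs = list(list(tf = "g0015",
                                            targets = c("g0001", "g0002"),
                                            lineage = "EPI")),
                    fragments = FALSE)
  tr <- truth_report(generate_multiome(cfg))
  expect_equal(nrow(tr$true_links), 12)
  expect_null(tr$true_gains)
  expect_equal(sum(tr$true_network$tf == "g0015"), 2)
  # a dataset without truth refuses
  ds <- generate_multiome(cfg)
  ds$truth <- NULL
  expect_error(truth_report(ds), "no planted truth")
})

test_that("inconsistent configurations are rejected", {
  expect_error(sim_config(seed = 1, n_genes = 10,
                          planted_links = data.frame(gene = "g0001",
                                                     peak = "nope", rho = 0.5)),
               "outside the peak universe|outside peak universe")
  expect_error(sim_config(seed = 1, n_genes = 10,
                          planted_links = data.frame(gene = "g0099",
                                                     peak = NA, rho = 0.5)),
               "gene universe")
  expect_error(sim_config(seed = 1, n_lineages = 1), "2 lineages")
  expect_error(sim_config(seed = 1, n_genes = 10,
                          gain_loss_plan = data.frame(stage = "Z",
                                                      peak = "g0001_pk1",
                                                      action = "open")),
               "stage")
})

test_that("datasets round-trip losslessly through the writers and readers", {
  cfg <- sim_config(seed = 9, n_lineages = 2, cells_per_group = 3,
                    n_genes = 8, n_extra_peaks = 3)
  ds <- generate_multiome(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_multiome_dataset(ds, dir)
  expect_true(all(file.exists(manifest)))
  back <- read_multiome_dataset(dir)
  expect_equal(back$expression, ds$expression, tolerance = 1e-7)
  expect_equal(back$accessibility, ds$accessibility)
  expect_equal(back$motif_hits, ds$motif_hits)
  expect_equal(nrow(back$fragments), nrow(ds$fragments))
  # fragments.tsv row count equals the number of fragment records
  expect_equal(length(readLines(file.path(dir, "fragments.tsv"))),
               nrow(ds$fragments))
  # BED format invariant: 0-based half-open, start < end
  bed <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_true(all(bed$start < bed$end))
  expect_true(all(bed$start >= 0))
})
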