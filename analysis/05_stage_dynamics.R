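#!/usr/bin/env Rscript
# Step 5 — gained/lost peaks across stages and chromatin-priming patterns.
#
# Within the TE lineage, computes per-stage accessible peak sets (>25% of
# cells nonzero), the gained and lost peaks across the ordered transitions
# A->B and B->C with per-gene change counts (1 / 2 / >=3 buckets), and
# classifies the lag-planted genes' accessibility-vs-expression timing along
# pseudotime. Writes results/stage_peaks.tsv, results/transitions.tsv,
# results/gene_change_counts.tsv and results/patterns.tsv.

library(chromprime)

ds <- read_multiome_dataset("results/dataset")
kept <- readLines("results/kept_cells.txt")
meta <- ds$cell_meta[match(kept, ds$cell_meta$barcode), ]
te <- meta$barcode[meta$lineage == "TE"]
A <- ds$accessibility[, te]
te_meta <- meta[match(te, meta$barcode), ]

acc <- accessible_by_stage(A, te_meta, stages = c("A", "B", "C"))
write.table(
  data.frame(stage = rep(names(acc), lengths(acc)), peak = unlist(acc)),
  "results/stage_peaks.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("accessible peaks per stage:",
    paste(names(acc), lengths(acc), collapse = ", "), "\n")

gl <- gained_lost(acc, data.frame(from = c("A", "B"), to = c("B", "C")),
                  genes = ds$genes, peaks = ds$peaks)
tr_tab <- do.call(rbind, lapply(gl$transitions, function(tr) rbind(
  if (length(tr$gained)) data.frame(from = tr$from, to = tr$to,
                                    peak = tr$gained, direction = "gained"),
  if (length(tr$lost)) data.frame(from = tr$from, to = tr$to,
                                  peak = tr$lost, direction = "lost"))))
write.table(tr_tab, "results/transitions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (tr in gl$transitions)
  cat(sprintf("%s -> %s: %d gained, %d lost\n", tr$from, tr$to,
              length(tr$gained), length(tr$lost)))
if (!is.null(gl$per_gene_counts))
  write.table(gl$per_gene_counts, "results/gene_change_counts.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)

# priming classification of the lag-planted genes; 20 bins keep ~7 cells
# per bin at this dataset size
pats <- do.call(rbind, lapply(c("g0100", "g0101"), function(g) {
  act <- pseudotime_curve(ds$accessibility[paste0(g, "_pk1"), ],
                          ds$cell_meta$pseudotime, n_bins = 20)$curve
  expr <- pseudotime_curve(ds$expression[g, ],
                           ds$cell_meta$pseudotime, n_bins = 20)$curve
  cl <- classify_priming(act, expr)
  data.frame(gene = g, pattern = cl$pattern, lag_bins = cl$lag_bins,
             unclassifiable = cl$unclassifiable)
}))
write.table(pats, "results/patterns.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(pats)
cat("pattern 1 = chromatin accessibility precedes expression;",
    "pattern 2 = concurrent\n")
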