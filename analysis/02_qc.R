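#!/usr/bin/env Rscript
# Step 2 — fragment-level quality control.
#
# Reads the dataset written by 01_simulate.R, computes per-cell usable
# fragments, promoter fraction (500-bp windows on the TSS) and FRiP, applies
# the >10,000-fragment / >10%-promoter-ratio cell filter, and reports the
# per-group medians. Writes results/qc.tsv and results/kept_cells.txt.

library(chromprime)

ds <- read_multiome_dataset("results/dataset")
proms <- promoter_windows(ds$genes, ds$genome)
qc <- compute_qc(ds$fragments, ds$peaks, proms)
kept <- filter_cells(qc)

write.table(qc, "results/qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(kept, "results/kept_cells.txt")

kq <- qc[qc$barcode %in% kept, ]
cat(sprintf("cells: %d sequenced, %d pass filter (%.1f%%)\n",
            nrow(qc), length(kept), 100 * length(kept) / nrow(qc)))
cat(sprintf("passing cells: median usable fragments %.0f, median promoter fraction %.2f%%, median FRiP %.2f%%\n",
            median(kq$usable_fragments),
            100 * median(kq$promoter_fraction), 100 * median(kq$frip)))

# the RNA-side filter, scaled to the synthetic gene panel (the TPM>1
# detected-gene cutoff is panel-size dependent)
rna_kept <- filter_rna_cells(
  ds$expression,
  setNames(ds$cell_meta$rna_mapped_reads, ds$cell_meta$barcode),
  min_genes = floor(nrow(ds$expression) / 2))
cat(sprintf("RNA filter keeps %d / %d cells\n", length(rna_kept),
            ncol(ds$expression)))
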