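#!/usr/bin/env Rscript
# Step 1 — simulate the study dataset.
#
# Generates the two-lineage (EPI vs TE), three-stage paired multiome used by
# the rest of the workflow: one dominant planted TF driving 10 EPI-side
# targets, four minor TFs, planted promoter-peak links (rho = 0.65), and a
# stage-wise gain/loss plan plus two lag-planted genes so the dynamics steps
# have signal to find. Writes the dataset as plain-text files under
# results/dataset/ and the planted truth summary to results/.

library(chromprime)

seed <- as.integer(Sys.getenv("CHROMPRIME_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cfg <- driver_study_config(seed = seed)
# add stage dynamics and priming structure on top of the driver design
cfg2 <- sim_config(
  seed = seed, n_lineages = 2, lineages = c("EPI", "TE"),
  stages = c("A", "B", "C"), cells_per_group = 25, n_genes = 120,
  peaks_per_gene = 4, n_extra_peaks = 30,
  planted_links = cfg$planted_links, planted_tfs = cfg$planted_tfs,
  gain_loss_plan = data.frame(
    stage = c("B", "B", "C"),
    peak = c("bg_pk0001", "bg_pk0002", "bg_pk0003"),
    action = c("open", "open", "close")),
  lag_plan = data.frame(gene = c("g0100", "g0101"),
                        delta = c(0.6, 0)))
attr(cfg2, "dominant_tf") <- attr(cfg, "dominant_tf")

ds <- generate_multiome(cfg2)
print(ds)
manifest <- write_multiome_dataset(ds, "results/dataset")
cat("wrote", length(manifest), "files under results/dataset/\n")

tr <- truth_report(ds)
write.table(tr$true_links, "results/planted_links.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tr$true_network, "results/planted_network.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("planted:", nrow(tr$true_links), "links,",
    nrow(tr$true_network), "TF-target edges, dominant TF",
    attr(cfg2, "dominant_tf"), "\n")
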