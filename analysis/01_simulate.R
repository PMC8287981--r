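#!/usr/bin/env Rscript
# Generate the synthetic mixed-tissue dataset that stands in for the real
# tumour/normal scRNA-seq accessions: ~5,000 cells, fibroblasts a small
# minority, tumour fibroblasts split non-paCAF/iCAF/myCAF, normal
# fibroblasts split tr-RF/tr-MSCF, with a latent tr-MSCF -> iCAF -> myCAF
# differentiation continuum. Writes a 10x-style triplet plus the per-cell
# ground truth under results/data/.

suppressPackageStartupMessages(library(cafpaths))

seed <- 1L
cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_mtx_triplet(sim$counts, "results/data")
write_truth(sim$truth, "results/data/truth.tsv")
write_config(as.list(unclass(cfg)), "results/data/sim_config.yaml")

truth <- sim$truth
message(sprintf("Simulated %d cells x %d genes (seed %d)", nrow(truth),
                nrow(sim$counts$counts), seed))
message(sprintf("  fibroblasts: %d (%.1f%%)",
                sum(truth$major_type == "fibroblast"),
                100 * mean(truth$major_type == "fibroblast")))
print(table(truth$tissue, truth$fib_subtype))
message("Wrote results/data/{matrix.mtx,features.tsv,barcodes.tsv,",
        "cell_meta.tsv,truth.tsv,sim_config.yaml}")
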