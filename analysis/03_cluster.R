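#!/usr/bin/env Rscript
# Per-sample k-means clustering of the identified fibroblasts, with the
# number of clusters chosen from the sum-of-squared-error curve (smallest
# k after which every relative SSE drop is below 10%). Writes cluster
# assignments, SSE curves and the PCA embedding.

suppressPackageStartupMessages(library(cafpaths))

fib <- read_mtx_triplet("results/fib_counts")
norm <- normalize_counts(fib)
clusters <- cluster_fibroblasts(norm, k_min = 1, k_max = 10,
                                drop_threshold = 0.10, seed = 2001L)

write.table(clusters$assignments, "results/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sse <- do.call(rbind, lapply(names(clusters$sse_curves), function(s)
  data.frame(sample_id = s, k = seq_along(clusters$sse_curves[[s]]),
             sse = as.numeric(clusters$sse_curves[[s]]))))
write.table(sse, "results/sse_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
emb <- data.frame(cell_id = rownames(clusters$embedding),
                  clusters$embedding, check.names = FALSE)
write.table(emb, "results/embedding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Chosen k per sample (SSE elbow):")
print(clusters$chosen_k)
print(table(clusters$assignments$cluster))
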