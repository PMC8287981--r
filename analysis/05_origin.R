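#!/usr/bin/env Rscript
# Origin tracing: all-pairwise Spearman correlation between tumour- and
# normal-cluster centroid profiles over highly variable genes. The
# expected pattern is exclusive correlation of paCAF (iCAF/myCAF)
# clusters with the tr-MSCF cluster and of non-paCAF clusters with tr-RF.

suppressPackageStartupMessages(library(cafpaths))

fib <- read_mtx_triplet("results/fib_counts")
norm <- normalize_counts(fib)
asg <- read.delim("results/clusters_final.tsv")
tax <- read.delim("results/taxonomy.tsv")

om <- trace_origins(norm, asg, n_hvg = 2000, delta = 0.05)

rho <- om$rho
write.table(data.frame(tumour_cluster = rownames(rho)[row(rho)],
                       normal_cluster = colnames(rho)[col(rho)],
                       rho = as.numeric(rho)),
            "results/origin_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(om$calls, "results/origin_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(round(om$rho, 3))
lab_of <- setNames(tax$label, tax$cluster)
calls <- transform(om$calls,
                   tumour_label = lab_of[tumour_cluster],
                   match_label = lab_of[best_match])
message("Origin calls (best-correlated normal cluster per tumour cluster):")
print(calls[, c("tumour_cluster", "tumour_label", "best_match",
                "match_label", "rho_best", "gap", "exclusive")],
      row.names = FALSE)
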