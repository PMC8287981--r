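#!/usr/bin/env Rscript
# Principal-curve pseudotime over the developmental path populations
# (tr-MSCF, iCAF, myCAF), rooted at tr-MSCF, with rank-sum ordering
# tests. The expected result is tr-MSCF < iCAF < myCAF in pseudotime,
# i.e. myCAFs lie significantly later than iCAFs.

suppressPackageStartupMessages(library(cafpaths))

asg <- read.delim("results/clusters_final.tsv")
tax <- read.delim("results/taxonomy.tsv")
emb_tab <- read.delim("results/embedding.tsv", check.names = FALSE)
emb <- as.matrix(emb_tab[, -1])
rownames(emb) <- emb_tab$cell_id

keep_cl <- tax$cluster[tax$label %in% c("tr-MSCF", "iCAF", "myCAF")]
cells <- asg$cell_id[asg$cluster %in% keep_cl]
lab <- setNames(tax$label[match(asg$cluster, tax$cluster)],
                asg$cell_id)[cells]

fit <- fit_principal_curve(emb[cells, ], max_iter = 50, smooth_span = 0.3,
                           tol = 1e-6)
traj <- assign_pseudotime(fit, lab, "tr-MSCF")

write.table(data.frame(cell_id = names(traj$pseudotime),
                       pseudotime = as.numeric(traj$pseudotime),
                       label = as.character(traj$labels)),
            "results/pseudotime.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(fit$s), "results/curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Median pseudotime per population:")
print(round(tapply(traj$pseudotime, traj$labels, median), 3))
tests <- list()
for (pp in list(c("iCAF", "myCAF"), c("tr-MSCF", "iCAF"),
                c("tr-MSCF", "myCAF"))) {
  ts <- test_ordering(traj, pp[1], pp[2])
  tests[[length(tests) + 1]] <-
    data.frame(pair = paste(pp, collapse = "_vs_"),
               statistic = ts$statistic, p = ts$p, direction = ts$direction)
  message(sprintf("  %s vs %s: %s (rank-sum p = %.3g)", pp[1], pp[2],
                  ts$direction, ts$p))
}
write.table(do.call(rbind, tests), "results/ordering_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read_truth("results/data/truth.tsv")
cont <- truth$cell_id[!is.na(truth$latent_pseudotime)]
shared <- intersect(names(traj$pseudotime), cont)
rho <- spearman_rho(traj$pseudotime[shared],
                    truth$latent_pseudotime[match(shared, truth$cell_id)])
message(sprintf("Spearman(inferred, planted pseudotime) on %d continuum cells: %.3f",
                length(shared), rho))
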