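# Shared fixtures. Heavy objects (full pipeline runs, the multi-seed sweep)
# are computed once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small caf_counts from a dense matrix (genes get symbols g1..gn unless named)
make_counts <- function(m, sample_id = "S1", tissue = "tumour") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  meta <- data.frame(cell_id = colnames(m),
                     sample_id = rep_len(sample_id, ncol(m)),
                     tissue = rep_len(tissue, ncol(m)),
                     stringsAsFactors = FALSE)
  new_caf_counts(m, meta)
}

# a small but complete simulated dataset (fast; ~1200 cells)
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_cells_tumour = 600L, n_cells_normal = 600L,
                    fibroblast_fraction = 0.25, n_genes = 600L,
                    seed = seed, ...)
  simulate_dataset(cfg)
}

# full default pipeline run, memoised per seed
default_run <- function(seed = 1) {
  memo(paste0("run_seed_", seed), run_all(default_config(seed = seed)))
}

# multi-seed sweep of the full pipeline collecting the quantities several
# acceptance properties need (ordering recovery, origin pattern)
pipeline_sweep <- function(seeds = 1:20) {
  memo(paste0("sweep_", min(seeds), "_", max(seeds)), {
    rows <- lapply(seeds, function(s) {
      rep <- run_all(default_config(seed = s))
      tax <- rep$taxonomy
      lab_of <- stats::setNames(tax$label, tax$cluster)
      pac_cl <- tax$cluster[tax$label %in% c("paCAF", "iCAF", "myCAF")]
      oc <- rep$origin$calls
      is_pac <- oc$tumour_cluster %in% pac_cl
      origin_ok <- length(pac_cl) > 0 &&
        all(lab_of[oc$best_match[is_pac]] == "tr-MSCF") &&
        all(lab_of[oc$best_match[!is_pac]] == "tr-RF")
      ord <- rep$ordering_tests[["iCAF_vs_myCAF"]]
      ordering_ok <- !is.null(ord) && ord$p < 0.05 &&
        ord$direction == "myCAF later"
      truth <- rep$truth
      pt <- rep$trajectory$pseudotime
      cont <- truth$cell_id[!is.na(truth$latent_pseudotime)]
      shared <- intersect(names(pt), cont)
      rho <- spearman_rho(pt[shared],
                          truth$latent_pseudotime[match(shared,
                                                        truth$cell_id)])
      data.frame(seed = s, origin_ok = origin_ok, ordering_ok = ordering_ok,
                 pt_rho = rho,
                 fibroblast_fraction = rep$fibroblast_fraction,
                 pacaf_fraction = rep$pacaf_fraction_of_cafs)
    })
    do.call(rbind, rows)
  })
}
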