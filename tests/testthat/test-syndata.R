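# Synthetic-data generator: determinism, planted structure, noise model.

test_that("identical seed gives byte-identical datasets", {
  cfg <- sim_config(n_cells_tumour = 200L, n_cells_normal = 200L,
                    n_genes = 400L, seed = 42L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(sim_config(n_cells_tumour = 200L,
                                    n_cells_normal = 200L,
                                    n_genes = 400L, seed = 43L))
  expect_false(identical(as.matrix(a$counts$counts),
                         as.matrix(c2$counts$counts)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(caf_composition = c(non_paCAF = 0.5, iCAF = 0.3,
                                              myCAF = 0.3)), "sum to 1")
  expect_error(sim_config(nf_composition = c(tr_RF = 1)), "named over")
  expect_error(sim_config(n_genes = 100L), "smaller than total marker")
  expect_error(sim_config(fibroblast_fraction = 0), "proportion")
  expect_error(sim_config(marker_fold_change = 0.5), "fold_change")
})

test_that("ground-truth invariants hold", {
  sim <- small_sim(seed = 3)
  truth <- sim$truth
  on_path <- truth$fib_subtype %in% c("tr_MSCF", "iCAF", "myCAF")
  expect_identical(!is.na(truth$latent_pseudotime), on_path)
  expect_identical(truth$fib_subtype == "none",
                   truth$major_type != "fibroblast")
  # realized fibroblast fraction within 2 binomial SD of the target
  n <- nrow(truth)
  p <- 0.25
  frac <- mean(truth$major_type == "fibroblast")
  expect_lt(abs(frac - p), 2 * sqrt(p * (1 - p) / n))
  # window placement of latent pseudotime
  expect_true(all(truth$latent_pseudotime[truth$fib_subtype == "tr_MSCF"]
                  <= 0.28))
  expect_true(all(truth$latent_pseudotime[truth$fib_subtype == "myCAF"]
                  >= 0.62))
})

test_that("marker programs are elevated in their populations", {
  sim <- small_sim(seed = 5)
  truth <- sim$truth
  m <- as.matrix(sim$counts$counts)
  gt <- sim$counts$gene_table
  mycaf_genes <- gt$gene_symbol[gt$program == "mycaf"]
  my_cells <- truth$cell_id[truth$fib_subtype == "myCAF"]
  i_cells <- truth$cell_id[truth$fib_subtype == "iCAF"]
  ratio <- mean(m[mycaf_genes, my_cells]) / mean(m[mycaf_genes, i_cells])
  expect_gte(ratio, 8 / 2)  # default fold change 8, factor fold/2
  # activation program absent from normal fibroblasts, present in paCAFs
  act_genes <- gt$gene_symbol[gt$program == "activation"]
  nf_cells <- truth$cell_id[truth$fib_subtype %in% c("tr_RF", "tr_MSCF")]
  expect_equal(sum(m[act_genes, nf_cells]), 0)
  expect_gt(mean(m[act_genes, my_cells]), 1)
})

test_that("fold change 1 removes all marker signal", {
  cfg <- sim_config(n_cells_tumour = 300L, n_cells_normal = 300L,
                    n_genes = 400L, marker_fold_change = 1,
                    marker_off_mean = 0.3, seed = 8L)
  sim <- simulate_dataset(cfg)
  gt <- sim$counts$gene_table
  m <- as.matrix(sim$counts$counts)
  marker <- gt$program != "background"
  # marker and background genes now share one distribution
  expect_lt(abs(mean(m[marker, ]) - mean(m[!marker, ])), 0.02)
})

test_that("zero dispersion gives Poisson mean-variance behaviour", {
  cfg <- sim_config(n_cells_tumour = 2000L, n_cells_normal = 0L,
                    n_genes = 250L, nb_dispersion = 0,
                    library_size_lognormal_sigma = 0, seed = 9L)
  sim <- simulate_dataset(cfg)
  gt <- sim$counts$gene_table
  bg <- which(gt$program == "background")[1:20]
  m <- as.matrix(sim$counts$counts[bg, , drop = FALSE])
  n <- ncol(m)
  for (g in seq_len(nrow(m))) {
    mu_hat <- mean(m[g, ])
    v_hat <- stats::var(m[g, ])
    # SE of the sample variance of a Poisson (var of s^2 ~ (mu + 2 mu^2)/n)
    se <- sqrt((mu_hat + 2 * mu_hat^2) / n)
    expect_lt(abs(v_hat - mu_hat), 3 * se)
  }
})

test_that("truth tables round-trip through TSV, including degenerate ones", {
  sim <- small_sim(seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back, sim$truth)
  # empty truth: header-only file
  empty <- sim$truth[0, ]
  write_truth(empty, path)
  expect_identical(length(readLines(path)), 1L)
  expect_equal(nrow(read_truth(path)), 0L)
  # three hand-built rows -> three data lines
  three <- sim$truth[1:3, ]
  write_truth(three, path)
  expect_identical(length(readLines(path)), 4L)
  expect_equal(read_truth(path)$cell_id, three$cell_id)
})

test_that("expected profiles are noise-free and monotone on the continuum", {
  cfg <- sim_config(n_cells_tumour = 300L, n_cells_normal = 300L,
                    n_genes = 400L, continuum_noise_sd = 0, seed = 4L)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth
  cont <- truth$cell_id[!is.na(truth$latent_pseudotime)]
  prof <- expected_profiles(cfg, truth, cells = cont)
  expect_identical(colnames(prof), cont)
  gt <- sim$counts$gene_table
  t_ord <- order(truth$latent_pseudotime[match(cont, truth$cell_id)])
  mycaf_mean <- colMeans(prof[gt$gene_symbol[gt$program == "mycaf"], ])
  icaf_mean <- colMeans(prof[gt$gene_symbol[gt$program == "icaf"], ])
  expect_true(all(diff(mycaf_mean[t_ord]) > 0))
  expect_true(all(diff(icaf_mean[t_ord]) < 0))
})
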