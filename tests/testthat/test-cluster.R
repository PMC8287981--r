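# PCA embedding, k-means SSE, elbow selection, per-sample clustering.

test_that("PCA of collinear data concentrates variance on PC1", {
  set.seed(1)
  t_vals <- seq(0, 1, length.out = 30)
  m <- round(100 * rbind(t_vals * 2, t_vals * 4, t_vals * 6, t_vals * 1,
                         t_vals * 3))
  norm <- structure(list(values = Matrix::Matrix(m, sparse = TRUE,
                                                 dimnames = list(
    sprintf("g%d", 1:5), sprintf("c%d", 1:30))),
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:30), sample_id = "S",
                           tissue = "tumour")), class = "caf_norm")
  emb <- embed_pca(norm, n_hvg = 5, n_pc = 3)
  ev <- attr(emb, "explained_variance")
  expect_gte(ev[1], 0.999)
})

test_that("PCA is equivariant to cell permutation up to component sign", {
  sim <- small_sim(seed = 11)
  norm <- normalize_counts(sim$counts)
  emb <- embed_pca(norm, n_hvg = 200, n_pc = 5)
  perm <- sample(ncol(norm$values))
  norm_p <- subset_norm(norm, colnames(norm$values)[perm])
  emb_p <- embed_pca(norm_p, n_hvg = 200, n_pc = 5)
  emb_p <- emb_p[rownames(emb), ]
  for (j in 1:5)
    expect_lt(min(max(abs(emb_p[, j] - emb[, j])),
                  max(abs(emb_p[, j] + emb[, j]))), 1e-6)
})

test_that("four standardized square corners give two equal eigenvalues", {
  # cells at (0,0), (0,1), (1,0), (1,1) in two genes: after
  # standardization the 2x2 covariance is the identity scaled by 4/3,
  # hence two equal eigenvalues and 50% explained variance each
  m <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), nrow = 2)
  norm <- structure(list(values = Matrix::Matrix(m, sparse = TRUE,
    dimnames = list(c("g1", "g2"), sprintf("c%d", 1:4))),
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:4), sample_id = "S",
                           tissue = "tumour")), class = "caf_norm")
  emb <- embed_pca(norm, n_hvg = 2, n_pc = 2)
  ev <- attr(emb, "explained_variance")
  expect_equal(as.numeric(ev), c(0.5, 0.5))
})

test_that("kmeans_sse reproduces hand-computed SSE values", {
  x <- matrix(c(0, 0, 10, 10), ncol = 1)
  fit2 <- kmeans_sse(x, 2, seed = 1)
  expect_equal(fit2$sse, 0)
  expect_equal(length(unique(fit2$labels)), 2L)
  fit1 <- kmeans_sse(x, 1, seed = 1)
  expect_equal(fit1$sse, 100)  # centroid 5, four squared deviations of 25
  fitn <- kmeans_sse(x, 4, seed = 1)
  expect_equal(fitn$sse, 0)
  expect_error(kmeans_sse(x, 5), "k must be")
})

test_that("kmeans_sse is reproducible under a fixed seed", {
  set.seed(99)
  x <- matrix(rnorm(200), ncol = 2)
  a <- kmeans_sse(x, 3, seed = 7)
  b <- kmeans_sse(x, 3, seed = 7)
  expect_identical(a, b)
})

test_that("select_k applies the relative-drop rule", {
  expect_equal(select_k(c("1" = 100, "2" = 10, "3" = 9, "4" = 8.5), 0.2), 2L)
  expect_equal(select_k(c("1" = 50, "2" = 50, "3" = 50), 0.2), 1L)
  geo <- setNames(100 / 2^(0:5), 1:6)
  expect_warning(k <- select_k(geo, 0.2), "no elbow")
  expect_equal(k, 6L)
  expect_error(select_k(c("1" = 10, "2" = 20), 0.2), "non-increasing")
  expect_error(select_k(c("2" = 10, "3" = 5), 0.2), "consecutive")
})

test_that("well-separated subtypes give the planted k and a perfect ARI", {
  skip_if_not_installed("mclust")
  fx <- memo("wellsep_fixture", {
    cfg <- sim_config(n_cells_tumour = 1500L, n_cells_normal = 1500L,
                      marker_fold_change = 64, continuum_noise_sd = 0,
                      nb_dispersion = 0.2, seed = 5L)
    sim <- simulate_dataset(cfg)
    truth <- sim$truth
    fibs <- truth$cell_id[truth$major_type == "fibroblast"]
    fn <- subset_norm(normalize_counts(sim$counts), fibs)
    list(clusters = cluster_fibroblasts(fn, seed = 5L), truth = truth,
         norm = fn)
  })
  cl <- fx$clusters
  # planted subtypes: 3 in tumour (non-paCAF, iCAF, myCAF), 2 in normal
  expect_equal(unname(cl$chosen_k["T1"]), 3L)
  expect_equal(unname(cl$chosen_k["N1"]), 2L)
  tr <- fx$truth[match(cl$assignments$cell_id, fx$truth$cell_id), ]
  ari <- mclust::adjustedRandIndex(cl$assignments$cluster, tr$fib_subtype)
  expect_equal(ari, 1.0)
})

test_that("recorded SSE curves are non-increasing", {
  run <- default_run(seed = 1)
  for (sse in run$clusters$sse_curves)
    expect_true(all(diff(sse) <= 1e-8 * pmax(sse[-length(sse)], 1)))
})

test_that("duplicated samples cluster identically and tiny samples warn", {
  sim <- small_sim(seed = 13)
  truth <- sim$truth
  fibs <- truth$cell_id[truth$major_type == "fibroblast" &
                          truth$tissue == "tumour"]
  fn <- subset_norm(normalize_counts(sim$counts), fibs)
  # duplicate the sample under a second id
  v2 <- cbind(fn$values, fn$values)
  colnames(v2) <- c(colnames(fn$values), paste0("dup_", colnames(fn$values)))
  meta2 <- rbind(fn$cell_meta,
                 transform(fn$cell_meta,
                           cell_id = paste0("dup_", cell_id),
                           sample_id = "T2"))
  norm2 <- structure(list(values = v2, cell_meta = meta2), class = "caf_norm")
  cl <- cluster_fibroblasts(norm2, seed = 3)
  a <- cl$assignments
  k1 <- sub("^T1\\.", "", a$cluster[a$sample_id == "T1"])
  k2 <- sub("^T2\\.", "", a$cluster[a$sample_id == "T2"])
  expect_equal(unname(cl$chosen_k["T1"]), unname(cl$chosen_k["T2"]))
  # identical partitions up to label permutation
  expect_equal(length(unique(paste(k1, k2))), length(unique(k1)))
  # a sample smaller than k_min falls back to k = 1 with a warning
  tiny_cells <- fn$cell_meta$cell_id[1:3]
  tiny <- subset_norm(fn, tiny_cells)
  tiny$cell_meta$sample_id <- "T9"
  expect_warning(cl9 <- cluster_fibroblasts(tiny, k_min = 5, seed = 1),
                 "k = 1")
  expect_equal(unname(cl9$chosen_k["T9"]), 1L)
})
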