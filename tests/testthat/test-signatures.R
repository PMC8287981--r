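# Signature scoring, taxonomy calls and the rank-sum test.

# independent loop-based oracle for score_sets
score_oracle <- function(values, asg, sets) {
  cells <- asg$cell_id
  cell_scores <- matrix(NA_real_, length(cells), length(sets),
                        dimnames = list(cells, names(sets)))
  for (s in names(sets)) {
    g <- intersect(sets[[s]], rownames(values))
    if (!length(g)) next
    for (i in seq_along(cells)) {
      tot <- 0
      for (gg in g) tot <- tot + values[gg, cells[i]]
      cell_scores[i, s] <- tot / length(g)
    }
  }
  cl <- sort(unique(asg$cluster))
  cluster_scores <- matrix(NA_real_, length(cl), length(sets),
                           dimnames = list(cl, names(sets)))
  for (cc in cl) for (s in names(sets))
    cluster_scores[cc, s] <-
      stats::median(cell_scores[asg$cluster == cc, s])
  list(cell = cell_scores, cluster = cluster_scores)
}

rand_panel_fixture <- function(seed) {
  set.seed(seed)
  n_g <- 12; n_c <- 9
  v <- matrix(round(stats::rexp(n_g * n_c), 3), n_g, n_c,
              dimnames = list(sprintf("g%d", 1:n_g), sprintf("c%d", 1:n_c)))
  norm <- structure(list(values = Matrix::Matrix(v, sparse = TRUE),
                         cell_meta = data.frame(
                           cell_id = colnames(v), sample_id = "S",
                           tissue = "tumour")), class = "caf_norm")
  sets <- list()
  for (nm in c("fibroblast_markers", "epithelial_markers", "immune_markers",
               "endothelial_markers", "activation", "caf_related",
               "bm_msc_markers", "hsc_markers"))
    sets[[nm]] <- sample(rownames(v), sample(1:4, 1))
  sets$mycaf_signature <- c("g1", "g2")
  sets$icaf_signature <- c("g3", "g4")
  panel <- new_gene_panel(sets)
  asg <- data.frame(cell_id = colnames(v),
                    cluster = sample(c("S.1", "S.2", "S.3"), n_c,
                                     replace = TRUE),
                    stringsAsFactors = FALSE)
  list(norm = norm, panel = panel, asg = asg, values = v, sets = sets)
}

test_that("score_sets equals a brute-force oracle on random fixtures", {
  for (seed in 1:20) {
    fx <- rand_panel_fixture(seed)
    got <- score_sets(fx$norm, fx$asg, fx$panel)
    want <- score_oracle(fx$values, fx$asg, fx$sets)
    expect_equal(got$cell_scores, want$cell,
                 tolerance = 1e-12, ignore_attr = FALSE)
    expect_equal(got$cluster_scores[, colnames(want$cluster)],
                 want$cluster, tolerance = 1e-12)
  }
})

test_that("cluster scores are medians and empty sets are flagged", {
  v <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  v["g1", ] <- c(0, 1, 2)  # g1-only set: cell scores 0, 1, 2
  norm <- structure(list(values = Matrix::Matrix(v, sparse = TRUE),
                         cell_meta = data.frame(cell_id = colnames(v),
                                                sample_id = "S",
                                                tissue = "tumour")),
                    class = "caf_norm")
  sets <- as.list(setNames(rep("g1", 10),
                           c("fibroblast_markers", "epithelial_markers",
                             "immune_markers", "endothelial_markers",
                             "activation", "caf_related", "bm_msc_markers",
                             "hsc_markers", "mycaf_signature",
                             "icaf_signature")))
  sets$icaf_signature <- "g2"
  sets$hsc_markers <- "absent_gene"
  panel <- new_gene_panel(sets)
  asg <- data.frame(cell_id = colnames(v), cluster = "S.1")
  expect_warning(sc <- score_sets(norm, asg, panel), "no matched genes")
  expect_equal(unname(sc$cluster_scores["S.1", "activation"]), 1)  # median
  expect_true(is.na(sc$cluster_scores["S.1", "hsc_markers"]))
  expect_equal(sc$unmatched, "hsc_markers")
  # a gene expressed nowhere scores zero everywhere
  expect_equal(unname(sc$cell_scores[, "icaf_signature"]), c(0, 0, 0))
})

test_that("paCAF calls follow the margin-over-mean rule", {
  sc <- structure(list(cluster_scores = rbind(
    "T.1" = c(activation = 2.0, caf_related = 1.5),
    "T.2" = c(activation = 0.0, caf_related = 0.1))),
    class = "signature_scores")
  out <- call_pacaf(sc, c("T.1", "T.2"), high_margin_sd = 0.5)
  # z of the high cluster is +1/sqrt(2) = 0.707 >= 0.5 on both scores
  expect_equal(out$label, c("paCAF", "non-paCAF"))
  # identical scores: nothing exceeds the mean, all non-paCAF
  sc2 <- structure(list(cluster_scores = rbind(
    "T.1" = c(activation = 1, caf_related = 1),
    "T.2" = c(activation = 1, caf_related = 1))),
    class = "signature_scores")
  expect_true(all(call_pacaf(sc2, c("T.1", "T.2"))$label == "non-paCAF"))
})

test_that("normal taxonomy requires high BM-MSC score and low HSC score", {
  sc <- structure(list(cluster_scores = rbind(
    "N.1" = c(bm_msc_markers = 1.8, hsc_markers = 0.0),
    "N.2" = c(bm_msc_markers = 0.2, hsc_markers = 0.0),
    "N.3" = c(bm_msc_markers = 0.1, hsc_markers = 0.0))),
    class = "signature_scores")
  out <- call_normal_taxonomy(sc, c("N.1", "N.2", "N.3"),
                              high_margin_sd = 0.5, low_ceiling = 0.1)
  expect_equal(out$label, c("tr-MSCF", "tr-RF", "tr-RF"))
  # high BM-MSC but HSC above the ceiling fails the exclusion
  sc$cluster_scores["N.1", "hsc_markers"] <- 0.5
  out2 <- call_normal_taxonomy(sc, c("N.1", "N.2", "N.3"),
                               high_margin_sd = 0.5, low_ceiling = 0.1)
  expect_equal(out2$label[1], "tr-RF")
})

test_that("paCAF subtyping assigns opposite programs and guards small n", {
  make_scores <- function(d_a, d_b) {
    cells <- sprintf("c%d", seq_len(length(d_a) + length(d_b)))
    cs <- matrix(0, length(cells), 2,
                 dimnames = list(cells, c("mycaf_signature",
                                          "icaf_signature")))
    cs[, "mycaf_signature"] <- pmax(c(d_a, d_b), 0)
    cs[, "icaf_signature"] <- pmax(-c(d_a, d_b), 0)
    structure(list(cell_scores = cs,
                   assignments = data.frame(
                     cell_id = cells,
                     cluster = rep(c("T.1", "T.2"),
                                   c(length(d_a), length(d_b))),
                     stringsAsFactors = FALSE)),
              class = "signature_scores")
  }
  # two large, perfectly opposed clusters
  set.seed(1)
  sc <- make_scores(stats::runif(40, 1, 2), -stats::runif(40, 1, 2))
  out <- subtype_pacaf(sc, c("T.1", "T.2"))
  expect_equal(out$label[out$cluster == "T.1"], "myCAF")
  expect_equal(out$label[out$cluster == "T.2"], "iCAF")
  expect_lt(max(out$p_value), 1e-6)
  # perfect separation at n = 2 vs 2 cannot reach significance
  sc2 <- make_scores(c(1, 2), c(-3, -4))
  out2 <- subtype_pacaf(sc2, c("T.1", "T.2"))
  expect_true(all(out2$label == "unassigned"))
  # identical clusters stay unassigned (null is true)
  sc3 <- make_scores(rep(c(1, -1), 10), rep(c(1, -1), 10))
  out3 <- subtype_pacaf(sc3, c("T.1", "T.2"))
  expect_true(all(out3$label == "unassigned"))
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  out <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1 / 3)   # 2 of the 6 arrangements are as extreme
  expect_equal(out$method, "exact")
  # identical multisets: p = 1 by symmetry
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # exact regime agrees with wilcox.test everywhere (no ties, small n)
  set.seed(42)
  for (i in 1:50) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    z <- sample(1000, m + n)   # distinct values: no ties
    x <- z[1:m]; y <- z[-(1:m)]
    got <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
  # normal approximation with ties agrees with wilcox.test's corrected one
  for (i in 1:20) {
    x <- sample(1:8, 15, replace = TRUE)
    y <- sample(1:8, 18, replace = TRUE)
    got <- rank_sum_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$method, "normal")
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("large-sample rank-sum p agrees with a permutation oracle", {
  set.seed(7)
  x <- stats::rnorm(30, 0.6); y <- stats::rnorm(35)
  got <- rank_sum_test(x, y)
  pooled <- c(x, y); m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[1:m]) - m * (m + 1) / 2
  B <- 10000
  u_perm <- replicate(B, {
    idx <- sample(length(pooled), m)
    sum(r[idx]) - m * (m + 1) / 2
  })
  p_perm <- mean(abs(u_perm - m * length(y) / 2) >=
                   abs(u_obs - m * length(y) / 2))
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B) + 2e-3
  expect_lt(abs(got$p - p_perm), mc_err + 0.25 * max(p_perm, got$p))
})

test_that("taxonomy calls are invariant to cluster relabeling and cell order", {
  fx <- rand_panel_fixture(99)
  tum_cl <- sort(unique(fx$asg$cluster))
  sc <- score_sets(fx$norm, fx$asg, fx$panel)
  out <- call_pacaf(sc, tum_cl)
  # permute cells
  perm <- sample(nrow(fx$asg))
  sc_p <- score_sets(fx$norm, fx$asg[perm, ], fx$panel)
  out_p <- call_pacaf(sc_p, tum_cl)
  expect_equal(out, out_p)
  # relabel clusters (S.k -> Z.k) and ask in the matching order
  asg_r <- fx$asg
  asg_r$cluster <- sub("^S", "Z", asg_r$cluster)
  sc_r <- score_sets(fx$norm, asg_r, fx$panel)
  out_r <- call_pacaf(sc_r, sub("^S", "Z", tum_cl))
  expect_equal(out_r$label, out$label)
})
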