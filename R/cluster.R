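# PCA embedding and per-sample k-means with SSE-based choice of k.

#' PCA embedding of cells on highly variable genes
#'
#' Standardizes the top \code{n_hvg} most variable genes (unit variance,
#' zero mean across cells) and returns the leading principal components,
#' computed from the gene-gene covariance eigendecomposition. Components
#' are ordered by decreasing explained variance; signs follow the
#' eigenvector convention and are arbitrary per component.
#'
#' @param norm a \code{caf_norm} object.
#' @param n_hvg number of highly variable genes to use.
#' @param n_pc number of components to return.
#' @return numeric matrix, cells x \code{n_pc}, rownames = cell ids, with
#'   attribute \code{"explained_variance"}.
#' @export
embed_pca <- function(norm, n_hvg = 2000L, n_pc = 20L) {
  stopifnot(inherits(norm, "caf_norm"))
  n_cells <- ncol(norm$values)
  if (n_cells < 3L) .stopf("embed_pca needs at least 3 cells")
  hvg <- .top_hvg(norm$values, n_hvg)
  X <- t(as.matrix(norm$values[hvg, , drop = FALSE]))  # cells x genes
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sdv[keep], "/")
  n_pc <- min(n_pc, ncol(X), n_cells)
  C <- crossprod(X) / (n_cells - 1)
  e <- eigen(C, symmetric = TRUE)
  emb <- X %*% e$vectors[, seq_len(n_pc), drop = FALSE]
  rownames(emb) <- colnames(norm$values)
  colnames(emb) <- sprintf("PC%d", seq_len(n_pc))
  attr(emb, "explained_variance") <-
    pmax(e$values[seq_len(n_pc)], 0) / sum(pmax(e$values, 0))
  emb
}

# brute-force SSE of an assignment
.sse_of <- function(x, labels, centroids) {
  sum((x - centroids[labels, , drop = FALSE])^2)
}

#' K-means with explicit sum of squared errors
#'
#' Runs Lloyd's algorithm from \code{n_init} random initializations (plus
#' any centroid sets supplied in \code{extra_starts}) and returns the best
#' solution by SSE, the total within-cluster sum of squared Euclidean
#' distances in the embedding. A fixed \code{seed} makes the output
#' reproducible.
#'
#' @param embedding numeric matrix, cells x dims.
#' @param k number of clusters, \code{1 <= k <= n_cells}.
#' @param seed integer RNG seed.
#' @param n_init number of random restarts.
#' @param extra_starts optional list of k x dims centroid matrices used as
#'   additional initializations.
#' @return list with \code{labels} (integer vector), \code{centroids}
#'   (k x dims) and \code{sse}.
#' @export
kmeans_sse <- function(embedding, k, seed = 1L, n_init = 10L,
                       extra_starts = NULL) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 1 || k > n) .stopf("k must be in [1, %d], got %s", n, format(k))
  if (k == 1) {
    cen <- matrix(colMeans(embedding), 1, ncol(embedding))
    return(list(labels = rep(1L, n), centroids = cen,
                sse = .sse_of(embedding, rep(1L, n), cen)))
  }
  set.seed(seed)
  best <- NULL
  run <- function(centers) {
    fit <- suppressWarnings(
      kmeans(embedding, centers = centers, iter.max = 100L,
             algorithm = "Lloyd"))
    list(labels = fit$cluster, centroids = fit$centers,
         sse = .sse_of(embedding, fit$cluster, fit$centers))
  }
  for (i in seq_len(n_init)) {
    centers <- embedding[sample.int(n, k), , drop = FALSE]
    if (anyDuplicated(centers)) next
    cand <- tryCatch(run(centers), error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse))
      best <- cand
  }
  for (st in extra_starts) {
    if (nrow(st) != k) next
    cand <- tryCatch(run(st), error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse))
      best <- cand
  }
  if (is.null(best)) {
    # fewer distinct points than k: group by point identity, cap at k
    key <- apply(embedding, 1, paste, collapse = "\r")
    lab <- pmin(as.integer(factor(key, levels = unique(key))), k)
    cen <- do.call(rbind, lapply(seq_len(max(lab)), function(j)
      colMeans(embedding[lab == j, , drop = FALSE])))
    if (nrow(cen) < k)
      cen <- rbind(cen, cen[rep(1L, k - nrow(cen)), , drop = FALSE])
    best <- list(labels = lab, centroids = cen,
                 sse = .sse_of(embedding, lab, cen))
  }
  best
}

#' Choose k from an SSE curve by the relative-drop rule
#'
#' The chosen k is the smallest k such that every subsequent relative SSE
#' drop \code{(SSE(k) - SSE(k+1)) / SSE(k)} on the recorded curve is below
#' \code{drop_threshold}; if no k qualifies, the largest recorded k is
#' returned with a warning. Zero-SSE steps count as zero drop.
#'
#' @param sse_curve named numeric vector, names = consecutive k starting at
#'   1, values = SSE; must be non-increasing.
#' @param drop_threshold relative-drop threshold in (0,1).
#' @return chosen k (integer).
#' @export
select_k <- function(sse_curve, drop_threshold = 0.10) {
  .check_prop(drop_threshold, "drop_threshold")
  ks <- as.integer(names(sse_curve))
  if (is.null(names(sse_curve)) || anyNA(ks) ||
      !identical(ks, seq_len(length(ks))))
    .stopf("sse_curve must be named with consecutive k starting at 1")
  sse <- as.numeric(sse_curve)
  if (any(diff(sse) > 1e-8 * pmax(sse[-length(sse)], 1)))
    .stopf("SSE curve is not non-increasing; upstream clustering bug")
  if (length(sse) == 1L) return(1L)
  drops <- ifelse(sse[-length(sse)] > 0,
                  (sse[-length(sse)] - sse[-1]) / sse[-length(sse)], 0)
  ok <- rev(cumprod(rev(drops < drop_threshold))) > 0  # all subsequent small
  if (any(ok)) return(min(which(ok)))
  .warnf("no elbow found below drop threshold %.3g; returning k_max = %d",
         drop_threshold, max(ks))
  max(ks)
}

#' Per-sample k-means clustering of fibroblasts with SSE-chosen k
#'
#' Embeds all supplied cells together by PCA, then clusters each sample
#' independently over \code{k = k_min..k_max}, recording the SSE curve and
#' choosing k by [select_k()]. The best solution at k is also used (with
#' one centroid duplicated at the farthest member point of its
#' worst-fitting cluster) as a candidate initialization at k+1, which
#' guarantees a non-increasing SSE curve.
#'
#' @param norm a \code{caf_norm} object restricted to the cells to cluster
#'   (typically the fibroblast calls).
#' @param k_min,k_max k range (curve always recorded from k = 1).
#' @param drop_threshold relative-drop threshold for [select_k()].
#' @param n_hvg,n_pc PCA parameters (see [embed_pca()]).
#' @param seed integer seed; per-sample seeds are derived from it.
#' @param n_init random restarts per k.
#' @return object of class \code{caf_clusters}: data frame
#'   \code{assignments} (cell_id, sample_id, tissue, cluster: sample-scoped
#'   id "SAMPLE.k"), list \code{sse_curves}, named integer \code{chosen_k},
#'   \code{centroids} (per-cluster median normalized expression), and the
#'   \code{embedding}.
#' @export
cluster_fibroblasts <- function(norm, k_min = 1L, k_max = 10L,
                                drop_threshold = 0.10, n_hvg = 2000L,
                                n_pc = 20L, seed = 1L, n_init = 10L) {
  stopifnot(inherits(norm, "caf_norm"), k_min >= 1L, k_max >= k_min)
  emb <- embed_pca(norm, n_hvg = n_hvg, n_pc = n_pc)
  meta <- norm$cell_meta
  samples <- unique(meta$sample_id)
  assignments <- NULL
  sse_curves <- list()
  chosen <- integer(0)
  for (si in seq_along(samples)) {
    s <- samples[si]
    cells <- meta$cell_id[meta$sample_id == s]
    e_s <- emb[cells, , drop = FALSE]
    k_hi <- min(k_max, nrow(e_s))
    if (nrow(e_s) < k_min) {
      .warnf("sample '%s' has %d cells (< k_min = %d); using k = 1",
             s, nrow(e_s), k_min)
      k_hi <- 1L
    }
    fits <- vector("list", k_hi)
    for (k in seq_len(k_hi)) {
      extra <- if (k > 1 && !is.null(fits[[k - 1]]))
        list(.split_worst(e_s, fits[[k - 1]])) else NULL
      fits[[k]] <- kmeans_sse(e_s, k, seed = seed + 131L * si + k,
                              n_init = n_init, extra_starts = extra)
    }
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    sse <- cummin(sse)  # guard against restart noise at the 1e-10 level
    names(sse) <- seq_len(k_hi)
    k_star <- max(select_k(sse, drop_threshold), min(k_min, k_hi))
    lab <- fits[[k_star]]$labels
    assignments <- rbind(assignments, data.frame(
      cell_id = cells, sample_id = s,
      tissue = meta$tissue[match(cells, meta$cell_id)],
      cluster = sprintf("%s.%d", s, lab), stringsAsFactors = FALSE))
    sse_curves[[s]] <- sse
    chosen[s] <- k_star
  }
  assignments <- assignments[match(meta$cell_id, assignments$cell_id), ]
  rownames(assignments) <- NULL
  centroids <- cluster_centroids(norm, assignments)
  structure(list(assignments = assignments, sse_curves = sse_curves,
                 chosen_k = chosen, centroids = centroids, embedding = emb),
            class = "caf_clusters")
}

# candidate initialization for k+1: previous centroids plus the member
# point farthest from its centroid in the cluster with the largest
# within-cluster SSE
.split_worst <- function(x, fit) {
  d2 <- rowSums((x - fit$centroids[fit$labels, , drop = FALSE])^2)
  wss <- tapply(d2, fit$labels, sum)
  worst <- as.integer(names(wss)[which.max(wss)])
  idx <- which(fit$labels == worst)
  far <- idx[which.max(d2[idx])]
  unname(rbind(fit$centroids, x[far, ]))
}

#' Per-cluster centroid profiles
#'
#' The centroid of a cluster is the per-gene median (or mean) of its
#' members' normalized expression.
#'
#' @param norm a \code{caf_norm} object.
#' @param assignments data frame with \code{cell_id} and \code{cluster}.
#' @param use_mean use the mean instead of the median.
#' @return matrix genes x clusters.
#' @export
cluster_centroids <- function(norm, assignments, use_mean = FALSE) {
  stopifnot(inherits(norm, "caf_norm"))
  cl <- sort(unique(assignments$cluster))
  out <- matrix(NA_real_, nrow(norm$values), length(cl),
                dimnames = list(rownames(norm$values), cl))
  for (cc in cl) {
    cells <- assignments$cell_id[assignments$cluster == cc]
    sub <- as.matrix(norm$values[, cells, drop = FALSE])
    out[, cc] <- if (use_mean) rowMeans(sub) else
      apply(sub, 1, stats::median)
  }
  out
}

#' @export
print.caf_clusters <- function(x, ...) {
  cat(sprintf("caf_clusters: %d cells, %d samples, chosen k: %s\n",
              nrow(x$assignments), length(x$chosen_k),
              paste(sprintf("%s=%d", names(x$chosen_k), x$chosen_k),
                    collapse = ", ")))
  invisible(x)
}
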