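# Origin tracing: all-pairwise Spearman correlation between tumour-cluster
# and normal-cluster centroid profiles over shared highly variable genes.
# A tumour cluster's putative origin is its best-correlated normal
# cluster; the claim is "exclusive" when the best correlation beats the
# runner-up by at least a margin delta.

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, computed explicitly. Constant input is
#' flagged with a warning and returns NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rank correlation in [-1, 1], or NA for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("spearman_rho needs two vectors of equal length >= 3")
  if (anyNA(x) || anyNA(y)) .stopf("NA values in spearman_rho input")
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    .warnf("constant vector in spearman_rho; correlation undefined")
    return(NA_real_)
  }
  sum(dx * dy) / den
}

#' Trace tumour-cluster origins by centroid correlation
#'
#' Computes cluster centroids (per-gene median normalized expression over
#' member cells), restricts to the top \code{n_hvg} variable genes (gene
#' variance pooled over all supplied cells), and fills the tumour x
#' normal Spearman correlation matrix. Clusters from "bm" tissue, if
#' present, enter as additional reference columns. Each tumour cluster
#' gets a best match, an exclusivity gap (best minus second-best rho) and
#' an exclusivity flag (gap >= delta); with a single reference cluster the
#' gap and flag are undefined (NA).
#'
#' @param norm a \code{caf_norm} object covering the clustered cells.
#' @param clusters a \code{caf_clusters} object or assignment data frame
#'   (cell_id, tissue, cluster).
#' @param n_hvg number of highly variable genes to correlate over.
#' @param delta exclusivity margin on rho.
#' @param use_mean centroid by mean instead of median.
#' @return object of class \code{origin_map}: \code{rho} matrix (tumour
#'   clusters x reference clusters), \code{calls} data frame
#'   (tumour_cluster, best_match, rho_best, gap, exclusive).
#' @export
trace_origins <- function(norm, clusters, n_hvg = 2000L, delta = 0.05,
                          use_mean = FALSE) {
  stopifnot(inherits(norm, "caf_norm"))
  asg <- if (inherits(clusters, "caf_clusters")) clusters$assignments else
    clusters
  stopifnot(all(c("cell_id", "tissue", "cluster") %in% names(asg)))
  tum <- sort(unique(asg$cluster[asg$tissue == "tumour"]))
  ref <- sort(unique(asg$cluster[asg$tissue %in% c("normal", "bm")]))
  if (!length(tum) || !length(ref))
    .stopf("need at least one tumour and one normal (or bm) cluster")
  sub <- subset_norm(norm, asg$cell_id)
  hvg <- rownames(sub$values)[.top_hvg(sub$values, n_hvg)]
  cen <- cluster_centroids(sub, asg, use_mean = use_mean)[hvg, , drop = FALSE]
  rho <- matrix(NA_real_, length(tum), length(ref),
                dimnames = list(tum, ref))
  for (a in tum) for (b in ref)
    rho[a, b] <- suppressWarnings(spearman_rho(cen[, a], cen[, b]))
  calls <- do.call(rbind, lapply(tum, function(a) {
    rr <- rho[a, ]
    best <- which.max(rr)
    gap <- if (length(rr) > 1)
      rr[best] - max(rr[-best]) else NA_real_
    data.frame(tumour_cluster = a, best_match = colnames(rho)[best],
               rho_best = as.numeric(rr[best]), gap = as.numeric(gap),
               exclusive = if (is.na(gap)) NA else gap >= delta,
               stringsAsFactors = FALSE)
  }))
  structure(list(rho = rho, calls = calls, delta = delta, n_hvg = n_hvg),
            class = "origin_map")
}

#' @export
print.origin_map <- function(x, ...) {
  cat(sprintf("origin_map: %d tumour x %d reference clusters (delta = %g)\n",
              nrow(x$rho), ncol(x$rho), x$delta))
  print(x$calls, row.names = FALSE)
  invisible(x)
}
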