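# Principal-curve pseudotime.
#
# A principal curve is a smooth one-dimensional curve minimizing squared
# orthogonal distance to the points, fitted by alternating (i) projection
# of every point to its nearest position on the current curve and (ii)
# re-estimation of each embedding coordinate by a scatterplot smoother
# against the arclength parameter, reparameterizing by arclength after
# each pass. Pseudotime is the normalized arclength of a cell's
# projection, oriented so the designated root population sits at 0.

# project points (n x d) onto the polyline through `curve` (K x d);
# returns arclength position and squared distance per point
.project_polyline <- function(points, curve) {
  K <- nrow(curve)
  if (K == 1L) {
    d2 <- rowSums(sweep(points, 2, curve[1, ])^2)
    return(list(lambda = rep(0, nrow(points)), dist2 = d2))
  }
  seg_start <- curve[-K, , drop = FALSE]
  seg_vec <- curve[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  arc0 <- c(0, cumsum(seg_len))[seq_len(K - 1)]
  best_d2 <- rep(Inf, nrow(points))
  best_lam <- rep(0, nrow(points))
  for (j in seq_len(K - 1)) {
    if (seg_len2[j] == 0) next
    w <- sweep(points, 2, seg_start[j, ])
    t <- pmin(1, pmax(0, (w %*% seg_vec[j, ])[, 1] / seg_len2[j]))
    proj <- outer(t, seg_vec[j, ]) + rep(seg_start[j, ], each = nrow(points))
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lam[upd] <- arc0[j] + t[upd] * seg_len[j]
  }
  list(lambda = best_lam, dist2 = best_d2)
}

# evaluate a lowess smoother of y vs x at positions x_out
.smooth_coord <- function(x, y, x_out, span) {
  fit <- stats::lowess(x, y, f = span, iter = 0)
  stats::approx(fit$x, fit$y, xout = x_out, rule = 2, ties = mean)$y
}

#' Fit a principal curve to an embedding
#'
#' Starts from the projection onto the first principal component of the
#' embedding and iterates projection / per-coordinate lowess smoothing /
#' arclength reparameterization until the mean squared projection distance
#' changes by less than \code{tol} or \code{max_iter} is reached. The
#' algorithm is deterministic; \code{seed} is accepted for interface
#' symmetry with the stochastic stages.
#'
#' @param embedding numeric matrix, cells x dims (>= 10 cells, >= 2 dims).
#' @param max_iter maximum smoothing iterations.
#' @param smooth_span lowess span as a fraction of points.
#' @param tol convergence tolerance on the mean squared projection
#'   distance.
#' @param seed unused (deterministic fit); kept for a uniform interface.
#' @param n_knots number of curve points kept (quantiles of arclength).
#' @return object of class \code{principal_curve}: \code{s} (ordered curve
#'   points), \code{lambda} (per-cell arclength, named by rownames),
#'   \code{dist2} (mean squared projection distance), \code{n_iter},
#'   \code{converged}.
#' @export
fit_principal_curve <- function(embedding, max_iter = 50L,
                                smooth_span = 0.3, tol = 1e-6, seed = 1L,
                                n_knots = 100L) {
  X <- as.matrix(embedding)
  if (nrow(X) < 10L) .stopf("principal curve needs >= 10 cells")
  if (ncol(X) < 2L) .stopf("principal curve needs >= 2 dimensions")
  if (all(apply(X, 2, stats::sd) == 0))
    .stopf("degenerate embedding: all points identical")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  v1 <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  lambda <- Xc %*% v1
  lambda <- lambda[, 1] - min(lambda)
  # linear extrapolation of the end segments (by the data diameter) so
  # points beyond the smoothed curve's ends project to distinct positions
  # instead of clamping to the endpoints
  diam <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  extend_ends <- function(curve) {
    K <- nrow(curve)
    if (K < 2L) return(curve)
    d1 <- curve[1, ] - curve[2, ]
    dK <- curve[K, ] - curve[K - 1, ]
    l1 <- sqrt(sum(d1^2)); lK <- sqrt(sum(dK^2))
    if (l1 > 0) curve <- rbind(curve[1, ] + d1 / l1 * diam, curve)
    if (lK > 0) curve <- rbind(curve, curve[nrow(curve), ] + dK / lK * diam)
    curve
  }
  mse_prev <- Inf
  n_iter <- 0L
  converged <- FALSE
  curve <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # knots at arclength quantiles; smooth each coordinate vs lambda
    qs <- unique(quantile(lambda, probs = seq(0, 1, length.out = n_knots),
                          names = FALSE, type = 7))
    curve <- vapply(seq_len(ncol(X)),
                    function(j) .smooth_coord(lambda, X[, j], qs,
                                              smooth_span),
                    numeric(length(qs)))
    if (is.null(dim(curve))) curve <- matrix(curve, nrow = length(qs))
    pr <- .project_polyline(X, extend_ends(curve))
    lambda <- pr$lambda
    mse <- mean(pr$dist2)
    if (abs(mse_prev - mse) < tol) { converged <- TRUE; break }
    mse_prev <- mse
  }
  names(lambda) <- rownames(X)
  structure(list(s = curve, lambda = lambda, dist2 = mean(pr$dist2),
                 n_iter = n_iter, converged = converged),
            class = "principal_curve")
}

#' Assign pseudotime along a fitted principal curve
#'
#' Pseudotime is the arclength of each cell's projection normalized to
#' [0, 1], oriented so that the root population's median pseudotime lies
#' at the low end.
#'
#' @param curve_fit a \code{principal_curve} from
#'   [fit_principal_curve()].
#' @param labels named character vector (or data frame with cell_id,
#'   label) giving each included cell's population label.
#' @param root_population label of the root population (must be present).
#' @return object of class \code{caf_trajectory}: \code{pseudotime} (named
#'   numeric in [0,1]), \code{labels}, \code{root_population},
#'   \code{curve}.
#' @export
assign_pseudotime <- function(curve_fit, labels, root_population) {
  stopifnot(inherits(curve_fit, "principal_curve"))
  if (is.data.frame(labels))
    labels <- setNames(labels$label, labels$cell_id)
  lam <- curve_fit$lambda
  labels <- labels[names(lam)]
  if (!any(labels == root_population, na.rm = TRUE))
    .stopf("root population '%s' absent from the trajectory cells",
           root_population)
  rng <- range(lam)
  pt <- if (diff(rng) == 0) rep(0, length(lam)) else
    (lam - rng[1]) / diff(rng)
  is_root <- !is.na(labels) & labels == root_population
  if (any(!is_root) &&
      stats::median(pt[is_root]) > stats::median(pt[!is_root]))
    pt <- 1 - pt
  names(pt) <- names(lam)
  structure(list(pseudotime = pt, labels = labels,
                 root_population = root_population, curve = curve_fit),
            class = "caf_trajectory")
}

#' Test pseudotime ordering between two populations
#'
#' Wilcoxon rank-sum test on the pseudotime values of two labeled
#' populations; \code{direction} names the population with the larger
#' median pseudotime ("tie" when medians are equal).
#'
#' @param result a \code{caf_trajectory}.
#' @param label_a,label_b population labels (>= 3 cells each).
#' @return list: \code{statistic}, \code{p}, \code{direction},
#'   \code{median_a}, \code{median_b}.
#' @export
test_ordering <- function(result, label_a, label_b) {
  stopifnot(inherits(result, "caf_trajectory"))
  pa <- result$pseudotime[!is.na(result$labels) & result$labels == label_a]
  pb <- result$pseudotime[!is.na(result$labels) & result$labels == label_b]
  if (length(pa) < 3 || length(pb) < 3)
    .stopf("both populations need >= 3 cells with pseudotime (have %d, %d)",
           length(pa), length(pb))
  ts <- rank_sum_test(pa, pb, alternative = "two.sided")
  ma <- stats::median(pa); mb <- stats::median(pb)
  direction <- if (ma > mb) paste(label_a, "later") else
    if (mb > ma) paste(label_b, "later") else "tie"
  list(statistic = ts$statistic, p = ts$p, direction = direction,
       median_a = ma, median_b = mb)
}

#' Centroid-shift alignment of a BM-MSC batch
#'
#' Crude batch alignment before a joint embedding: shifts each batch so
#' that its mean expression over a set of shared background genes matches
#' the overall mean. Intended for adding a bone-marrow MSC sample to the
#' tissue fibroblasts; it removes a global offset, nothing subtler.
#'
#' @param norm a \code{caf_norm} object.
#' @param batch named character/factor vector over cells.
#' @param background_genes genes used to estimate the per-batch offset
#'   (default: all genes).
#' @return a \code{caf_norm} with shifted values (dense-backed).
#' @export
align_batches <- function(norm, batch, background_genes = NULL) {
  stopifnot(inherits(norm, "caf_norm"))
  batch <- batch[colnames(norm$values)]
  v <- as.matrix(norm$values)
  bg <- if (is.null(background_genes)) rownames(v) else
    intersect(background_genes, rownames(v))
  overall <- mean(v[bg, ])
  for (b in unique(batch)) {
    idx <- which(batch == b)
    v[, idx] <- v[, idx] + (overall - mean(v[bg, idx]))
  }
  v[v < 0] <- 0
  structure(list(values = as(v, "CsparseMatrix"),
                 cell_meta = norm$cell_meta, gene_table = norm$gene_table),
            class = "caf_norm")
}
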