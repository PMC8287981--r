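# Gene-set signature scoring and the fibroblast taxonomy calls:
# paCAF vs non-paCAF on tumour clusters (PRRX1 activation + CAF-related
# genes), tr-MSCF vs tr-RF on normal clusters (BM-MSC markers with
# HSC-marker exclusion), and myCAF vs iCAF subtyping of paCAF clusters
# backed by a Wilcoxon rank-sum test.

#' Score marker gene sets per cell and per cluster
#'
#' The per-cell score of a set is the mean normalized expression over its
#' matched genes; the per-cluster score is the median of its member cells'
#' scores (mean-of-means available via \code{use_mean}). Sets with no
#' matched genes get NA scores and are flagged.
#'
#' @param norm a \code{caf_norm} object.
#' @param clusters a \code{caf_clusters} object, or a data frame with
#'   \code{cell_id} and \code{cluster}.
#' @param panel a \code{gene_panel}.
#' @param use_mean summarize clusters by the mean instead of the median.
#' @return object of class \code{signature_scores}: \code{cell_scores}
#'   (cells x sets), \code{cluster_scores} (clusters x sets),
#'   \code{unmatched} (set names with zero matched genes), and the
#'   assignment table.
#' @export
score_sets <- function(norm, clusters, panel, use_mean = FALSE) {
  stopifnot(inherits(norm, "caf_norm"), inherits(panel, "gene_panel"))
  asg <- if (inherits(clusters, "caf_clusters")) clusters$assignments else
    clusters
  stopifnot(all(c("cell_id", "cluster") %in% names(asg)))
  asg <- asg[asg$cell_id %in% colnames(norm$values), , drop = FALSE]
  sets <- .panel_set_names
  gene_names <- rownames(norm$values)
  cells <- asg$cell_id
  vals <- norm$values[, cells, drop = FALSE]
  cell_scores <- matrix(NA_real_, length(cells), length(sets),
                        dimnames = list(cells, sets))
  unmatched <- character(0)
  for (s in sets) {
    g <- .match_set(panel[[s]], gene_names, s, quiet = TRUE)
    if (!length(g)) { unmatched <- c(unmatched, s); next }
    cell_scores[, s] <- Matrix::colMeans(vals[g, , drop = FALSE])
  }
  if (length(unmatched))
    .warnf("panel set(s) with no matched genes: %s",
           paste(unmatched, collapse = ", "))
  cl <- sort(unique(asg$cluster))
  summ <- if (use_mean) mean else stats::median
  cluster_scores <- do.call(rbind, lapply(cl, function(cc) {
    apply(cell_scores[asg$cluster == cc, , drop = FALSE], 2, summ)
  }))
  rownames(cluster_scores) <- cl
  structure(list(cell_scores = cell_scores,
                 cluster_scores = cluster_scores,
                 unmatched = unmatched, assignments = asg),
            class = "signature_scores")
}

# margin-over-mean rule: which entries of score vector exceed mean + m*sd;
# degenerate SD (all equal) means nothing is "high"
.high_by_margin <- function(x, margin_sd) {
  sdv <- stats::sd(x)
  if (is.na(sdv) || sdv == 0) return(rep(FALSE, length(x)))
  (x - mean(x)) / sdv >= margin_sd
}

#' Call perpetually activated CAF (paCAF) clusters
#'
#' A tumour cluster is paCAF iff both its PRRX1 activation score and its
#' CAF-related gene score exceed the across-tumour-cluster mean by at least
#' \code{high_margin_sd} standard deviations; otherwise non-paCAF. With a
#' single tumour cluster the margin rule is undefined and an absolute
#' threshold (\code{abs_threshold} on both scores) is used instead.
#'
#' @param scores a \code{signature_scores} object.
#' @param tumour_clusters character vector of tumour cluster ids.
#' @param high_margin_sd margin in SD units (default from the panel
#'   convention, 0.5).
#' @param abs_threshold absolute fallback threshold for the
#'   single-cluster case.
#' @return data frame: cluster, label ("paCAF"/"non-paCAF"), activation and
#'   caf_related scores and their z-values.
#' @export
call_pacaf <- function(scores, tumour_clusters, high_margin_sd = 0.5,
                       abs_threshold = 0.5) {
  stopifnot(inherits(scores, "signature_scores"))
  cs <- scores$cluster_scores
  missing <- setdiff(tumour_clusters, rownames(cs))
  if (length(missing)) .stopf("unknown tumour clusters: %s",
                              paste(missing, collapse = ", "))
  act <- cs[tumour_clusters, "activation"]
  caf <- cs[tumour_clusters, "caf_related"]
  if (length(tumour_clusters) >= 2) {
    high <- .high_by_margin(act, high_margin_sd) &
      .high_by_margin(caf, high_margin_sd)
  } else {
    high <- act > abs_threshold & caf > abs_threshold
  }
  z <- function(x) if (length(x) > 1 && stats::sd(x) > 0)
    (x - mean(x)) / stats::sd(x) else rep(NA_real_, length(x))
  data.frame(cluster = tumour_clusters,
             label = ifelse(high, "paCAF", "non-paCAF"),
             activation_score = as.numeric(act),
             caf_related_score = as.numeric(caf),
             activation_z = z(act), caf_related_z = z(caf),
             stringsAsFactors = FALSE)
}

#' Call the normal-fibroblast taxonomy (tr-MSCF vs tr-RF)
#'
#' A normal cluster is tr-MSCF iff its BM-MSC marker score exceeds the
#' across-normal-cluster mean by \code{high_margin_sd} SDs and its HSC
#' marker score is at most \code{low_ceiling}; all other normal clusters
#' are tr-RF.
#'
#' @param scores a \code{signature_scores} object.
#' @param normal_clusters character vector of normal cluster ids (>= 1).
#' @param high_margin_sd,low_ceiling thresholds.
#' @return data frame: cluster, label ("tr-MSCF"/"tr-RF"), bm_msc and hsc
#'   scores.
#' @export
call_normal_taxonomy <- function(scores, normal_clusters,
                                 high_margin_sd = 0.5, low_ceiling = 0.1) {
  stopifnot(inherits(scores, "signature_scores"),
            length(normal_clusters) >= 1)
  cs <- scores$cluster_scores
  missing <- setdiff(normal_clusters, rownames(cs))
  if (length(missing)) .stopf("unknown normal clusters: %s",
                              paste(missing, collapse = ", "))
  bm <- cs[normal_clusters, "bm_msc_markers"]
  hsc <- cs[normal_clusters, "hsc_markers"]
  hsc[is.na(hsc)] <- 0  # no HSC markers in matrix: exclusion vacuous
  high <- .high_by_margin(bm, high_margin_sd) & hsc <= low_ceiling
  data.frame(cluster = normal_clusters,
             label = ifelse(high, "tr-MSCF", "tr-RF"),
             bm_msc_score = as.numeric(bm), hsc_score = as.numeric(hsc),
             stringsAsFactors = FALSE)
}

#' Subtype paCAF clusters into myCAF vs iCAF
#'
#' Each paCAF cluster is compared with the remaining paCAF cells on the
#' per-cell difference (myCAF-signature score minus iCAF-signature score)
#' with a two-sided Wilcoxon rank-sum test. A cluster is labeled myCAF if
#' its cluster-level myCAF score exceeds its iCAF score and the test is
#' significant at \code{alpha}; symmetrically for iCAF; otherwise
#' "unassigned". Clusters with fewer than 3 cells cannot be tested. With a
#' single paCAF cluster, set \code{resubcluster = TRUE} to split it first
#' by k = 2 k-means on the embedding (suffixes ".a"/".b").
#'
#' @param scores a \code{signature_scores} object.
#' @param pacaf_clusters character vector of paCAF cluster ids.
#' @param embedding cells x dims matrix (needed for resubclustering).
#' @param resubcluster split a lone paCAF cluster by k-means.
#' @param alpha two-sided significance level.
#' @param seed seed for the resubclustering k-means.
#' @return data frame: cluster, label ("myCAF"/"iCAF"/"unassigned"),
#'   mycaf/icaf cluster scores, rank-sum statistic and p value, plus the
#'   (possibly resubclustered) assignment table as attribute
#'   \code{"assignments"}.
#' @export
subtype_pacaf <- function(scores, pacaf_clusters, embedding = NULL,
                          resubcluster = FALSE, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(scores, "signature_scores"))
  asg <- scores$assignments
  asg <- asg[asg$cluster %in% pacaf_clusters, , drop = FALSE]
  if (!nrow(asg)) .stopf("no cells in the supplied paCAF clusters")
  if (length(pacaf_clusters) < 2) {
    if (!resubcluster)
      .stopf("need >= 2 paCAF clusters, or resubcluster = TRUE")
    if (is.null(embedding)) .stopf("resubclustering requires an embedding")
    e <- embedding[asg$cell_id, , drop = FALSE]
    km <- kmeans_sse(e, 2L, seed = seed)
    asg$cluster <- paste0(asg$cluster, c(".a", ".b")[km$labels])
    pacaf_clusters <- sort(unique(asg$cluster))
  }
  d <- scores$cell_scores[asg$cell_id, "mycaf_signature"] -
    scores$cell_scores[asg$cell_id, "icaf_signature"]
  cl_my <- tapply(scores$cell_scores[asg$cell_id, "mycaf_signature"],
                  asg$cluster, stats::median)
  cl_i <- tapply(scores$cell_scores[asg$cell_id, "icaf_signature"],
                 asg$cluster, stats::median)
  out <- lapply(pacaf_clusters, function(cc) {
    inside <- asg$cluster == cc
    if (sum(inside) < 3 || sum(!inside) < 1) {
      return(data.frame(cluster = cc, label = "unassigned",
                        mycaf_score = cl_my[[cc]], icaf_score = cl_i[[cc]],
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ts <- rank_sum_test(d[inside], d[!inside])
    lab <- if (ts$p >= alpha) "unassigned" else
      if (cl_my[[cc]] > cl_i[[cc]]) "myCAF" else
        if (cl_i[[cc]] > cl_my[[cc]]) "iCAF" else "unassigned"
    data.frame(cluster = cc, label = lab, mycaf_score = cl_my[[cc]],
               icaf_score = cl_i[[cc]], statistic = ts$statistic,
               p_value = ts$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "assignments") <- asg
  res
}

#' Wilcoxon / Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic for \code{x} (number of pairs
#' where x beats y, ties counting one half) using midranks. The null
#' distribution is enumerated exactly when \code{length(x) + length(y) <=
#' 12} and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction is used. The exact two-sided p is
#' the null probability of a U at least as far from its mean mn/2 as
#' observed.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative "two.sided", "greater" (x tends larger) or "less".
#' @return list with \code{statistic} (U), \code{p}, and \code{method}
#'   ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) .stopf("empty input to rank_sum_test")
  if (anyNA(c(x, y))) .stopf("NA values in rank_sum_test input")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (N <= 12 && !has_ties) {
    combs <- combn(N, m)
    u_null <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- switch(alternative,
                two.sided = mean(abs(u_null - m * n / 2) >=
                                   abs(u - m * n / 2) - 1e-9),
                greater = mean(u_null >= u - 1e-9),
                less = mean(u_null <= u + 1e-9))
    return(list(statistic = u, p = p, method = "exact"))
  }
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)  # all values identical
    return(list(statistic = u, p = 1, method = "normal"))
  sigma <- sqrt(sigma2)
  mu <- m * n / 2
  p <- switch(alternative,
              two.sided = {
                z <- (abs(u - mu) - 0.5) / sigma
                min(1, 2 * pnorm(-max(z, 0)))
              },
              greater = pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
              less = pnorm((u - mu + 0.5) / sigma))
  list(statistic = u, p = min(1, p), method = "normal")
}
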