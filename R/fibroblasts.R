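# Two-step fibroblast identification.
#
# Step 1 works at cluster level: coarse k-means over a PCA embedding of all
# cells, then a cluster is a fibroblast candidate iff its mean
# pan-fibroblast marker score exceeds the across-cluster mean by a margin
# in standard deviations. Step 2 works at cell level: within candidate
# clusters, any cell expressing an epithelial / immune / endothelial
# lineage marker above a ceiling is excluded. The screen is deliberately
# strict: it trades recall of atypical fibroblasts for purity of the set
# that all downstream stages operate on.

#' Two-step strict fibroblast identification
#'
#' @param norm a \code{caf_norm} object covering all cells.
#' @param panel a \code{gene_panel} with \code{fibroblast_markers} and the
#'   three lineage exclusion sets.
#' @param coarse_k number of coarse k-means clusters (>= 2).
#' @param step1_margin margin over the across-cluster mean fibroblast
#'   score, in SD units, for a cluster to be a candidate.
#' @param step2_max_norm_expr per-cell ceiling on normalized expression of
#'   any exclusion-set marker.
#' @param n_hvg,n_pc PCA parameters for the coarse embedding.
#' @param seed,n_init k-means reproducibility controls.
#' @return object of class \code{fibroblast_calls}: data frame
#'   \code{calls} (cell_id, call in {fibroblast, excluded_lineage, other},
#'   offending_marker), \code{cluster_evidence} (per-cluster mean
#'   fibroblast score and candidate flag), and the coarse cluster labels.
#' @export
identify_fibroblasts <- function(norm, panel, coarse_k = 10L,
                                 step1_margin = 1.0,
                                 step2_max_norm_expr = 0.25,
                                 n_hvg = 2000L, n_pc = 20L, seed = 1L,
                                 n_init = 5L) {
  stopifnot(inherits(norm, "caf_norm"), inherits(panel, "gene_panel"))
  if (coarse_k < 2L) .stopf("coarse_k must be >= 2")
  gene_names <- rownames(norm$values)
  fib_genes <- .match_set(panel$fibroblast_markers, gene_names,
                          "fibroblast_markers")
  if (!length(fib_genes)) .stopf("no fibroblast markers found in matrix")
  excl_sets <- list(epithelial = panel$epithelial_markers,
                    immune = panel$immune_markers,
                    endothelial = panel$endothelial_markers)
  excl_sets <- lapply(names(excl_sets), function(nm)
    .match_set(excl_sets[[nm]], gene_names, paste0(nm, "_markers")))
  names(excl_sets) <- c("epithelial", "immune", "endothelial")
  if (!any(lengths(excl_sets)))
    .stopf("no lineage exclusion markers found in matrix")

  emb <- embed_pca(norm, n_hvg = n_hvg, n_pc = n_pc)
  km <- kmeans_sse(emb, k = min(coarse_k, nrow(emb)), seed = seed,
                   n_init = n_init)
  lab <- km$labels

  # step 1: cluster-level fibroblast-marker score
  cell_score <- Matrix::colMeans(norm$values[fib_genes, , drop = FALSE])
  cl_score <- tapply(cell_score, lab, mean)
  mu <- mean(cl_score); sdv <- stats::sd(cl_score)
  candidate <- if (is.na(sdv) || sdv == 0) rep(FALSE, length(cl_score)) else
    (cl_score - mu) / sdv >= step1_margin
  cand_clusters <- as.integer(names(cl_score)[candidate])

  # step 2: per-cell lineage exclusion inside candidate clusters
  calls <- rep("other", ncol(norm$values))
  offending <- rep(NA_character_, ncol(norm$values))
  in_cand <- lab %in% cand_clusters
  if (any(in_cand)) {
    excl_genes <- unlist(excl_sets, use.names = FALSE)
    sub <- norm$values[excl_genes, in_cand, drop = FALSE]
    over <- as.matrix(sub > step2_max_norm_expr)
    hit <- apply(over, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
    idx <- which(in_cand)
    calls[idx] <- ifelse(is.na(hit), "fibroblast", "excluded_lineage")
    offending[idx[!is.na(hit)]] <- excl_genes[hit[!is.na(hit)]]
  }
  structure(list(
    calls = data.frame(cell_id = colnames(norm$values), call = calls,
                       offending_marker = offending,
                       stringsAsFactors = FALSE),
    cluster_evidence = data.frame(cluster = as.integer(names(cl_score)),
                                  mean_fib_score = as.numeric(cl_score),
                                  candidate = as.logical(candidate)),
    coarse_labels = lab), class = "fibroblast_calls")
}

#' @export
print.fibroblast_calls <- function(x, ...) {
  tab <- table(x$calls$call)
  cat("fibroblast_calls:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Cell ids called fibroblast
#' @param calls a \code{fibroblast_calls} object.
#' @return character vector.
#' @export
fibroblast_cells <- function(calls) {
  stopifnot(inherits(calls, "fibroblast_calls"))
  calls$calls$cell_id[calls$calls$call == "fibroblast"]
}
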