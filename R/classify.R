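# The classify stage: signature scoring plus the three taxonomy calls,
# with a lone paCAF cluster resubclustered so its myCAF/iCAF halves become
# clusters of their own.

#' Classify fibroblast clusters into the CAF/NF taxonomy
#'
#' Scores the marker panel per cell and cluster, then: tumour clusters are
#' called paCAF / non-paCAF from PRRX1 activation and CAF-related gene
#' scores ([call_pacaf()]); normal clusters are called tr-MSCF / tr-RF
#' from BM-MSC markers with HSC exclusion ([call_normal_taxonomy()]);
#' paCAF clusters are subtyped myCAF / iCAF with a rank-sum test
#' ([subtype_pacaf()]). If only one paCAF cluster exists it is split by
#' k = 2 k-means first, and the subclusters are folded back into the
#' assignment table so downstream stages (origin tracing, trajectory) see
#' them as clusters of their own. Clusters from "bm" tissue are labeled
#' BM-MSC-like.
#'
#' @param norm a \code{caf_norm} restricted to the clustered fibroblasts.
#' @param clusters a \code{caf_clusters} object.
#' @param panel a \code{gene_panel}.
#' @param high_margin_sd,low_ceiling,alpha taxonomy thresholds.
#' @param seed seed for the resubclustering k-means.
#' @return list with \code{taxonomy} (data frame: cluster, tissue,
#'   pacaf_label, label; attributes \code{"scores"} and
#'   \code{"subtype_tests"}) and \code{clusters} (the possibly updated
#'   \code{caf_clusters}).
#' @export
classify_fibroblast_clusters <- function(norm, clusters, panel,
                                         high_margin_sd = 0.5,
                                         low_ceiling = 0.1, alpha = 0.05,
                                         seed = 1L) {
  stopifnot(inherits(clusters, "caf_clusters"))
  scores <- score_sets(norm, clusters, panel)
  asg <- clusters$assignments
  tumour_cl <- sort(unique(asg$cluster[asg$tissue == "tumour"]))
  normal_cl <- sort(unique(asg$cluster[asg$tissue == "normal"]))
  if (!length(tumour_cl)) .stopf("no tumour fibroblast clusters")
  if (!length(normal_cl)) .stopf("no normal fibroblast clusters")
  pac <- call_pacaf(scores, tumour_cl, high_margin_sd = high_margin_sd)
  nor <- call_normal_taxonomy(scores, normal_cl,
                              high_margin_sd = high_margin_sd,
                              low_ceiling = low_ceiling)
  pacaf_cl <- pac$cluster[pac$label == "paCAF"]
  sub <- if (length(pacaf_cl) >= 1) {
    subtype_pacaf(scores, pacaf_cl, embedding = clusters$embedding,
                  resubcluster = length(pacaf_cl) == 1, alpha = alpha,
                  seed = seed)
  } else NULL
  if (!is.null(sub)) {
    sub_asg <- attr(sub, "assignments")
    idx <- match(sub_asg$cell_id, clusters$assignments$cell_id)
    clusters$assignments$cluster[idx] <- sub_asg$cluster
    asg <- clusters$assignments
    tumour_cl <- sort(unique(asg$cluster[asg$tissue == "tumour"]))
  }
  tum_label <- setNames(rep("non-paCAF", length(tumour_cl)), tumour_cl)
  tum_pacaf <- setNames(rep("non-paCAF", length(tumour_cl)), tumour_cl)
  if (!is.null(sub)) {
    tum_pacaf[sub$cluster] <- "paCAF"
    tum_label[sub$cluster] <-
      ifelse(sub$label == "unassigned", "paCAF", sub$label)
  }
  tax <- rbind(
    data.frame(cluster = tumour_cl, tissue = "tumour",
               pacaf_label = as.character(tum_pacaf),
               label = as.character(tum_label), stringsAsFactors = FALSE),
    data.frame(cluster = nor$cluster, tissue = "normal",
               pacaf_label = NA_character_, label = nor$label,
               stringsAsFactors = FALSE))
  bm_cl <- sort(unique(asg$cluster[asg$tissue == "bm"]))
  if (length(bm_cl))
    tax <- rbind(tax, data.frame(cluster = bm_cl, tissue = "bm",
                                 pacaf_label = NA_character_,
                                 label = "BM-MSC-like",
                                 stringsAsFactors = FALSE))
  attr(tax, "scores") <- scores
  attr(tax, "subtype_tests") <- sub
  list(taxonomy = tax, clusters = clusters)
}
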