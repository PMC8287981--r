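# Marker gene-set panels.
#
# A panel is a named list of gene-symbol sets plus the two thresholds used
# by the taxonomy calls. Sets follow field usage: pan-fibroblast and
# lineage-exclusion markers for the two-step fibroblast screen; PRRX1 and
# CAF-related genes for the perpetually-activated call; BM-MSC and
# hematopoietic (HSC) markers for the tr-MSCF call; ACTA2/TAGLN-type and
# PDGFRA/CFD/CXCL12-type signatures for myCAF/iCAF subtyping.

.panel_set_names <- c("fibroblast_markers", "epithelial_markers",
                      "immune_markers", "endothelial_markers", "activation",
                      "caf_related", "bm_msc_markers", "hsc_markers",
                      "mycaf_signature", "icaf_signature")

#' Default marker gene-set panel
#'
#' Returns the panel matching the synthetic generator's gene naming: the
#' canonical marker symbols plus the generator's per-program filler genes,
#' so that a set covers its whole planted program. \code{n_fill = 0} gives
#' canonical symbols only (usable on real data).
#'
#' @param n_fill how many filler genes per program to include (default
#'   matches [sim_config()]'s 25 genes per program).
#' @param high_margin_sd margin, in across-cluster standard deviations, by
#'   which a score must exceed the cluster mean to count as "high".
#' @param low_ceiling maximum score still counting as "absent" (used for
#'   HSC-marker exclusion).
#' @return object of class \code{gene_panel}: named list of character
#'   vectors plus \code{thresholds}.
#' @export
default_panel <- function(n_fill = 20L, high_margin_sd = 0.5,
                          low_ceiling = 0.1) {
  fill <- function(p) {
    seeds <- .program_seed_symbols[[p]]
    n <- max(0L, min(n_fill, 25L - length(seeds)))
    c(seeds, if (n > 0) sprintf("%s_M%02d", toupper(p), seq_len(n)))
  }
  sets <- list(
    fibroblast_markers  = fill("fibroblast"),
    epithelial_markers  = fill("epithelial"),
    immune_markers      = fill("immune"),
    endothelial_markers = fill("endothelial"),
    activation          = "PRRX1",
    caf_related         = setdiff(fill("activation"), "PRRX1"),
    bm_msc_markers      = fill("bm_msc"),
    hsc_markers         = c("PTPRC", "CD34"),
    mycaf_signature     = fill("mycaf"),
    icaf_signature      = fill("icaf")
  )
  new_gene_panel(sets, high_margin_sd = high_margin_sd,
                 low_ceiling = low_ceiling)
}

#' Construct and validate a gene-set panel
#'
#' @param sets named list of non-empty character vectors; must include all
#'   of the standard set names (see [default_panel()]). The myCAF and iCAF
#'   signatures must be disjoint.
#' @param high_margin_sd,low_ceiling taxonomy thresholds.
#' @return object of class \code{gene_panel}.
#' @export
new_gene_panel <- function(sets, high_margin_sd = 0.5, low_ceiling = 0.1) {
  missing <- setdiff(.panel_set_names, names(sets))
  if (length(missing))
    .stopf("panel is missing sets: %s", paste(missing, collapse = ", "))
  if (any(!vapply(sets[.panel_set_names], length, 1L)))
    .stopf("every panel set must be non-empty")
  if (length(intersect(sets$mycaf_signature, sets$icaf_signature)))
    .stopf("mycaf_signature and icaf_signature must be disjoint")
  structure(c(sets[.panel_set_names],
              list(thresholds = list(high_margin_sd = high_margin_sd,
                                     low_ceiling = low_ceiling))),
            class = "gene_panel")
}

#' Read / write a panel as keyed YAML text
#'
#' The file maps set names to gene-symbol lists, with an optional
#' \code{thresholds} block (\code{high_margin_sd}, \code{low_ceiling}).
#'
#' @param path file path.
#' @return \code{read_panel} returns a \code{gene_panel};
#'   \code{write_panel} returns the path invisibly.
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  thr <- raw$thresholds
  raw$thresholds <- NULL
  new_gene_panel(lapply(raw, as.character),
                 high_margin_sd = if (!is.null(thr$high_margin_sd))
                   thr$high_margin_sd else 0.5,
                 low_ceiling = if (!is.null(thr$low_ceiling))
                   thr$low_ceiling else 0.1)
}

#' @rdname read_panel
#' @param panel a \code{gene_panel} object.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  yaml::write_yaml(unclass(panel), path)
  invisible(path)
}

# match one set's symbols against matrix genes; unmatched are reported once
.match_set <- function(set, gene_names, set_name, quiet = FALSE) {
  hit <- intersect(set, gene_names)
  if (!quiet && length(hit) < length(set))
    message(sprintf("panel set '%s': %d/%d genes not in matrix (ignored)",
                    set_name, length(set) - length(hit), length(set)))
  hit
}
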