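# End-to-end orchestration: simulate (or ingest) -> QC/normalize ->
# two-step fibroblast identification -> per-sample clustering ->
# taxonomy -> origin tracing -> trajectory, with a machine-readable run
# report. A single top-level seed fans out to per-stage seeds by fixed
# offsets so each stage is individually reproducible.

.stage_seed <- function(seed, stage) {
  seed + c(simulate = 0L, prep = 1000L, cluster = 2000L,
           classify = 3000L, trajectory = 4000L)[[stage]]
}

#' Default pipeline configuration
#'
#' Returns the full configuration for [run_all()]: a simulation block
#' (see [sim_config()]) plus per-stage parameter blocks with the package
#' defaults.
#'
#' @param seed top-level integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = as.list(unclass(sim_config(seed = seed))),
    prep = list(coarse_k = 10L, step1_margin = 1.0,
                step2_max_norm_expr = 0.25, min_genes_per_cell = 200L,
                min_cells_per_gene = 3L),
    cluster = list(k_min = 1L, k_max = 10L, drop_threshold = 0.10,
                   n_hvg = 2000L, n_pc = 20L, n_init = 10L),
    classify = list(high_margin_sd = 0.5, low_ceiling = 0.1, alpha = 0.05),
    origin = list(n_hvg = 2000L, delta = 0.05),
    trajectory = list(root = "tr-MSCF", smooth_span = 0.3, max_iter = 50L,
                      tol = 1e-6, n_dim = 20L)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @return \code{read_config} returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  for (blk in intersect(names(base), names(cfg)))
    if (is.list(base[[blk]]))
      base[[blk]][names(cfg[[blk]])] <- cfg[[blk]] else
        base[[blk]] <- cfg[[blk]]
  if (!is.null(cfg$input_dir)) base$input_dir <- cfg$input_dir
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: simulation (or triplet ingestion from
#' \code{config$input_dir}), QC and normalization, two-step fibroblast
#' identification, per-sample SSE-elbow k-means clustering, taxonomy
#' calls (paCAF / non-paCAF, tr-MSCF / tr-RF, myCAF / iCAF), origin
#' tracing, and principal-curve pseudotime with ordering tests. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config configuration list (see [default_config()]), or a path
#'   to a YAML configuration file.
#' @param out_dir optional output directory; when given, every stage's
#'   tables plus \code{report.json} are written there.
#' @param panel optional \code{gene_panel}; defaults to [default_panel()]
#'   with the classify-block thresholds.
#' @return object of class \code{caf_run_report} (a list): headline
#'   quantities (\code{fibroblast_fraction}, \code{chosen_k},
#'   \code{pacaf_fraction_of_cafs}), the taxonomy, origin and ordering
#'   tables, intermediate objects, and the configuration used.
#' @export
run_all <- function(config = default_config(), out_dir = NULL,
                    panel = NULL) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(config$seed)
  if (is.null(panel))
    panel <- default_panel(high_margin_sd = config$classify$high_margin_sd,
                           low_ceiling = config$classify$low_ceiling)

  truth <- NULL
  counts <- .run_stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_mtx_triplet(config$input_dir)
    } else {
      sim_args <- config$simulate
      sim_args$seed <- .stage_seed(seed, "simulate")
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      truth <- sim$truth
      sim$counts
    }
  })

  norm <- .run_stage("prep", {
    filtered <- qc_filter(counts, config$prep$min_genes_per_cell,
                          config$prep$min_cells_per_gene)
    normalize_counts(filtered)
  })
  calls <- .run_stage("prep", identify_fibroblasts(
    norm, panel, coarse_k = config$prep$coarse_k,
    step1_margin = config$prep$step1_margin,
    step2_max_norm_expr = config$prep$step2_max_norm_expr,
    n_hvg = config$cluster$n_hvg, n_pc = config$cluster$n_pc,
    seed = .stage_seed(seed, "prep")))
  fib_cells <- fibroblast_cells(calls)
  if (length(fib_cells) < 4L)
    .stopf("stage 'prep' failed: only %d fibroblasts identified",
           length(fib_cells))
  fibroblast_fraction <- length(fib_cells) / ncol(norm$values)

  fib_norm <- subset_norm(norm, fib_cells)
  clusters <- .run_stage("cluster", cluster_fibroblasts(
    fib_norm, k_min = config$cluster$k_min, k_max = config$cluster$k_max,
    drop_threshold = config$cluster$drop_threshold,
    n_hvg = config$cluster$n_hvg, n_pc = config$cluster$n_pc,
    seed = .stage_seed(seed, "cluster"), n_init = config$cluster$n_init))

  classified <- .run_stage("classify", classify_fibroblast_clusters(
    fib_norm, clusters, panel,
    high_margin_sd = config$classify$high_margin_sd,
    low_ceiling = config$classify$low_ceiling,
    alpha = config$classify$alpha,
    seed = .stage_seed(seed, "classify")))
  taxonomy <- classified$taxonomy
  clusters <- classified$clusters

  origin <- .run_stage("origin", trace_origins(
    fib_norm, clusters, n_hvg = config$origin$n_hvg,
    delta = config$origin$delta))

  trajectory <- .run_stage("trajectory", {
    traj_labels <- c("tr-MSCF", "iCAF", "myCAF", "BM-MSC-like")
    keep_cl <- taxonomy$cluster[taxonomy$label %in% traj_labels]
    asg <- clusters$assignments
    cells <- asg$cell_id[asg$cluster %in% keep_cl]
    if (length(cells) < 10L)
      .stopf("too few trajectory cells (%d)", length(cells))
    lab <- setNames(taxonomy$label[match(asg$cluster, taxonomy$cluster)],
                    asg$cell_id)[cells]
    n_dim <- min(config$trajectory$n_dim, ncol(clusters$embedding))
    emb <- clusters$embedding[cells, seq_len(n_dim), drop = FALSE]
    fit <- fit_principal_curve(emb,
                               max_iter = config$trajectory$max_iter,
                               smooth_span = config$trajectory$smooth_span,
                               tol = config$trajectory$tol,
                               seed = .stage_seed(seed, "trajectory"))
    root <- config$trajectory$root
    if (!root %in% lab) .stopf("root population '%s' has no cells", root)
    traj <- assign_pseudotime(fit, lab, root)
    ord <- list()
    pairs <- list(c("iCAF", "myCAF"), c("tr-MSCF", "iCAF"),
                  c("tr-MSCF", "myCAF"))
    for (pp in pairs) {
      if (sum(lab == pp[1], na.rm = TRUE) >= 3 &&
          sum(lab == pp[2], na.rm = TRUE) >= 3) {
        ts <- test_ordering(traj, pp[1], pp[2])
        ord[[paste(pp, collapse = "_vs_")]] <- ts
      }
    }
    list(result = traj, ordering_tests = ord)
  })

  pacaf_fraction <- summarize_pacaf_fraction(taxonomy, clusters)

  report <- structure(list(
    fibroblast_fraction = fibroblast_fraction,
    chosen_k = as.list(clusters$chosen_k),
    pacaf_fraction_of_cafs = pacaf_fraction,
    taxonomy = taxonomy,
    origin = origin,
    ordering_tests = trajectory$ordering_tests,
    trajectory = trajectory$result,
    clusters = clusters,
    calls = calls,
    norm = norm,
    truth = truth,
    config = config
  ), class = "caf_run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.caf_run_report <- function(x, ...) {
  cat("caf_run_report\n")
  cat(sprintf("  fibroblast fraction: %.4f\n", x$fibroblast_fraction))
  cat(sprintf("  chosen k: %s\n",
              paste(sprintf("%s=%d", names(x$chosen_k),
                            unlist(x$chosen_k)), collapse = ", ")))
  cat(sprintf("  paCAF fraction of CAFs: %.4f\n", x$pacaf_fraction_of_cafs))
  cat("  taxonomy:\n")
  print(x$taxonomy[, c("cluster", "tissue", "label")], row.names = FALSE)
  for (nm in names(x$ordering_tests)) {
    ts <- x$ordering_tests[[nm]]
    cat(sprintf("  ordering %s: %s (p = %.3g)\n", nm, ts$direction, ts$p))
  }
  invisible(x)
}

#' paCAF fraction of CAFs
#'
#' Number of tumour fibroblast cells in paCAF-labeled clusters (including
#' their myCAF/iCAF subtypes) divided by all tumour fibroblast cells.
#'
#' @param taxonomy taxonomy table with \code{cluster} and \code{label}.
#' @param clusters a \code{caf_clusters} object or assignment data frame.
#' @return proportion in [0, 1].
#' @export
summarize_pacaf_fraction <- function(taxonomy, clusters) {
  asg <- if (inherits(clusters, "caf_clusters")) clusters$assignments else
    clusters
  tum <- asg[asg$tissue == "tumour", , drop = FALSE]
  if (!nrow(tum)) .stopf("no tumour fibroblast cells")
  pac_cl <- taxonomy$cluster[taxonomy$label %in% c("paCAF", "iCAF", "myCAF")]
  sum(tum$cluster %in% pac_cl) / nrow(tum)
}

#' Write a run report to disk
#'
#' Writes \code{report.json} (headline quantities) plus TSV mirrors of the
#' taxonomy, cluster assignments, SSE curves, origin map and calls,
#' pseudotime and ordering tests.
#'
#' @param report a \code{caf_run_report}.
#' @param out_dir output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "caf_run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$taxonomy, "taxonomy.tsv")
  tsv(report$clusters$assignments, "clusters.tsv")
  sse <- do.call(rbind, lapply(names(report$clusters$sse_curves), function(s)
    data.frame(sample_id = s, k = as.integer(names(
      report$clusters$sse_curves[[s]])),
      sse = as.numeric(report$clusters$sse_curves[[s]]))))
  tsv(sse, "sse_curves.tsv")
  rho <- report$origin$rho
  tsv(data.frame(tumour_cluster = rownames(rho)[row(rho)],
                 normal_cluster = colnames(rho)[col(rho)],
                 rho = as.numeric(rho)), "origin_map.tsv")
  tsv(report$origin$calls, "origin_calls.tsv")
  pt <- report$trajectory$pseudotime
  tsv(data.frame(cell_id = names(pt), pseudotime = as.numeric(pt),
                 label = as.character(report$trajectory$labels)),
      "pseudotime.tsv")
  ord <- do.call(rbind, lapply(names(report$ordering_tests), function(nm) {
    ts <- report$ordering_tests[[nm]]
    data.frame(pair = nm, statistic = ts$statistic, p = ts$p,
               direction = ts$direction)
  }))
  if (!is.null(ord)) tsv(ord, "ordering_tests.tsv")
  headline <- list(
    fibroblast_fraction = report$fibroblast_fraction,
    chosen_k = report$chosen_k,
    pacaf_fraction_of_cafs = report$pacaf_fraction_of_cafs,
    ordering_tests = lapply(report$ordering_tests, function(ts)
      list(statistic = ts$statistic, p = ts$p, direction = ts$direction)),
    seed = report$config$seed
  )
  jsonlite::write_json(headline, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
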