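# Synthetic mixed-tissue scRNA-seq generator.
#
# The generator plants the population structure the downstream analysis
# assumes: a mixed-tissue dataset in which fibroblasts are a small minority
# among epithelial/immune/endothelial cells, tumour fibroblasts split into
# non-paCAF / iCAF / myCAF, normal fibroblasts into tr-RF / tr-MSCF, and the
# tr-MSCF -> iCAF -> myCAF populations lie on a latent differentiation
# continuum along which marker-program activity changes smoothly.

# marker program gene symbols; the first few are canonical field markers,
# the rest synthetic fillers so each program has n_marker_genes_per_program
# disjoint genes
.program_seed_symbols <- list(
  epithelial  = c("EPCAM", "KRT8", "KRT18", "KRT19", "CDH1"),
  immune      = c("PTPRC", "CD3D", "CD3E", "CD2", "LYZ"),
  endothelial = c("PECAM1", "VWF", "CDH5", "CLDN5", "CD34"),
  fibroblast  = c("COL1A1", "COL1A2", "COL3A1", "DCN", "LUM"),
  activation  = c("PRRX1", "FAP", "POSTN", "FN1", "THBS2"),
  bm_msc      = c("ENG", "NT5E", "THY1", "PDGFRB", "CD44"),
  icaf        = c("PDGFRA", "CFD", "CXCL12", "IL6", "CXCL1"),
  mycaf       = c("ACTA2", "TAGLN", "MYH11", "MYL9", "CTGF")
)

# latent-pseudotime windows for continuum populations
.pt_windows <- list(
  bm_msc  = c(0.00, 0.15),
  tr_MSCF = c(0.05, 0.28),
  iCAF    = c(0.32, 0.60),
  myCAF   = c(0.62, 1.00)
)

# program activity in [0,1] as a function of latent pseudotime; logistic
# dynamics: iCAF program decays, myCAF program rises, BM-MSC program is
# highest near the root but keeps a floor of 0.5 so that paCAFs retain
# elevated MSC-marker expression (they share an MSC origin with tr-MSCFs)
.continuum_activity <- function(t) {
  cbind(
    bm_msc = 0.65 + 0.35 * stats::plogis((0.25 - t) / 0.15),
    icaf   = stats::plogis((0.61 - t) / 0.04),
    mycaf  = stats::plogis((t - 0.61) / 0.04)
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults describe a matched tumour/normal pair of ~5,000 cells in which
#' fibroblasts are 8\% of cells, perpetually activated CAFs (iCAF + myCAF)
#' are 65\% of tumour fibroblasts, and tr-MSCFs are 40\% of normal
#' fibroblasts.
#'
#' @param n_cells_tumour,n_cells_normal cells per tissue.
#' @param fibroblast_fraction probability that a cell is a fibroblast.
#' @param caf_composition named proportions over
#'   \code{c("non_paCAF","iCAF","myCAF")}, summing to 1.
#' @param nf_composition named proportions over \code{c("tr_RF","tr_MSCF")},
#'   summing to 1.
#' @param include_bm_msc include a bone-marrow MSC population (tissue "bm").
#' @param n_bm_msc number of BM-MSC cells when included.
#' @param n_genes total genes (must cover all marker programs).
#' @param n_marker_genes_per_program genes per marker program (8 disjoint
#'   programs).
#' @param baseline_mean negative-binomial mean of background genes.
#' @param marker_fold_change multiplicative elevation of a fully active
#'   marker gene over baseline (>= 1).
#' @param marker_off_mean NB mean of a marker gene in cells where its
#'   program is inactive; the default 0 makes markers perfectly
#'   lineage-specific (no ambient contamination is modelled).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2);
#'   0 gives Poisson noise.
#' @param library_size_lognormal_sigma sd of the per-cell log-normal
#'   library-size factor.
#' @param continuum_noise_sd sd of Gaussian noise added to the log-mean of
#'   each continuum program, per cell and program.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells_tumour = 2500L,
                       n_cells_normal = 2500L,
                       fibroblast_fraction = 0.08,
                       caf_composition = c(non_paCAF = 0.35, iCAF = 0.30,
                                           myCAF = 0.35),
                       nf_composition = c(tr_RF = 0.60, tr_MSCF = 0.40),
                       include_bm_msc = FALSE,
                       n_bm_msc = 300L,
                       n_genes = 2000L,
                       n_marker_genes_per_program = 25L,
                       baseline_mean = 0.3,
                       marker_fold_change = 8,
                       marker_off_mean = 0,
                       nb_dispersion = 0.5,
                       library_size_lognormal_sigma = 0.3,
                       continuum_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_cells_tumour = .check_count(n_cells_tumour, "n_cells_tumour"),
    n_cells_normal = .check_count(n_cells_normal, "n_cells_normal"),
    fibroblast_fraction = .check_prop(fibroblast_fraction,
                                      "fibroblast_fraction"),
    caf_composition = caf_composition,
    nf_composition = nf_composition,
    include_bm_msc = isTRUE(include_bm_msc),
    n_bm_msc = .check_count(n_bm_msc, "n_bm_msc"),
    n_genes = .check_count(n_genes, "n_genes", min = 1L),
    n_marker_genes_per_program =
      .check_count(n_marker_genes_per_program, "n_marker_genes_per_program",
                   min = 5L),
    baseline_mean = baseline_mean,
    marker_fold_change = marker_fold_change,
    marker_off_mean = marker_off_mean,
    nb_dispersion = nb_dispersion,
    library_size_lognormal_sigma = library_size_lognormal_sigma,
    continuum_noise_sd = continuum_noise_sd,
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  .check_composition <- function(x, name, levels) {
    if (is.null(names(x)) || !setequal(names(x), levels))
      .stopf("'%s' must be named over {%s}", name,
             paste(levels, collapse = ", "))
    if (any(x <= 0) || any(x >= 1))
      .stopf("'%s' proportions must lie in (0,1)", name)
    if (abs(sum(x) - 1) > 1e-9)
      .stopf("'%s' must sum to 1 (got %.12f)", name, sum(x))
  }
  .check_composition(cfg$caf_composition, "caf_composition",
                     c("non_paCAF", "iCAF", "myCAF"))
  .check_composition(cfg$nf_composition, "nf_composition",
                     c("tr_RF", "tr_MSCF"))
  if (cfg$baseline_mean <= 0) .stopf("'baseline_mean' must be positive")
  if (cfg$marker_fold_change < 1)
    .stopf("'marker_fold_change' must be >= 1")
  if (cfg$marker_off_mean < 0) .stopf("'marker_off_mean' must be >= 0")
  if (cfg$nb_dispersion < 0) .stopf("'nb_dispersion' must be >= 0")
  if (cfg$library_size_lognormal_sigma < 0)
    .stopf("'library_size_lognormal_sigma' must be >= 0")
  if (cfg$continuum_noise_sd < 0) .stopf("'continuum_noise_sd' must be >= 0")
  n_marker <- length(.program_seed_symbols) * cfg$n_marker_genes_per_program
  if (cfg$n_genes < n_marker)
    .stopf("n_genes (%d) smaller than total marker genes (%d)",
           cfg$n_genes, n_marker)
  invisible(cfg)
}

# gene symbol table: marker programs occupy the first blocks, the remainder
# are background genes
.build_gene_table <- function(cfg) {
  k <- cfg$n_marker_genes_per_program
  progs <- names(.program_seed_symbols)
  symbols <- character(0)
  program <- character(0)
  for (p in progs) {
    seeds <- .program_seed_symbols[[p]]
    fill <- sprintf("%s_M%02d", toupper(p), seq_len(k - length(seeds)))
    symbols <- c(symbols, c(seeds, fill)[seq_len(k)])
    program <- c(program, rep(p, k))
  }
  n_bg <- cfg$n_genes - length(symbols)
  symbols <- c(symbols, sprintf("BG%05d", seq_len(n_bg)))
  program <- c(program, rep("background", n_bg))
  data.frame(gene_id = sprintf("ENSG%08d", seq_len(cfg$n_genes)),
             gene_symbol = symbols, program = program,
             stringsAsFactors = FALSE)
}

# per-cell ground-truth table; draws consume the RNG in a fixed order:
# (1) major type per tissue, (2) fibroblast subtype, (3) latent pseudotime
.draw_truth <- function(cfg) {
  one_tissue <- function(n, tissue, prefix) {
    if (n == 0L)
      return(data.frame(cell_id = character(0), tissue = character(0),
                        major_type = character(0), fib_subtype = character(0),
                        latent_pseudotime = numeric(0),
                        stringsAsFactors = FALSE))
    is_fib <- runif(n) < cfg$fibroblast_fraction
    major <- character(n)
    major[is_fib] <- "fibroblast"
    n_other <- sum(!is_fib)
    major[!is_fib] <- sample(c("epithelial", "immune", "endothelial"),
                             n_other, replace = TRUE,
                             prob = c(0.50, 0.35, 0.15))
    sub <- rep("none", n)
    comp <- if (tissue == "tumour") cfg$caf_composition else cfg$nf_composition
    sub[is_fib] <- sample(names(comp), sum(is_fib), replace = TRUE,
                          prob = comp)
    data.frame(cell_id = sprintf("%s_%05d", prefix, seq_len(n)),
               tissue = tissue, major_type = major, fib_subtype = sub,
               latent_pseudotime = NA_real_, stringsAsFactors = FALSE)
  }
  truth <- rbind(one_tissue(cfg$n_cells_tumour, "tumour", "T1"),
                 one_tissue(cfg$n_cells_normal, "normal", "N1"))
  if (cfg$include_bm_msc && cfg$n_bm_msc > 0L) {
    bm <- data.frame(cell_id = sprintf("BM_%05d", seq_len(cfg$n_bm_msc)),
                     tissue = "bm", major_type = "bm_msc",
                     fib_subtype = "none", latent_pseudotime = NA_real_,
                     stringsAsFactors = FALSE)
    truth <- rbind(truth, bm)
  }
  on_path <- truth$fib_subtype %in% c("tr_MSCF", "iCAF", "myCAF") |
    truth$major_type == "bm_msc"
  key <- ifelse(truth$major_type == "bm_msc", "bm_msc", truth$fib_subtype)
  for (pop in names(.pt_windows)) {
    idx <- which(on_path & key == pop)
    if (length(idx))
      truth$latent_pseudotime[idx] <- runif(length(idx),
                                            .pt_windows[[pop]][1],
                                            .pt_windows[[pop]][2])
  }
  truth
}

# activity matrix: programs x cells, entries in [0,1]
.activity_matrix <- function(cfg, truth) {
  progs <- names(.program_seed_symbols)
  a <- matrix(0, length(progs), nrow(truth), dimnames = list(progs, NULL))
  mt <- truth$major_type
  fs <- truth$fib_subtype
  a["epithelial", mt == "epithelial"] <- 1
  a["immune", mt == "immune"] <- 1
  a["endothelial", mt == "endothelial"] <- 1
  a["fibroblast", mt %in% c("fibroblast", "bm_msc")] <- 1
  a["activation", fs %in% c("iCAF", "myCAF")] <- 1
  on_path <- !is.na(truth$latent_pseudotime)
  if (any(on_path)) {
    act <- .continuum_activity(truth$latent_pseudotime[on_path])
    a["bm_msc", on_path] <- act[, "bm_msc"]
    a["icaf", on_path] <- act[, "icaf"]
    a["mycaf", on_path] <- act[, "mycaf"]
  }
  a
}

#' Simulate a mixed-tissue single-cell dataset with planted fibroblast
#' structure
#'
#' Draws gene-by-cell negative-binomial counts for a tumour/normal pair (and
#' optionally a BM-MSC sample). Marker-program genes are elevated
#' \code{marker_fold_change}-fold in cells whose program is active; cells on
#' the tr-MSCF/iCAF/myCAF continuum get smoothly varying program activity
#' driven by a latent pseudotime. All randomness comes from one RNG stream
#' seeded with \code{config$seed}, consumed in a fixed documented order
#' (labels, pseudotimes, library factors, continuum noise, counts), so
#' identical configurations give byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements \code{counts} (a \code{caf_counts} object:
#'   sparse genes x cells counts, gene table, cell metadata) and
#'   \code{truth} (per-cell ground-truth data frame with tissue, major type,
#'   fibroblast subtype and latent pseudotime).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  set.seed(config$seed)
  genes <- .build_gene_table(config)
  truth <- .draw_truth(config)
  n_cells <- nrow(truth)
  if (n_cells == 0L) .stopf("configuration yields zero cells")
  lib <- rlnorm(n_cells, 0, config$library_size_lognormal_sigma)
  act <- .activity_matrix(config, truth)
  if (config$continuum_noise_sd > 0) {
    on_path <- which(!is.na(truth$latent_pseudotime))
    for (p in c("bm_msc", "icaf", "mycaf"))
      act[p, on_path] <- act[p, on_path] *
        exp(rnorm(length(on_path), 0, config$continuum_noise_sd))
  }
  # per-gene x per-cell NB mean
  log_fold <- log(config$marker_fold_change)
  mu <- matrix(config$baseline_mean, config$n_genes, n_cells)
  for (p in rownames(act)) {
    g <- which(genes$program == p)
    a_p <- act[p, ]
    on <- a_p > 0
    mu[g, on] <- config$baseline_mean *
      exp(rep(a_p[on], each = length(g)) * log_fold)
    if (any(!on)) mu[g, !on] <- config$marker_off_mean
  }
  mu <- sweep(mu, 2, lib, "*")
  counts <- if (config$nb_dispersion == 0) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  m <- matrix(as.integer(counts), config$n_genes, n_cells)
  dimnames(m) <- list(genes$gene_symbol, truth$cell_id)
  counts_sp <- Matrix::Matrix(m, sparse = TRUE)
  meta <- data.frame(cell_id = truth$cell_id,
                     sample_id = c(tumour = "T1", normal = "N1",
                                   bm = "BM1")[truth$tissue],
                     tissue = truth$tissue, stringsAsFactors = FALSE)
  counts_obj <- new_caf_counts(counts_sp, meta, gene_table = genes)
  list(counts = counts_obj, truth = truth)
}

#' Deterministic expected expression profiles
#'
#' Returns the noise-free per-cell log-mean expression implied by a
#' configuration and a ground-truth table: \code{log(baseline) + a *
#' log(fold)} for marker genes with activity \code{a}, \code{log(baseline)}
#' for background genes. Library-size factors, continuum noise and count
#' sampling are all excluded, so profiles of continuum cells lie exactly on
#' the latent curve; useful for zero-noise checks of trajectory recovery.
#'
#' @param config a [sim_config()] object.
#' @param truth ground-truth table from [simulate_dataset()].
#' @param cells optional character vector of cell ids to restrict to.
#' @return dense matrix, genes x cells.
#' @export
expected_profiles <- function(config, truth, cells = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(cells)) truth <- truth[match(cells, truth$cell_id), ]
  genes <- .build_gene_table(config)
  act <- .activity_matrix(config, truth)
  log_base <- log(config$baseline_mean)
  log_off <- log(max(config$marker_off_mean, 1e-8))
  out <- matrix(log_base, config$n_genes, nrow(truth),
                dimnames = list(genes$gene_symbol, truth$cell_id))
  for (p in rownames(act)) {
    g <- which(genes$program == p)
    out[g, ] <- ifelse(rep(act[p, ] > 0, each = length(g)),
                       log_base + rep(act[p, ], each = length(g)) *
                         log(config$marker_fold_change),
                       log_off)
  }
  out
}

#' Write / read a ground-truth table
#'
#' Tab-separated, one row per cell; round-trips losslessly (an empty table
#' writes a header-only file).
#'
#' @param truth ground-truth data frame.
#' @param path file path.
#' @return \code{write_truth} returns the path invisibly; \code{read_truth}
#'   returns the data frame.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(latent_pseudotime = "numeric"))
}
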