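#' @importFrom methods as is
#' @importFrom stats median rnorm runif rnbinom rpois rlnorm var sd quantile
#'   lowess approx pnorm kmeans prcomp setNames aggregate
#' @importFrom utils head read.delim write.table combn
NULL

# stop() with sprintf formatting, no call in message
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check a probability-like scalar
.check_prop <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) .stopf("'%s' must be a proportion in %s, got %s",
                  name, if (open) "(0,1)" else "[0,1]", format(x))
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) .stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# row variances of a dense or sparse matrix (genes x cells), without
# densifying the sparse case
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m * m)
  (ex2 - mu^2) * n / (n - 1)
}

# indices of the top-n most variable rows (ties broken by row order)
.top_hvg <- function(values, n_hvg) {
  v <- .row_vars(values)
  n <- min(n_hvg, nrow(values))
  order(v, decreasing = TRUE)[seq_len(n)]
}

#' Select the n most highly variable genes
#'
#' Ranks genes by their variance across cells of the supplied normalized
#' expression matrix and returns the identifiers of the top \code{n_hvg}.
#'
#' @param norm a \code{caf_norm} object (see [normalize_counts()]).
#' @param n_hvg number of genes to keep.
#' @return character vector of gene identifiers.
#' @export
highly_variable_genes <- function(norm, n_hvg = 2000L) {
  stopifnot(inherits(norm, "caf_norm"))
  rownames(norm$values)[.top_hvg(norm$values, n_hvg)]
}
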