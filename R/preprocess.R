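#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one distribution: each sample's
#' sorted values are replaced by the across-sample mean of order statistics;
#' ties within a sample receive the mean of their assigned quantile values.
#'
#' @param m Genes x samples numeric matrix, finite values, >= 2 samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (!all(is.finite(m))) stop("non-finite values in expression matrix")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Filter to expressed, variable genes
#'
#' Keeps genes whose across-sample median is at least `min_median` and whose
#' across-sample SD is strictly greater than `min_sd`. The strict inequality
#' guarantees that no constant gene (sigma = 0) survives into z-scoring.
#' The surviving genes define the "expressed" universe used by regulator
#' enrichment and composite scoring.
#'
#' @param m Genes x samples matrix (log2 scale).
#' @param min_median Minimum median expression (log2 units).
#' @param min_sd SD must exceed this (log2 units).
#' @return List with `matrix` (row subset, original order) and `report`
#'   (n_genes_in, n_genes_kept, thresholds).
#' @export
filter_expressed <- function(m, min_median = 1.0, min_sd = 0.0) {
  if (min_median < 0 || min_sd < 0) stop("thresholds must be >= 0")
  med <- apply(m, 1L, stats::median)
  sds <- apply(m, 1L, stats::sd)
  keep <- med >= min_median & sds > min_sd
  if (!any(keep)) stop("filter removed all genes (min_median=", min_median,
                       ", min_sd=", min_sd, ")")
  list(matrix = m[keep, , drop = FALSE],
       report = list(n_genes_in = nrow(m), n_genes_kept = sum(keep),
                     min_median = min_median, min_sd = min_sd))
}

#' Remove latent expression factors by PCA residualization
#'
#' A simplified factor adjustment to reduce the dependence structure among
#' genes before multiple testing: the matrix is centered on group x timepoint
#' cell means (so condition signal is protected), the top-k principal
#' components of the residual are removed, and the cell means are added back.
#' `k = 0` is the identity.
#'
#' @param m Genes x samples matrix.
#' @param design Validated cohort design covering the columns of `m`.
#' @param k Number of latent factors to remove; must be < number of samples.
#' @return Adjusted matrix, same shape and dimnames.
#' @export
remove_latent_factors <- function(m, design, k) {
  if (k >= ncol(m)) stop("k must be smaller than the number of samples")
  if (k == 0L) return(m)
  cond <- paste(design$group, design$timepoint)[match(colnames(m), design$sample_id)]
  if (anyNA(cond)) stop("samples missing from design: ",
                        paste(colnames(m)[is.na(cond)], collapse = ", "))
  cell_means <- vapply(split(seq_len(ncol(m)), cond),
                       function(j) rowMeans(m[, j, drop = FALSE]),
                       numeric(nrow(m)))
  fitted <- cell_means[, cond, drop = FALSE]
  resid <- m - fitted
  sv <- svd(resid, nu = k, nv = k)
  low_rank <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  out <- m - low_rank
  dimnames(out) <- dimnames(m)
  out
}
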