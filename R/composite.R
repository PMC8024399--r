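#' Standardize expression to z-scores over a cohort
#'
#' Per gene, `z = (x - mu) / sigma`, where `mu` and `sigma` are the mean and
#' the population standard deviation (divisor n, not n-1) over the
#' standardization cohort — all analyzed samples by default, so baseline and
#' post-surgery scores live on one scale.
#'
#' @param m Genes x samples matrix (filtered so every gene varies).
#' @param cohort Sample IDs defining the standardization population
#'   (default: all columns of `m`).
#' @return List of class `zscore_matrix`: `z` (genes x cohort), `mu`,
#'   `sigma` (per gene), `gene_ids`, `sample_ids`.
#' @export
zscore_matrix <- function(m, cohort = colnames(m)) {
  if (!all(cohort %in% colnames(m)))
    stop("cohort samples missing from matrix: ",
         paste(setdiff(cohort, colnames(m)), collapse = ", "))
  x <- m[, cohort, drop = FALSE]
  n <- ncol(x)
  mu <- rowMeans(x)
  sigma <- sqrt(rowSums((x - mu)^2) / n)      # population SD
  if (any(sigma == 0))
    stop("zero-variance gene(s) reached z-scoring (filtering bug): ",
         paste(utils::head(rownames(x)[sigma == 0], 3L), collapse = ", "))
  structure(list(z = (x - mu) / sigma, mu = mu, sigma = sigma,
                 gene_ids = rownames(x), sample_ids = cohort),
            class = "zscore_matrix")
}

#' Composite z-score biomarkers per sample and regulator
#'
#' The pathway biomarker: for each sample, the composite z-score of a
#' transcription factor is the unweighted mean of the z-scores of its target
#' genes, restricted to targets expressed in the data set. Over the
#' standardization cohort every composite has mean zero by construction.
#'
#' @param z A [zscore_matrix()].
#' @param sets Gene set collection (regulator -> targets).
#' @param expressed Expressed-gene universe; targets outside it are dropped
#'   (default: all genes in `z`).
#' @return Data frame: sample_id, regulator, score, n_targets_used.
#' @export
composite_scores <- function(z, sets, expressed = z$gene_ids) {
  stopifnot(inherits(z, "zscore_matrix"))
  if (!length(sets)) stop("empty gene set collection")
  usable <- lapply(sets, function(g) intersect(intersect(g, expressed), z$gene_ids))
  empty <- names(sets)[!vapply(usable, length, 1L)]
  if (length(empty))
    stop("regulator(s) with no expressed target: ", paste(empty, collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    g <- usable[[nm]]
    data.frame(sample_id = z$sample_ids,
               regulator = nm,
               score = colMeans(z$z[g, , drop = FALSE]),
               n_targets_used = length(g),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
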