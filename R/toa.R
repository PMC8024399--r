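#' Cell-type diagnosticity scores from a reference transcriptome
#'
#' For each gene, its expression in one cell type relative to its average
#' across cell types: `score(g, c) = ref(g, c) - mean_c' ref(g, c')`. Rows
#' sum to zero by construction; a large positive score marks a gene
#' preponderantly expressed by that cell type.
#'
#' @param reference Genes x cell-types matrix, log2 scale, >= 2 cell types.
#' @return Matrix of the same shape, row-centered.
#' @export
diagnosticity <- function(reference) {
  if (ncol(reference) < 2L) stop("need >= 2 cell types")
  reference - rowMeans(reference)
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so pipeline determinism is unaffected.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Transcript origin test for one cell type
#'
#' Tests whether a differential-expression gene list is overrepresented in
#' genes preponderantly expressed by one cell type: the observed statistic
#' is the mean diagnosticity of the DE genes for that cell type, and the
#' null is the distribution of means of `n_boot` equal-sized gene lists
#' drawn without replacement from all scored genes. One-sided
#' (overrepresentation only), with +1 smoothing so p is never 0, and ties
#' between null and observed counted with weight one half (so a list that
#' IS the whole scored universe sits at p near 0.5, not at 1):
#' `p = (1 + #(null > obs) + 0.5 #(null == obs)) / (n_boot + 1)`.
#'
#' @param de_genes Character vector of DE genes.
#' @param scores Diagnosticity matrix from [diagnosticity()].
#' @param cell_type Column of `scores` to test.
#' @param n_boot Number of bootstrap lists (>= 100).
#' @param seed Integer seed for the resampling (local RNG stream).
#' @return List of class `toa_result`: cell_type, mean_diagnosticity,
#'   boot_p, n_genes_scored, n_boot.
#' @export
toa_test <- function(de_genes, scores, cell_type, n_boot = 2000L, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (!cell_type %in% colnames(scores)) stop("unknown cell type: ", cell_type)
  hit <- intersect(unique(de_genes), rownames(scores))
  if (!length(hit)) stop("DE list does not intersect the scored genes")
  v <- scores[, cell_type]
  observed <- mean(v[hit])
  k <- length(hit)
  null_means <- .with_seed(seed, function()
    vapply(seq_len(n_boot), function(i) mean(v[sample.int(length(v), k)]), 0))
  n_ge <- sum(null_means > observed) + 0.5 * sum(null_means == observed)
  structure(list(cell_type = cell_type, mean_diagnosticity = observed,
                 boot_p = (1 + n_ge) / (n_boot + 1),
                 n_genes_scored = k, n_boot = as.integer(n_boot)),
            class = "toa_result")
}

#' Transcript origin profile over all cell types, up and down lists
#'
#' Runs [toa_test()] separately for the up- and down-regulated gene lists
#' against every cell type of the reference, and BH-adjusts the bootstrap
#' p-values across the whole table. Empty direction lists are skipped and
#' recorded in the `skipped` attribute.
#'
#' @param de_up,de_down Character vectors of up-/down-regulated DE genes.
#' @param scores Diagnosticity matrix.
#' @param n_boot Bootstrap lists per test.
#' @param seed Base seed; each (direction, cell type) test gets a distinct
#'   deterministic sub-seed.
#' @return Data frame: direction, cell_type, mean_diagnosticity, boot_p,
#'   boot_fdr, n_genes_scored, n_boot.
#' @export
toa_profile <- function(de_up, de_down, scores, n_boot = 2000L, seed = 1L) {
  lists <- list(up = unique(de_up), down = unique(de_down))
  skipped <- names(lists)[!vapply(lists, length, 1L)]
  lists <- lists[vapply(lists, length, 1L) > 0L]
  if (!length(lists)) stop("both direction lists are empty")
  rows <- list()
  i <- 0L
  for (dir in names(lists)) {
    for (ct in colnames(scores)) {
      i <- i + 1L
      r <- toa_test(lists[[dir]], scores, ct, n_boot = n_boot, seed = seed + i)
      rows[[i]] <- data.frame(direction = dir, cell_type = ct,
                              mean_diagnosticity = r$mean_diagnosticity,
                              boot_p = r$boot_p,
                              n_genes_scored = r$n_genes_scored,
                              n_boot = r$n_boot, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$boot_fdr <- bh_adjust(out$boot_p)
  out <- out[, c("direction", "cell_type", "mean_diagnosticity", "boot_p",
                 "boot_fdr", "n_genes_scored", "n_boot")]
  attr(out, "skipped") <- skipped
  out
}
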