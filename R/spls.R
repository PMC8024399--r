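#' Sparse partial least squares regression for gene selection
#'
#' Selects the genes most associated with a continuous response (here the
#' MADRS depression score) by sparse PLS in regression mode. Per component,
#' the X-loading is the soft-thresholded, renormalized covariance `X'y` on
#' standardized data, with the threshold set by order statistic so exactly
#' `keep_x` loadings are nonzero; X is deflated by its own scores between
#' components, y is not deflated. Ties at the threshold are broken by gene
#' ID (lexicographic), and the sign is fixed so the largest-magnitude
#' loading is positive, making the fit deterministic across backends.
#'
#' @param m Genes x samples matrix.
#' @param y Numeric response, one value per sample (non-constant).
#' @param keep_x Number of genes retained per component.
#' @param n_components Number of sPLS components (default 1: the intended
#'   use is selection, not prediction).
#' @return List of class `spls_fit`: `loadings` (genes x components, unit
#'   Euclidean norm per component), `selected` (data frame gene / r /
#'   component, sorted by |r| descending, r = Pearson correlation with `y`),
#'   `keep_x`, `n_components`.
#' @export
fit_spls <- function(m, y, keep_x, n_components = 1L) {
  if (ncol(m) != length(y)) stop("length(y) must match the number of samples")
  if (keep_x <= 0L) stop("keep_x must be positive")
  keep_x <- min(as.integer(keep_x), nrow(m))
  if (stats::sd(y) == 0) stop("response has zero variance")
  gene_ids <- rownames(m)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(m)))

  n <- ncol(m)
  X <- t(m)                                  # samples x genes
  X <- scale(X)                              # zero mean, unit variance per gene
  if (any(!is.finite(X))) {
    const <- which(apply(t(m), 2L, stats::sd) == 0)
    stop("constant gene(s) cannot be standardized: ",
         paste(gene_ids[const[seq_len(min(3L, length(const)))]], collapse = ", "))
  }
  yz <- as.vector(scale(y))

  loadings <- matrix(0, nrow(m), n_components, dimnames = list(gene_ids, NULL))
  for (h in seq_len(n_components)) {
    cv <- as.vector(crossprod(X, yz)) / (n - 1)
    ord <- order(-abs(cv), gene_ids)
    kept <- ord[seq_len(keep_x)]
    lambda <- if (keep_x < length(cv)) abs(cv[ord[keep_x + 1L]]) else 0
    w <- numeric(length(cv))
    w[kept] <- sign(cv[kept]) * (abs(cv[kept]) - lambda)
    # exact ties at the threshold soft-threshold to zero; keep the kept genes
    # in the support with a weight below any untied kept gene
    zero_kept <- kept[w[kept] == 0]
    if (length(zero_kept)) {
      eps <- if (any(w[kept] != 0)) min(abs(w[kept][w[kept] != 0])) * 1e-6 else 1
      w[zero_kept] <- sign(cv[zero_kept] + (cv[zero_kept] == 0)) * eps
    }
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    loadings[, h] <- w
    scores <- as.vector(X %*% w)
    p <- as.vector(crossprod(X, scores)) / sum(scores^2)
    X <- X - tcrossprod(scores, p)           # regression-mode deflation
  }

  sel_idx <- which(rowSums(loadings != 0) > 0)
  first_comp <- apply(loadings[sel_idx, , drop = FALSE] != 0, 1L, which.max)
  r <- apply(m[sel_idx, , drop = FALSE], 1L, stats::cor, y = y)
  selected <- data.frame(gene = gene_ids[sel_idx], r = r,
                         component = as.integer(first_comp),
                         stringsAsFactors = FALSE)
  selected <- selected[order(-abs(selected$r), selected$gene), ]
  rownames(selected) <- NULL
  structure(list(loadings = loadings, selected = selected,
                 keep_x = keep_x, n_components = as.integer(n_components)),
            class = "spls_fit")
}

#' Split sPLS-selected genes by a correlation cutoff
#'
#' Retains the selected genes whose absolute Pearson correlation with the
#' response exceeds `r_min`, split into positively and negatively correlated
#' lists ("highly correlated" genes in the selection stage).
#'
#' @param fit An [fit_spls()] result.
#' @param r_min Correlation magnitude cutoff (default 0.5).
#' @return List with `up` and `down` character vectors (may be empty).
#' @export
threshold_by_r <- function(fit, r_min = 0.5) {
  stopifnot(inherits(fit, "spls_fit"))
  s <- fit$selected[abs(fit$selected$r) > r_min, , drop = FALSE]
  list(up = s$gene[s$r > 0], down = s$gene[s$r < 0])
}
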