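#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure: sort p ascending, set
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, and map back to the input
#' order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return FDR-adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Vectorized Welch two-sample t over matrix rows. Rows with zero pooled
# spread are degenerate: t = 0, p = 1 (flagged).
.welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- pmin(2 * stats::pt(-abs(t), df), 1)
  p[degenerate] <- 1
  list(log2fc = m1 - m2, t = t, df = df, p = p, degenerate = degenerate)
}

# Moments estimator of an inverse-chisquare variance prior from the
# distribution of log sample variances; returns prior df d0 and scale s0^2.
# Used by the moderated mode to shrink gene-wise variances.
.fit_var_prior <- function(s2, df) {
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) return(list(d0 = Inf, s02 = exp(ebar)))
  # invert trigamma(d0/2) = excess by Newton on x = d0/2
  x <- 0.5 + 1 / excess
  for (i in 1:50) {
    delta <- trigamma(x) * (1 - trigamma(x) / excess) / psigamma(x, 2L)
    x <- x + delta
    if (abs(delta) < 1e-10 * x) break
  }
  d0 <- 2 * x
  s02 <- exp(ebar + digamma(x) - log(x))
  list(d0 = d0, s02 = s02)
}

.de_table <- function(gene, log2fc, t, df, p, degenerate) {
  fdr <- bh_adjust(p)
  direction <- ifelse(log2fc > 0, "up",
                      ifelse(log2fc < 0, "down", ifelse(t > 0, "up", "down")))
  data.frame(gene = gene, log2fc = log2fc, t_stat = t, df = df, p = p,
             fdr = fdr, direction = direction, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unpaired differential expression between groups
#'
#' Per-gene two-sample test of one group against another at a fixed
#' timepoint, BH-adjusted over all tested genes. The default is the Welch
#' unequal-variance t; `method = "moderated"` pools per-gene equal-variance
#' estimates toward an inverse-chisquare prior fitted by moments from the
#' log sample variances, adding the prior df to the residual df.
#'
#' @param m Genes x samples matrix.
#' @param design Validated cohort design.
#' @param contrast Length-2 character, groups compared as first minus second
#'   (default `c("MDD", "nonMDD")`).
#' @param timepoint Timepoint at which to compare (default "baseline").
#' @param method "welch" (default) or "moderated".
#' @return Data frame with gene, log2fc, t_stat, df, p, fdr, direction,
#'   degenerate; attribute `method` records the test used.
#' @export
unpaired_de <- function(m, design, contrast = c("MDD", "nonMDD"),
                        timepoint = "baseline",
                        method = c("welch", "moderated")) {
  method <- match.arg(method)
  stopifnot(length(contrast) == 2L)
  s1 <- design$sample_id[design$group == contrast[1L] & design$timepoint == timepoint]
  s2 <- design$sample_id[design$group == contrast[2L] & design$timepoint == timepoint]
  s1 <- intersect(s1, colnames(m)); s2 <- intersect(s2, colnames(m))
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each group needs >= 2 samples (", contrast[1L], ": ", length(s1),
         ", ", contrast[2L], ": ", length(s2), ")")
  x1 <- m[, s1, drop = FALSE]; x2 <- m[, s2, drop = FALSE]
  if (method == "welch") {
    w <- .welch_rows(x1, x2)
    out <- .de_table(rownames(m), w$log2fc, w$t, w$df, w$p, w$degenerate)
  } else {
    n1 <- length(s1); n2 <- length(s2); df <- n1 + n2 - 2
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    s2p <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / df
    prior <- .fit_var_prior(s2p, df)
    s2t <- if (is.finite(prior$d0)) (prior$d0 * prior$s02 + df * s2p) / (prior$d0 + df)
           else rep(prior$s02, length(s2p))
    dft <- df + min(prior$d0, 1e6)
    tt <- (m1 - m2) / sqrt(s2t * (1 / n1 + 1 / n2))
    degenerate <- s2t == 0
    tt[degenerate] <- 0
    p <- pmin(2 * stats::pt(-abs(tt), dft), 1)
    p[degenerate] <- 1
    out <- .de_table(rownames(m), m1 - m2, tt, rep(dft, length(tt)), p, degenerate)
  }
  attr(out, "method") <- method
  attr(out, "n_per_group") <- c(length(s1), length(s2))
  out
}

#' Paired differential expression (post vs baseline) within a group
#'
#' One-sample t-test on within-patient post-minus-baseline differences,
#' restricted to complete pairs; patients lost to follow-up are excluded and
#' counted in the `n_excluded` attribute. Genes with all differences equal
#' to zero are degenerate (t = 0, p = 1, flagged).
#'
#' @param m Genes x samples matrix.
#' @param design Validated cohort design.
#' @param group Group in which to test ("MDD" or "nonMDD").
#' @param method "welch" (ordinary one-sample t) or "moderated" (variance
#'   of the differences shrunk toward a moments-fitted prior).
#' @return Data frame as [unpaired_de()], log2fc = mean(post - baseline);
#'   attributes `n_pairs`, `n_excluded`.
#' @export
paired_de <- function(m, design, group = "MDD",
                      method = c("welch", "moderated")) {
  method <- match.arg(method)
  d <- design[design$group == group, , drop = FALSE]
  base <- d[d$timepoint == "baseline", ]
  post <- d[d$timepoint == "post", ]
  paired_pat <- intersect(base$patient_id, post$patient_id)
  paired_pat <- paired_pat[
    base$sample_id[match(paired_pat, base$patient_id)] %in% colnames(m) &
    post$sample_id[match(paired_pat, post$patient_id)] %in% colnames(m)]
  n_excluded <- length(unique(d$patient_id)) - length(paired_pat)
  if (length(paired_pat) < 2L) stop("need >= 2 complete pairs in group ", group)
  diffs <- m[, post$sample_id[match(paired_pat, post$patient_id)], drop = FALSE] -
           m[, base$sample_id[match(paired_pat, base$patient_id)], drop = FALSE]
  n <- ncol(diffs)
  md <- rowMeans(diffs)
  vd <- rowSums((diffs - md)^2) / (n - 1)
  if (method == "welch") {
    t <- md / sqrt(vd / n)
    df <- rep(n - 1, nrow(diffs))
  } else {
    prior <- .fit_var_prior(vd, n - 1)
    vt <- if (is.finite(prior$d0)) (prior$d0 * prior$s02 + (n - 1) * vd) / (prior$d0 + n - 1)
          else rep(prior$s02, length(vd))
    t <- md / sqrt(vt / n)
    df <- rep(n - 1 + min(prior$d0, 1e6), nrow(diffs))
  }
  degenerate <- vd == 0 & md == 0            # post = pre for every pair
  t[degenerate] <- 0
  p <- pmin(2 * stats::pt(-abs(t), df), 1)
  p[degenerate] <- 1
  out <- .de_table(rownames(m), md, t, df, p, degenerate)
  attr(out, "method") <- method
  attr(out, "n_pairs") <- length(paired_pat)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Differentially expressed genes at an FDR threshold
#' @param de A [unpaired_de()] / [paired_de()] result.
#' @param fdr FDR cutoff (default 0.05).
#' @return Character vector of gene IDs with `fdr <=` the cutoff.
#' @export
de_genes <- function(de, fdr = 0.05) de$gene[de$fdr <= fdr]
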