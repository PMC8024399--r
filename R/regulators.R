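#' Hypergeometric overlap test between a DE list and a regulator target set
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a differential-expression gene list and a regulator's
#' target set, both restricted to the expressed-gene universe:
#' `P(X >= k)` for `X ~ Hypergeometric(N = |universe|,
#' K = |targets in universe|, n = |DE list|)`.
#'
#' @param de_genes Character vector, subset of `universe`.
#' @param targets Character vector of target genes (intersected with the
#'   universe first).
#' @param universe Character vector of expressed genes (background).
#' @return List: `n_overlap`, `n_targets_in_universe`, `p` (in (0, 1]), and
#'   `flag` ("no_targets_in_universe" when the intersection is empty).
#' @export
overlap_test <- function(de_genes, targets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_genes <- unique(de_genes)
  if (!length(de_genes)) stop("empty DE list")
  if (!all(de_genes %in% universe)) stop("DE genes must be a subset of the universe")
  targets <- intersect(unique(targets), universe)
  k <- length(intersect(de_genes, targets))
  K <- length(targets)
  if (K == 0L)
    return(list(n_overlap = 0L, n_targets_in_universe = 0L, p = 1,
                flag = "no_targets_in_universe"))
  p <- stats::phyper(k - 1L, K, length(universe) - K, length(de_genes),
                     lower.tail = FALSE)
  list(n_overlap = k, n_targets_in_universe = K, p = min(p, 1), flag = NA_character_)
}

#' Activation z-score of a regulator over a DE table
#'
#' Signed consistency statistic: over the DE genes that are directional
#' targets of the regulator, `z = (n_consistent - n_inconsistent) / sqrt(N)`,
#' where a target is consistent when its observed DE direction equals the
#' direction expected under regulator activation. Targets without a known
#' expected direction contribute nothing; with no overlapping directional
#' target the score is 0 (flagged).
#'
#' @param de_table DE result restricted to significant genes (columns `gene`,
#'   `direction`).
#' @param directions Named character vector, target gene -> expected
#'   direction ("up"/"down") under activation.
#' @return List: `z`, `n_directional` (overlapping directional targets),
#'   `flag` ("no_directional_overlap" when N = 0).
#' @export
activation_zscore <- function(de_table, directions) {
  if (length(directions) && !all(directions %in% c("up", "down")))
    stop("expected directions must be 'up' or 'down'")
  common <- intersect(de_table$gene, names(directions))
  if (!length(common))
    return(list(z = 0, n_directional = 0L, flag = "no_directional_overlap"))
  obs <- de_table$direction[match(common, de_table$gene)]
  consistent <- sum(obs == directions[common])
  n <- length(common)
  list(z = (consistent - (n - consistent)) / sqrt(n),
       n_directional = n, flag = NA_character_)
}

#' Score all regulators of a collection against one DE contrast
#'
#' Combines the hypergeometric overlap p-value with the signed activation
#' z-score per regulator, and BH-adjusts the overlap p-values across
#' regulators. The conventional raw cutoff for calling a regulator is
#' overlap p < 0.001; both raw p and BH FDR are reported.
#'
#' @param de_table Full DE result (all tested genes).
#' @param sets Gene set collection (named list; optional `directions`
#'   attribute as from [read_gmt()]).
#' @param universe Expressed-gene universe (background).
#' @param fdr DE significance cutoff defining the DE list (default 0.05).
#' @param contrast Label stored in the output (default "contrast").
#' @return Data frame, one row per regulator: regulator,
#'   n_targets_in_universe, n_overlap, overlap_p, overlap_fdr, activation_z,
#'   n_directional, contrast.
#' @export
score_regulators <- function(de_table, sets, universe, fdr = 0.05,
                             contrast = "contrast") {
  if (!length(sets)) stop("empty gene set collection")
  sig <- de_table[de_table$fdr <= fdr, , drop = FALSE]
  if (!nrow(sig)) stop("no DE genes at FDR <= ", fdr, " for contrast ", contrast)
  dirs <- attr(sets, "directions")
  rows <- lapply(names(sets), function(nm) {
    ov <- overlap_test(sig$gene, sets[[nm]], universe)
    az <- activation_zscore(sig, dirs[[nm]])
    data.frame(regulator = nm,
               n_targets_in_universe = ov$n_targets_in_universe,
               n_overlap = ov$n_overlap, overlap_p = ov$p,
               activation_z = az$z, n_directional = az$n_directional,
               contrast = contrast, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$overlap_fdr <- bh_adjust(out$overlap_p)
  out[, c("regulator", "n_targets_in_universe", "n_overlap", "overlap_p",
          "overlap_fdr", "activation_z", "n_directional", "contrast")]
}

#' Compare regulator activation across contrasts
#'
#' Builds the regulators x contrasts comparison table: activation z-scores
#' side by side with overlap p annotations, rows sorted by the maximum
#' absolute z across contrasts (the layout used to contrast pre/post changes
#' in depressed vs non-depressed patients).
#'
#' @param scores Named list of [score_regulators()] tables, one per contrast;
#'   names label the columns.
#' @return Data frame: regulator, one `z_<contrast>` and one `p_<contrast>`
#'   column per contrast, and `max_abs_z`; sorted by `max_abs_z` descending.
#' @export
compare_contrasts <- function(scores) {
  if (!length(scores) || any(!vapply(scores, nrow, 1L)))
    stop("need non-empty score tables")
  if (length(scores) < 2L) stop("need >= 2 contrasts to compare")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    names(scores) <- vapply(scores, function(s) s$contrast[1L], "")
  regs <- unique(unlist(lapply(scores, `[[`, "regulator")))
  universes_differ <- length(unique(vapply(scores, nrow, 1L))) > 1L
  out <- data.frame(regulator = regs, stringsAsFactors = FALSE)
  for (nm in names(scores)) {
    s <- scores[[nm]]
    i <- match(regs, s$regulator)
    out[[paste0("z_", nm)]] <- s$activation_z[i]
    out[[paste0("p_", nm)]] <- s$overlap_p[i]
  }
  zc <- grep("^z_", names(out))
  out$max_abs_z <- apply(abs(as.matrix(out[, zc, drop = FALSE])), 1L,
                         max, na.rm = TRUE)
  out <- out[order(-out$max_abs_z), , drop = FALSE]
  rownames(out) <- NULL
  if (universes_differ)
    attr(out, "warning") <- "regulator sets differ across contrasts; union used"
  out
}
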