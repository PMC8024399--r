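#' Default pipeline configuration
#'
#' Stage parameters for [run_pipeline()]; any subset can be overridden via
#' the `config` argument or a YAML file. Paths (`expression`, `design`,
#' `gmt`, `reference`) may be given to run on real data; when absent, a
#' synthetic cohort is generated from the `simulate` block.
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    paths = list(expression = NULL, design = NULL, gmt = NULL, reference = NULL),
    simulate = list(),                      # overrides for simulation_config()
    preprocess = list(quantile = TRUE, min_median = 1.0, min_sd = 0.0, k_factors = 0L),
    spls = list(keep_x = 2000L, n_components = 1L, r_min = 0.5),
    de = list(fdr = 0.05, method = "welch"),
    toa = list(n_boot = 2000L),
    composite = list(cohort = "all"),       # or "baseline-only"
    evaluate = list(covariates = c("sex", "age", "bmi"))
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full biomarker pipeline
#'
#' Executes the whole workflow in order: data loading (or cohort
#' simulation), preprocessing (quantile normalization, expression filter,
#' optional latent-factor removal), sPLS gene selection against MADRS,
#' differential expression for the three contrasts (MDD vs non-MDD at
#' baseline; post vs baseline within each group), upstream-regulator
#' scoring with a cross-contrast comparison, transcript origin analysis of
#' the baseline contrast, composite z-score biomarkers, and the
#' ANOVA/regression evaluation. Every output TSV carries a `#` header with
#' package version, seed, and a configuration digest; a `manifest.tsv`
#' records per-stage row counts. Deterministic under a fixed seed.
#'
#' @param config Path to a YAML file or a nested list overriding
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created; pass NULL to skip writing).
#' @return Invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  provenance <- c(paste0("deptx ", as.character(utils::packageVersion("deptx")),
                         " seed=", cfg$seed),
                  paste0("config_digest=", .config_digest(cfg)))
  write_out <- function(tab, name) {
    if (!is.null(out_dir)) write_table(tab, file.path(out_dir, name), comment = provenance)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  simulated <- is.null(cfg$paths$expression)
  if (simulated) {
    sim_cfg <- do.call(simulation_config, c(cfg$simulate, list(seed = cfg$seed)))
    sim <- simulate_cohort(sim_cfg)
    expr <- sim$expression; design <- sim$design; sets <- sim$gene_sets
    ref <- simulate_reference(sim_cfg)$reference
  } else {
    for (p in c("expression", "design", "gmt"))
      if (is.null(cfg$paths[[p]])) stop("config missing path: ", p)
    expr <- read_expression(cfg$paths$expression)
    design <- read_design(cfg$paths$design)
    sets <- read_gmt(cfg$paths$gmt)
    ref <- if (!is.null(cfg$paths$reference)) read_expression(cfg$paths$reference) else NULL
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  pp <- run_stage("preprocess", function() {
    x <- if (isTRUE(cfg$preprocess$quantile)) quantile_normalize(expr) else expr
    if (cfg$preprocess$k_factors > 0L)
      x <- remove_latent_factors(x, design, cfg$preprocess$k_factors)
    filter_expressed(x, cfg$preprocess$min_median, cfg$preprocess$min_sd)
  })
  expr_f <- pp$matrix
  universe <- rownames(expr_f)
  write_out(as.data.frame(pp$report), "preprocess_report.tsv")

  base_ids <- design$sample_id[design$timepoint == "baseline"]
  sel <- run_stage("spls", function() {
    y <- design$madrs[match(base_ids, design$sample_id)]
    fit <- fit_spls(expr_f[, base_ids, drop = FALSE], y,
                    keep_x = min(cfg$spls$keep_x, nrow(expr_f)),
                    n_components = cfg$spls$n_components)
    list(fit = fit, split = threshold_by_r(fit, cfg$spls$r_min))
  })
  write_out(sel$fit$selected, "spls_selected.tsv")

  de <- run_stage("diffexpr", function() list(
    baseline = unpaired_de(expr_f, design, method = cfg$de$method),
    paired_mdd = paired_de(expr_f, design, "MDD", method = cfg$de$method),
    paired_nonmdd = paired_de(expr_f, design, "nonMDD", method = cfg$de$method)))
  for (nm in names(de)) write_out(de[[nm]][order(de[[nm]]$p), ], paste0("de_", nm, ".tsv"))

  reg <- run_stage("regulators", function() {
    tabs <- lapply(names(de), function(nm)
      tryCatch(score_regulators(de[[nm]], sets, universe, fdr = cfg$de$fdr, contrast = nm),
               error = function(e) NULL))
    names(tabs) <- names(de)
    tabs <- tabs[!vapply(tabs, is.null, TRUE)]
    if (length(tabs) >= 2L) list(tables = tabs, comparison = compare_contrasts(tabs))
    else list(tables = tabs, comparison = NULL)
  })
  if (!is.null(reg$comparison)) write_out(reg$comparison, "regulator_comparison.tsv")

  toa_res <- run_stage("toa", function() {
    if (is.null(ref)) return(NULL)
    sig <- de$baseline[de$baseline$fdr <= cfg$de$fdr, ]
    up <- sig$gene[sig$direction == "up"]; down <- sig$gene[sig$direction == "down"]
    if (!length(up) && !length(down)) return(NULL)
    toa_profile(up, down, diagnosticity(ref[intersect(rownames(ref), universe), , drop = FALSE]),
                n_boot = cfg$toa$n_boot, seed = cfg$seed)
  })
  if (!is.null(toa_res)) write_out(toa_res, "toa_profile.tsv")

  comp <- run_stage("composite", function() {
    cohort <- if (identical(cfg$composite$cohort, "baseline-only")) base_ids
              else colnames(expr_f)
    composite_scores(zscore_matrix(expr_f, cohort), sets, universe)
  })
  write_out(comp, "composite_scores.tsv")

  eval_res <- run_stage("evaluate", function() {
    regs <- unique(comp$regulator)
    covs <- intersect(cfg$evaluate$covariates, names(design))
    list(anova = lapply(stats::setNames(regs, regs), function(r)
           two_way_anova(comp, design, r)),
         crude = lapply(stats::setNames(regs, regs), function(r)
           regress_madrs(comp, design, r)),
         adjusted = lapply(stats::setNames(regs, regs), function(r)
           regress_madrs(comp, design, r, covariates = covs)),
         delta = lapply(stats::setNames(regs, regs), function(r)
           delta_regression(comp, design, r)),
         cohort = cohort_tests(design))
  })
  reg_row <- function(r, model) data.frame(
    regulator = r$predictor, model = model, beta_std = r$beta_std, F = r$F,
    df1 = r$df[1L], df2 = r$df[2L], p = r$p, n = r$n, stringsAsFactors = FALSE)
  regressions <- rbind(
    do.call(rbind, lapply(eval_res$crude, reg_row, model = "crude")),
    do.call(rbind, lapply(eval_res$adjusted, reg_row, model = "adjusted")),
    do.call(rbind, lapply(eval_res$delta, reg_row, model = "delta")))
  write_out(regressions, "regressions.tsv")
  write_out(do.call(rbind, lapply(names(eval_res$anova), function(r)
    cbind(regulator = r, eval_res$anova[[r]]$anova))), "anova.tsv")
  write_out(eval_res$cohort, "cohort_tests.tsv")

  manifest <- data.frame(
    stage = c("input", "preprocess", "spls", "de_baseline", "de_paired_mdd",
              "de_paired_nonmdd", "composite", "regressions"),
    rows = c(nrow(expr), nrow(expr_f), nrow(sel$fit$selected), nrow(de$baseline),
             nrow(de$paired_mdd), nrow(de$paired_nonmdd), nrow(comp), nrow(regressions)),
    stringsAsFactors = FALSE)
  write_out(manifest, "manifest.tsv")

  invisible(list(config = cfg, expression = expr_f, design = design,
                 preprocess = pp$report, spls = sel, de = de, regulators = reg,
                 toa = toa_res, composite = comp, evaluate = eval_res,
                 manifest = manifest))
}

# Stable short digest of the effective configuration for provenance headers
# (order-independent over names, no external hashing dependency).
.config_digest <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)), collapse = "\n")
  sum0 <- 0
  for (ch in utf8ToInt(s)) sum0 <- (sum0 * 31 + ch) %% 2147483647
  sprintf("%08x", sum0)
}
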