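.merge_scores <- function(scores, design, regulator) {
  if (!is.null(regulator))
    scores <- scores[scores$regulator == regulator, , drop = FALSE]
  if (!nrow(scores)) stop("no scores for regulator ", regulator)
  if (length(unique(scores$regulator)) > 1L)
    stop("scores span several regulators; pass `regulator`")
  d <- merge(scores, design, by = "sample_id")
  if (!nrow(d)) stop("scores and design share no samples")
  d
}

#' Two-way group x surgery ANOVA on composite scores
#'
#' Ordinary two-way ANOVA with interaction on
#' `score ~ group * timepoint`, using Type II sums of squares (the design is
#' unbalanced after dropout; switchable to Type III). Followed by the four
#' Bonferroni post hoc contrasts of interest: MDD vs non-MDD within each
#' timepoint and baseline vs post within each group, each a pooled-MSE t
#' contrast with p multiplied by 4 (capped at 1).
#'
#' @param scores [composite_scores()] table (one regulator, or pass
#'   `regulator`).
#' @param design Validated cohort design.
#' @param regulator Regulator to evaluate when `scores` holds several.
#' @param type Sum-of-squares type, 2 (default) or 3.
#' @return List of class `anova_result`: `anova` (effect, F, df1, df2, p)
#'   and `posthoc` (comparison, estimate, t, p_raw, p_bonferroni).
#' @export
two_way_anova <- function(scores, design, regulator = NULL, type = 2) {
  d <- .merge_scores(scores, design, regulator)
  cell <- table(d$group, d$timepoint)
  if (any(cell < 2L)) stop("every group x timepoint cell needs >= 2 observations")
  contr_bak <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(contr_bak))
  fit <- stats::lm(score ~ group * timepoint, data = d)
  an <- car::Anova(fit, type = type)
  eff <- c("group", "timepoint", "group:timepoint")
  lab <- c("group", "surgery", "interaction")
  df2 <- an["Residuals", "Df"]
  anova_tab <- data.frame(effect = lab,
                          F = an[eff, "F value"],
                          df1 = an[eff, "Df"], df2 = df2,
                          p = an[eff, "Pr(>F)"],
                          stringsAsFactors = FALSE, row.names = NULL)

  mse <- sum(stats::residuals(fit)^2) / df2
  cm <- function(g, tp) mean(d$score[d$group == g & d$timepoint == tp])
  cn <- function(g, tp) sum(d$group == g & d$timepoint == tp)
  contrast <- function(label, g1, t1, g2, t2) {
    est <- cm(g1, t1) - cm(g2, t2)
    se <- sqrt(mse * (1 / cn(g1, t1) + 1 / cn(g2, t2)))
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df2)
    data.frame(comparison = label, estimate = est, t = t, p_raw = p,
               p_bonferroni = min(1, 4 * p), stringsAsFactors = FALSE)
  }
  posthoc <- rbind(
    contrast("MDD vs nonMDD at baseline", "MDD", "baseline", "nonMDD", "baseline"),
    contrast("MDD vs nonMDD at post",     "MDD", "post",     "nonMDD", "post"),
    contrast("post vs baseline in MDD",   "MDD", "post",     "MDD", "baseline"),
    contrast("post vs baseline in nonMDD","nonMDD", "post",  "nonMDD", "baseline"))
  structure(list(anova = anova_tab, posthoc = posthoc), class = "anova_result")
}

.standardized_ols <- function(y, x, covars = NULL) {
  df <- data.frame(.y = as.vector(scale(y)), .x = as.vector(scale(x)))
  rhs <- ".x"
  if (!is.null(covars) && ncol(covars)) {
    for (nm in colnames(covars)) {
      v <- covars[[nm]]
      df[[nm]] <- if (is.numeric(v)) as.vector(scale(v)) else factor(v)
    }
    rhs <- paste(c(".x", colnames(covars)), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  sm <- summary(fit)
  beta <- stats::coef(fit)[".x"]
  t <- sm$coefficients[".x", "t value"]
  df2 <- fit$df.residual
  list(beta_std = unname(beta), F = t^2, df = c(1L, df2),
       p = sm$coefficients[".x", "Pr(>|t|)"], fit = fit)
}

#' Regress MADRS on a composite biomarker score
#'
#' Ordinary least squares of the MADRS depression score on the composite
#' z-score at baseline (crude), optionally adjusted for covariates such as
#' sex, age, and BMI. The reported `beta_std` is the coefficient on
#' standardized variables (equal to the Pearson correlation in the crude
#' model); `F` and `p` test the score's contribution.
#'
#' @param scores Composite score table.
#' @param design Validated cohort design.
#' @param regulator Regulator to evaluate when `scores` holds several.
#' @param covariates Character vector of design columns to adjust for
#'   (e.g., `c("sex", "age", "bmi")`).
#' @param timepoint Samples used (default "baseline").
#' @return List of class `regression_result`: predictor, beta_std, F,
#'   df (numerator, denominator), p, covariates, n.
#' @export
regress_madrs <- function(scores, design, regulator = NULL,
                          covariates = NULL, timepoint = "baseline") {
  d <- .merge_scores(scores, design, regulator)
  d <- d[d$timepoint == timepoint, , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 samples at timepoint ", timepoint)
  if (stats::sd(d$score) == 0) stop("composite score has zero variance")
  covars <- NULL
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, names(d))
    if (length(missing)) stop("covariate(s) absent from design: ",
                              paste(missing, collapse = ", "))
    if (anyNA(d[covariates])) stop("missing covariate values; not imputing")
    covars <- d[covariates]
  }
  r <- .standardized_ols(d$madrs, d$score, covars)
  structure(list(predictor = unique(scores$regulator), beta_std = r$beta_std,
                 F = r$F, df = r$df, p = r$p,
                 covariates = covariates %||% character(0), n = nrow(d)),
            class = "regression_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress the MADRS decrease on the composite-score decrease after surgery
#'
#' Over complete patient pairs, OLS of `MADRS_baseline - MADRS_post`
#' (positive = clinical improvement) on `score_baseline - score_post`:
#' does normalization of the pathway biomarker track remission?
#'
#' @param scores Composite score table covering both timepoints.
#' @param design Validated cohort design.
#' @param regulator Regulator to evaluate when `scores` holds several.
#' @return `regression_result` as [regress_madrs()]; `n` = number of pairs.
#' @export
delta_regression <- function(scores, design, regulator = NULL) {
  d <- .merge_scores(scores, design, regulator)
  base <- d[d$timepoint == "baseline", ]
  post <- d[d$timepoint == "post", ]
  pat <- intersect(base$patient_id, post$patient_id)
  if (length(pat) < 3L) stop("need >= 3 complete pairs")
  i <- match(pat, base$patient_id); j <- match(pat, post$patient_id)
  d_score <- base$score[i] - post$score[j]
  d_madrs <- base$madrs[i] - post$madrs[j]
  if (stats::sd(d_score) == 0) stop("score differences have zero variance")
  r <- .standardized_ols(d_madrs, d_score)
  structure(list(predictor = unique(d$regulator), beta_std = r$beta_std,
                 F = r$F, df = r$df, p = r$p, covariates = character(0),
                 n = length(pat)),
            class = "regression_result")
}

#' Cohort characteristics tests (group comparison table)
#'
#' The descriptive statistics layer: Welch t-tests comparing MDD and
#' non-MDD patients at baseline on continuous fields (MADRS, age, BMI),
#' Fisher exact tests on 2x2 counts (sex by group; MDD prevalence at
#' baseline vs post-surgery), a paired t-test on pre/post BMI, and the
#' baseline MDD prevalence as a percentage. Missing optional fields skip
#' their rows (recorded in the `skipped` attribute).
#'
#' @param design Validated cohort design.
#' @return Data frame: test, statistic, p, note.
#' @export
cohort_tests <- function(design) {
  base <- design[design$timepoint == "baseline", ]
  post <- design[design$timepoint == "post", ]
  if (!all(.group_levels %in% base$group)) stop("both groups required at baseline")
  rows <- list()
  skipped <- character(0)
  welch_row <- function(label, field, data = base) {
    if (is.null(data[[field]]) || anyNA(data[[field]])) { skipped <<- c(skipped, label); return(NULL) }
    w <- .welch_rows(matrix(data[[field]][data$group == "MDD"], 1L),
                     matrix(data[[field]][data$group == "nonMDD"], 1L))
    data.frame(test = label, statistic = w$t, p = w$p,
               note = "Welch t, MDD vs nonMDD", stringsAsFactors = FALSE)
  }
  rows$madrs <- welch_row("madrs_baseline", "madrs")
  rows$age <- welch_row("age_baseline", "age")
  rows$bmi <- welch_row("bmi_baseline", "bmi")
  rows$madrs_post <- if (nrow(post)) welch_row("madrs_post", "madrs", post) else NULL

  # MDD prevalence: percentage at baseline, and Fisher exact on the
  # baseline-vs-post 2x2 of MDD counts (depression remits after surgery)
  n_mdd_base <- sum(base$group == "MDD")
  prev <- 100 * n_mdd_base / nrow(base)
  rows$prev <- data.frame(test = "mdd_prevalence_baseline_pct", statistic = prev,
                          p = NA_real_, note = paste0(n_mdd_base, "/", nrow(base)),
                          stringsAsFactors = FALSE)
  if (nrow(post)) {
    post_mdd <- sum(post$madrs >= 15)        # still clinically depressed post-surgery
    tab <- matrix(c(n_mdd_base, nrow(base) - n_mdd_base,
                    post_mdd, nrow(post) - post_mdd), 2L)
    ft <- stats::fisher.test(tab)
    rows$fisher_prev <- data.frame(test = "mdd_prevalence_fisher",
                                   statistic = unname(ft$estimate), p = ft$p.value,
                                   note = paste0("baseline ", n_mdd_base, "/", nrow(base),
                                                 " vs post ", post_mdd, "/", nrow(post)),
                                   stringsAsFactors = FALSE)
  }
  if (!is.null(base$sex) && !anyNA(base$sex)) {
    tab <- table(factor(base$sex), base$group)
    if (nrow(tab) == 2L) {
      ft <- stats::fisher.test(tab)
      rows$sex <- data.frame(test = "sex_by_group_fisher", statistic = unname(ft$estimate),
                             p = ft$p.value, note = "Fisher exact",
                             stringsAsFactors = FALSE)
    }
  } else skipped <- c(skipped, "sex_by_group_fisher")
  if (!is.null(design$bmi) && !anyNA(design$bmi) && nrow(post) >= 2L) {
    pat <- intersect(base$patient_id, post$patient_id)
    dif <- base$bmi[match(pat, base$patient_id)] - post$bmi[match(pat, post$patient_id)]
    n <- length(dif)
    sdd <- stats::sd(dif)
    t <- if (sdd == 0) { if (mean(dif) == 0) 0 else Inf * sign(mean(dif)) }
         else mean(dif) / (sdd / sqrt(n))
    p <- if (sdd == 0 && mean(dif) == 0) 1 else min(2 * stats::pt(-abs(t), n - 1), 1)
    rows$bmi_paired <- data.frame(test = "bmi_pre_post_paired", statistic = t,
                                  p = p, note = paste0(n, " pairs"),
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Fisher exact test on a printed 2x2 count table
#'
#' Convenience wrapper for testing a change in a binary prevalence between
#' two timepoints from the four printed counts, two-sided by the standard
#' convention (summing probabilities of tables at most as probable as the
#' observed one).
#'
#' @param a,b First condition counts (e.g., MDD / non-MDD at baseline).
#' @param c,d Second condition counts (e.g., MDD / non-MDD post-surgery).
#' @return List: `p` (two-sided), `odds_ratio`.
#' @export
prevalence_fisher <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, b, c, d), 2L))
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}
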