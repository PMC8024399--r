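cell_design <- function(cells) {
  # cells: named list like list(MDD.baseline = c(...), ...) of score values
  rows <- lapply(names(cells), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    n <- length(cells[[nm]])
    data.frame(patient_id = paste0(nm, seq_len(n)), group = parts[1],
               timepoint = parts[2], madrs = 10, score = cells[[nm]],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  # post rows need baseline partners: give posts their own baseline stubs
  post <- d[d$timepoint == "post", ]
  if (nrow(post)) {
    stubs <- transform(post, timepoint = "baseline", score = NA)
    d <- rbind(d, stubs[!paste(stubs$patient_id, "baseline") %in%
                          paste(d$patient_id, d$timepoint), ])
  }
  design <- validate_design(d[, c("patient_id", "group", "timepoint", "madrs")])
  sc <- d$score[match(paste(design$patient_id, design$timepoint),
                      paste(d$patient_id, d$timepoint))]
  scores <- data.frame(sample_id = design$sample_id[!is.na(sc)],
                       regulator = "TP53", score = sc[!is.na(sc)],
                       n_targets_used = 5L, stringsAsFactors = FALSE)
  list(scores = scores, design = design)
}

test_that("the balanced 2x2 fixture yields the hand-computed interaction F", {
  f <- cell_design(list(MDD.baseline = c(0, 2), MDD.post = c(1, 3),
                        nonMDD.baseline = c(2, 4), nonMDD.post = c(7, 9)))
  res <- two_way_anova(f$scores, f$design, "TP53")
  int <- res$anova[res$anova$effect == "interaction", ]
  expect_equal(int$F, 4, tolerance = 1e-9)      # SSint = 8, MSE = 2
  expect_equal(c(int$df1, int$df2), c(1, 4))
})

test_that("equal cell means give a null interaction", {
  f <- cell_design(list(MDD.baseline = c(1, 3), MDD.post = c(0, 4),
                        nonMDD.baseline = c(2, 2), nonMDD.post = c(1, 3)))
  res <- two_way_anova(f$scores, f$design, "TP53")
  expect_equal(res$anova$F[res$anova$effect == "interaction"], 0, tolerance = 1e-9)
})

test_that("balanced ANOVA agrees with brute-force sums of squares", {
  set.seed(40)
  for (rep in 1:5) {
    vals <- lapply(1:4, function(i) rnorm(4, mean = i))
    names(vals) <- c("MDD.baseline", "MDD.post", "nonMDD.baseline", "nonMDD.post")
    f <- cell_design(vals)
    res <- two_way_anova(f$scores, f$design, "TP53")$anova
    # brute force on the balanced layout
    y <- f$scores$score
    g <- f$design$group[match(f$scores$sample_id, f$design$sample_id)]
    tp <- f$design$timepoint[match(f$scores$sample_id, f$design$sample_id)]
    cm <- tapply(y, list(g, tp), mean)
    gm <- mean(y)
    n <- 4
    ss_g <- 2 * n * sum((rowMeans(cm) - gm)^2)
    ss_t <- 2 * n * sum((colMeans(cm) - gm)^2)
    ss_int <- n * sum((sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + gm)^2)
    ss_e <- sum((y - cm[cbind(as.character(g), as.character(tp))])^2)
    mse <- ss_e / 12
    expect_equal(res$F, c(ss_g, ss_t, ss_int) / mse, tolerance = 1e-9)
  }
})

test_that("post hoc contrasts are the four of interest, Bonferroni-capped", {
  f <- cell_design(list(MDD.baseline = c(0, 2, 1), MDD.post = c(1, 3, 2),
                        nonMDD.baseline = c(2, 4, 3), nonMDD.post = c(7, 9, 8)))
  res <- two_way_anova(f$scores, f$design, "TP53")
  expect_equal(nrow(res$posthoc), 4)
  expect_true(all(res$posthoc$p_bonferroni >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_bonferroni <= 1))
  expect_equal(res$posthoc$p_bonferroni,
               pmin(1, 4 * res$posthoc$p_raw))
})

test_that("an empty cell is an error", {
  f <- cell_design(list(MDD.baseline = c(0, 2), MDD.post = c(1, 3),
                        nonMDD.baseline = c(2, 4), nonMDD.post = c(7, 9)))
  scores <- f$scores[!grepl("nonMDD.post", f$scores$sample_id), ]
  expect_error(two_way_anova(scores, f$design, "TP53"), "cell")
})

baseline_fixture <- function(score, madrs, ...) {
  n <- length(score)
  design <- validate_design(data.frame(
    patient_id = sprintf("P%02d", 1:n), group = rep(c("MDD", "nonMDD"), length.out = n),
    timepoint = "baseline", madrs = madrs, ..., stringsAsFactors = FALSE))
  scores <- data.frame(sample_id = design$sample_id, regulator = "TP53",
                       score = score, n_targets_used = 3L, stringsAsFactors = FALSE)
  list(scores = scores, design = design)
}

test_that("simple regression reproduces the closed-form beta and F", {
  f <- baseline_fixture(score = c(1, 2, 3, 4), madrs = c(1, 2, 3, 5))
  res <- regress_madrs(f$scores, f$design, "TP53")
  expect_equal(res$beta_std, 0.982708, tolerance = 1e-5)
  expect_equal(res$F, res$beta_std^2 * 2 / (1 - res$beta_std^2), tolerance = 1e-6)
  expect_equal(res$df, c(1L, 2L))
})

test_that("beta_std equals the Pearson correlation and F equals t squared", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    sc <- rnorm(n); md <- abs(2 * sc + rnorm(n) + 10)
    f <- baseline_fixture(sc, md)
    res <- regress_madrs(f$scores, f$design, "TP53")
    expect_equal(res$beta_std, cor(sc, md), tolerance = 1e-9)
    tt <- summary(lm(scale(md) ~ scale(sc)))$coefficients[2, "t value"]
    expect_equal(res$F, tt^2, tolerance = 1e-9)
    expect_lte(abs(res$beta_std), 1)
  }
})

test_that("covariates orthogonal to score and MADRS barely move beta", {
  set.seed(42)
  n <- 40
  sc <- rnorm(n)
  md <- abs(1.5 * sc + rnorm(n) + 8)
  covar <- residuals(lm(rnorm(n) ~ sc + md))     # orthogonal by construction
  f <- baseline_fixture(sc, md, age = covar + 40)
  crude <- regress_madrs(f$scores, f$design, "TP53")
  adj <- regress_madrs(f$scores, f$design, "TP53", covariates = "age")
  expect_lt(abs(adj$beta_std - crude$beta_std), 0.02)
  expect_identical(adj$covariates, "age")
})

test_that("regression input validation", {
  f <- baseline_fixture(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_error(regress_madrs(f$scores, f$design, "TP53"), "zero variance")
  f2 <- baseline_fixture(rnorm(5), 1:5)
  expect_error(regress_madrs(f2$scores, f2$design, "TP53", covariates = "bmi"),
               "absent")
})

paired_scores <- function(d_score, d_madrs, seed = 1) {
  set.seed(seed)
  n <- length(d_score)
  pat <- sprintf("P%02d", 1:n)
  base_madrs <- abs(rnorm(n, 15, 4))
  design <- validate_design(data.frame(
    patient_id = rep(pat, 2), group = "MDD",
    timepoint = rep(c("baseline", "post"), each = n),
    madrs = c(base_madrs, base_madrs - d_madrs), stringsAsFactors = FALSE))
  base_score <- rnorm(n)
  scores <- data.frame(sample_id = design$sample_id, regulator = "TP53",
                       score = c(base_score, base_score - d_score),
                       n_targets_used = 3L, stringsAsFactors = FALSE)
  list(scores = scores, design = design)
}

test_that("collinear pre/post deltas give beta_std = 1", {
  d <- c(1, 3, 2, 5, 4)
  f <- paired_scores(d_score = d, d_madrs = 2 * d)
  res <- suppressWarnings(delta_regression(f$scores, f$design, "TP53"))
  expect_equal(res$beta_std, 1, tolerance = 1e-9)
  expect_equal(res$n, 5)
})

test_that("delta regression needs at least three pairs", {
  f <- paired_scores(d_score = c(1, 2), d_madrs = c(2, 4))
  expect_error(delta_regression(f$scores, f$design, "TP53"), ">= 3")
})

test_that("cohort tests compute prevalence, Fisher, and group t-tests", {
  # Table-1-like design: 15/18 at baseline, 11/13 followed up
  pat <- sprintf("P%02d", 1:33)
  grp <- rep(c("MDD", "nonMDD"), c(15, 18))
  followed <- c(pat[1:11], pat[16:28])
  set.seed(43)
  d <- validate_design(data.frame(
    patient_id = c(pat, followed),
    group = c(grp, grp[match(followed, pat)]),
    timepoint = rep(c("baseline", "post"), c(33, 24)),
    madrs = c(abs(rnorm(15, 19, 4)), abs(rnorm(18, 6.5, 3.5)), rep(2, 24)),
    age = rep(40, 57), sex = rep(c("F", "M"), length.out = 57),
    bmi = c(rep(42, 33), rep(31, 24)), stringsAsFactors = FALSE))
  tab <- cohort_tests(d)
  prev <- tab$statistic[tab$test == "mdd_prevalence_baseline_pct"]
  expect_equal(prev, 100 * 15 / 33, tolerance = 1e-9)
  expect_true("mdd_prevalence_fisher" %in% tab$test)
  expect_lt(tab$p[tab$test == "mdd_prevalence_fisher"], 0.001)
  expect_true(all(c("madrs_baseline", "bmi_pre_post_paired") %in% tab$test))
  # identical groups on a continuous field: t = 0, p = 1
  expect_equal(tab$statistic[tab$test == "age_baseline"], 0)
  expect_equal(tab$p[tab$test == "age_baseline"], 1)
})

test_that("printed 2x2 prevalence counts give the exact Fisher p", {
  res <- prevalence_fisher(15, 18, 0, 24)
  expect_lt(res$p, 0.0006)
  expect_equal(res$p, fisher.test(matrix(c(15, 18, 0, 24), 2))$p.value)
})
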