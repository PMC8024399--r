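test_that("overlap p is the exact hypergeometric upper tail", {
  universe <- sprintf("g%02d", 1:20)
  targets <- universe[1:5]
  de <- universe[c(1, 2, 3, 10)]           # overlap 3 of 4
  res <- overlap_test(de, targets, universe)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)

  # zero overlap: the tail at zero is the whole distribution
  res0 <- overlap_test(universe[10:13], targets, universe)
  expect_equal(res0$p, 1)

  # targets disjoint from the universe: flagged, p = 1
  resd <- overlap_test(de, c("x1", "x2"), universe)
  expect_equal(resd$n_targets_in_universe, 0L)
  expect_equal(resd$p, 1)
  expect_identical(resd$flag, "no_targets_in_universe")

  expect_error(overlap_test(character(0), targets, universe), "empty DE")
  expect_error(overlap_test(de, targets, character(0)), "empty universe")
  expect_error(overlap_test("not_in_universe", targets, universe), "subset")
})

test_that("overlap p matches Fisher's exact upper tail on random tables", {
  set.seed(20)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    universe <- sprintf("u%03d", 1:N)
    targets <- sample(universe, sample(1:N, 1))
    de <- sample(universe, sample(1:N, 1))
    res <- overlap_test(de, targets, universe)
    tab <- matrix(c(res$n_overlap,
                    length(targets) - res$n_overlap,
                    length(de) - res$n_overlap,
                    N - length(targets) - length(de) + res$n_overlap), 2)
    ft <- fisher.test(tab, alternative = "greater")
    expect_equal(res$p, ft$p.value, tolerance = 1e-9)
  }
})

de_tab <- function(genes, directions) {
  data.frame(gene = genes, direction = directions, stringsAsFactors = FALSE)
}

test_that("activation z counts direction-consistent targets", {
  de <- de_tab(c("A", "B", "C", "D"), c("up", "up", "up", "up"))
  dirs <- c(A = "up", B = "up", C = "up", D = "up")
  expect_equal(activation_zscore(de, dirs)$z, 2)               # 4/sqrt(4)
  dirs["D"] <- "down"
  expect_equal(activation_zscore(de, dirs)$z, 1)               # (3-1)/2
  de2 <- de_tab(c("A", "B", "C", "D"), c("up", "up", "down", "down"))
  expect_equal(activation_zscore(de2, c(A = "up", B = "down", C = "up", D = "down"))$z, 0)

  none <- activation_zscore(de, c(X = "up"))
  expect_equal(none$z, 0)
  expect_identical(none$flag, "no_directional_overlap")
  expect_error(activation_zscore(de, c(A = "increased")), "'up' or 'down'")
})

test_that("activation z is antisymmetric under flipping expected directions", {
  set.seed(21)
  for (i in 1:20) {
    genes <- sprintf("g%02d", 1:12)
    de <- de_tab(genes, sample(c("up", "down"), 12, replace = TRUE))
    dirs <- setNames(sample(c("up", "down"), 8, replace = TRUE), sample(genes, 8))
    flipped <- setNames(ifelse(dirs == "up", "down", "up"), names(dirs))
    expect_equal(activation_zscore(de, dirs)$z, -activation_zscore(de, flipped)$z)
  }
})

test_that("regulator scoring combines overlap, direction, and BH across sets", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(TP53 = universe[1:8], NR3C1 = universe[9:16], RELA = universe[30:34])
  attr(sets, "directions") <- list(
    TP53 = setNames(rep("up", 8), sets$TP53),
    NR3C1 = setNames(rep("down", 8), sets$NR3C1),
    RELA = setNames(rep("up", 5), sets$RELA))
  de <- data.frame(gene = universe, direction = rep(c("up", "down"), 20),
                   fdr = c(rep(0.01, 10), rep(0.5, 30)), stringsAsFactors = FALSE)
  sc <- score_regulators(de, sets, universe, fdr = 0.05, contrast = "demo")
  expect_equal(nrow(sc), 3)
  expect_equal(sc$n_overlap[sc$regulator == "TP53"], 8L)
  expect_equal(sc$n_overlap[sc$regulator == "RELA"], 0L)
  expect_equal(sc$overlap_fdr, bh_adjust(sc$overlap_p))
  # TP53 targets alternate up/down but all expected up: 4 - 4 over sqrt(8)
  expect_equal(sc$activation_z[sc$regulator == "TP53"], 0)
})

test_that("contrast comparison sorts by max |z| and keeps per-contrast columns", {
  mk <- function(z1, z2, contrast) data.frame(
    regulator = c("TP53", "NR3C1"), n_targets_in_universe = 8L, n_overlap = 4L,
    overlap_p = c(0.001, 0.2), overlap_fdr = c(0.002, 0.2),
    activation_z = c(z1, z2), n_directional = 4L, contrast = contrast,
    stringsAsFactors = FALSE)
  # a regulator responding only in the MDD arm
  cmp <- compare_contrasts(list(paired_mdd = mk(2.8, 0.5, "paired_mdd"),
                                paired_nonmdd = mk(0.3, 0.2, "paired_nonmdd")))
  expect_identical(cmp$regulator[1], "TP53")
  expect_gt(abs(cmp$z_paired_mdd[1]), 2)
  expect_lt(abs(cmp$z_paired_nonmdd[1]), 1)
  expect_equal(cmp$max_abs_z[1], 2.8)

  one <- mk(1, 0.5, "a")[1, ]
  cmp1 <- compare_contrasts(list(a = one, b = transform(one, contrast = "b")))
  expect_equal(dim(cmp1), c(1L, 6L))
  expect_error(compare_contrasts(list()), "non-empty")
  expect_error(compare_contrasts(list(a = mk(1, 1, "a"))), ">= 2 contrasts")
})

test_that("a regulator coupled only in the MDD arm separates the paired contrasts", {
  # construct DE tables from the simulator: strong coupling means the paired
  # MDD contrast moves the targets down post-surgery (MADRS falls), while
  # the non-MDD arm barely changes
  sim <- simulate_cohort(quick_config(31, n_genes = 300, coupling_alpha = 2.5,
                                      noise_sd = 0.3))
  de_mdd <- paired_de(sim$expression, sim$design, "MDD")
  de_non <- paired_de(sim$expression, sim$design, "nonMDD")
  universe <- rownames(sim$expression)
  sc_mdd <- score_regulators(de_mdd, sim$gene_sets, universe, fdr = 0.2,
                             contrast = "paired_mdd")
  z_mdd <- sc_mdd$activation_z[sc_mdd$regulator == "TP53"]
  expect_gt(abs(z_mdd), 2)          # remission: targets move against activation
  sc_non <- tryCatch(
    score_regulators(de_non, sim$gene_sets, universe, fdr = 0.2,
                     contrast = "paired_nonmdd"),
    error = function(e) NULL)       # possibly no DE genes at all in this arm
  if (!is.null(sc_non)) {
    z_non <- sc_non$activation_z[sc_non$regulator == "TP53"]
    expect_gt(abs(z_mdd), abs(z_non))
  }
})
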