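#' Default MADRS distribution parameters by group and timepoint
#'
#' Group-level means and SDs (MADRS points) of the cohort the generator
#' emulates: depressed (MDD) and non-depressed obese patients before and
#' after bariatric surgery. Depression scores fall sharply after surgery in
#' the MDD group (remission).
#'
#' @return Data frame with columns `group`, `timepoint`, `mean`, `sd`.
#' @export
default_madrs_params <- function() {
  data.frame(
    group     = c("MDD", "nonMDD", "MDD", "nonMDD"),
    timepoint = c("baseline", "baseline", "post", "post"),
    mean      = c(19.00, 6.56, 6.36, 2.08),
    sd        = c(3.87, 3.59, 5.09, 3.29),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Parameters of the synthetic paired pre/post cohort. Defaults mirror the
#' emulated study: 33 patients (15 MDD / 18 non-MDD at baseline), 9 lost to
#' follow-up, MADRS distributions per group and timepoint, and three latent
#' transcription-factor activations (TP53, NR3C1, RELA) linearly coupled to
#' the cohort-standardized MADRS score.
#'
#' @param n_patients Number of patients at baseline.
#' @param frac_mdd Fraction of patients in the MDD group.
#' @param n_genes Total genes on the array.
#' @param n_regulators Number of latent regulators with target blocks.
#' @param targets_per_regulator Targets per regulator (disjoint blocks).
#' @param coupling_alpha Per-regulator coupling (z-units of latent activation
#'   per SD of MADRS); scalar is recycled.
#' @param noise_sd Residual SD of expression (log2 units).
#' @param b_range Range of the positive per-gene latent loading `b_g`
#'   (log2 units per latent unit), drawn uniformly.
#' @param patient_sd SD of patient-level per-gene baseline offsets
#'   (log2 units), shared across timepoints so pairing is informative.
#' @param madrs_params Data frame as [default_madrs_params()] (MADRS points;
#'   draws truncated at 0).
#' @param dropout_frac Fraction of patients lost at follow-up (applied
#'   per group, rounded).
#' @param n_cell_types Cell types in the synthetic reference transcriptome.
#' @param markers_per_type Marker genes per cell type (disjoint blocks).
#' @param marker_offset Log2 elevation of a marker in its own cell type.
#' @param mixture_on If TRUE, blend a small cell-type mixture signal into the
#'   bulk expression so marker genes carry cell-of-origin structure.
#' @param seed Integer seed; one seed drives all randomness, with per-stage
#'   sub-streams derived deterministically from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 33L, frac_mdd = 15 / 33,
                              n_genes = 2000L, n_regulators = 3L,
                              targets_per_regulator = 40L,
                              coupling_alpha = 1.5, noise_sd = 0.5,
                              b_range = c(0.3, 0.7), patient_sd = 0.3,
                              madrs_params = default_madrs_params(),
                              dropout_frac = 9 / 33,
                              n_cell_types = 5L, markers_per_type = 25L,
                              marker_offset = 3, mixture_on = FALSE,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), frac_mdd = frac_mdd,
              n_genes = as.integer(n_genes), n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              coupling_alpha = rep_len(coupling_alpha, n_regulators),
              noise_sd = noise_sd, b_range = b_range, patient_sd = patient_sd,
              madrs_params = madrs_params, dropout_frac = dropout_frac,
              n_cell_types = as.integer(n_cell_types),
              markers_per_type = as.integer(markers_per_type),
              marker_offset = marker_offset, mixture_on = isTRUE(mixture_on),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2L, cfg$n_genes >= 1L, cfg$n_regulators >= 1L)
  if (cfg$frac_mdd < 0 || cfg$frac_mdd > 1) stop("frac_mdd must be in [0, 1]")
  if (cfg$dropout_frac < 0 || cfg$dropout_frac > 1) stop("dropout_frac must be in [0, 1]")
  if (cfg$n_regulators * cfg$targets_per_regulator > cfg$n_genes)
    stop("n_regulators * targets_per_regulator exceeds n_genes")
  if (cfg$noise_sd <= 0 || cfg$patient_sd < 0) stop("noise_sd must be > 0")
  if (any(cfg$madrs_params$sd <= 0)) stop("MADRS SDs must be > 0")
  invisible(cfg)
}

# Normal draw truncated below at 0 via inverse-CDF (exact, no rejection loop,
# so the random-stream length is deterministic).
rtnorm0 <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

.regulator_names <- function(k) {
  base <- c("TP53", "NR3C1", "RELA")
  if (k <= 3L) base[seq_len(k)] else c(base, sprintf("REG%d", seq_len(k - 3L)))
}

#' Simulate a paired pre/post expression cohort with latent TF activation
#'
#' Generative model, per sample `i` and regulator `r`:
#' `a_r(i) = alpha_r * zMADRS(i) + N(0, 1)`, where `zMADRS` is the MADRS
#' score standardized over all simulated samples; expression of a target
#' gene `g` of `r` is `baseline_g(patient) + b_g * a_r(i) + N(0, noise_sd)`
#' with `b_g > 0`; non-target genes are baseline plus noise. MADRS is drawn
#' per group x timepoint from `madrs_params`, truncated at 0. Post-surgery
#' latents are re-drawn from the post-surgery MADRS, so clinical remission
#' propagates into the transcriptome by construction. Patients keep their
#' per-gene baseline offsets across timepoints, and a configurable fraction
#' drops out after baseline (post-surgery samples are removed patient-wise,
#' preserving pairing).
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression` (genes x samples log2 matrix), `design`
#'   (validated cohort design), `gene_sets` (regulator -> targets, all
#'   direction `"up"` since loadings are positive), and `truth` (latent
#'   activations `a`, loadings `b`, couplings, and target assignment) for
#'   parameter-recovery tests.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  n_mdd <- round(cfg$n_patients * cfg$frac_mdd)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  group <- rep(c("MDD", "nonMDD"), c(n_mdd, cfg$n_patients - n_mdd))

  # dropout stratified by group so follow-up loss is balanced
  drop <- character(0)
  for (g in unique(group)) {
    pg <- patients[group == g]
    k <- round(length(pg) * cfg$dropout_frac)
    if (k > 0L) drop <- c(drop, sample(pg, k))
  }
  keep_post <- setdiff(patients, drop)

  design <- rbind(
    data.frame(patient_id = patients, group = group, timepoint = "baseline",
               stringsAsFactors = FALSE),
    data.frame(patient_id = keep_post, group = group[match(keep_post, patients)],
               timepoint = "post", stringsAsFactors = FALSE)
  )
  n_samples <- nrow(design)

  mp <- cfg$madrs_params
  key <- paste(design$group, design$timepoint)
  idx <- match(key, paste(mp$group, mp$timepoint))
  if (anyNA(idx)) stop("madrs_params missing a group x timepoint combination")
  design$madrs <- rtnorm0(n_samples, mp$mean[idx], mp$sd[idx])
  design$age <- round(rtnorm0(cfg$n_patients, 38.5, 11.7))[match(design$patient_id, patients)]
  design$sex <- ifelse(stats::runif(cfg$n_patients) < 0.9, "F", "M")[match(design$patient_id, patients)]
  bmi_base <- rtnorm0(cfg$n_patients, 42.0, 5.1)
  bmi_post <- bmi_base - rtnorm0(cfg$n_patients, 10.9, 2.5)
  design$bmi <- ifelse(design$timepoint == "baseline",
                       bmi_base[match(design$patient_id, patients)],
                       bmi_post[match(design$patient_id, patients)])

  # latent activations coupled to cohort-standardized MADRS
  z_madrs <- as.vector(scale(design$madrs))
  a <- outer(z_madrs, cfg$coupling_alpha) +
    matrix(stats::rnorm(n_samples * cfg$n_regulators), n_samples, cfg$n_regulators)
  colnames(a) <- .regulator_names(cfg$n_regulators)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_tgt <- cfg$n_regulators * cfg$targets_per_regulator
  target_of <- rep(NA_integer_, cfg$n_genes)
  target_of[seq_len(n_tgt)] <- rep(seq_len(cfg$n_regulators), each = cfg$targets_per_regulator)

  mu_g <- stats::runif(cfg$n_genes, 6, 12)
  b <- rep(0, cfg$n_genes)
  b[seq_len(n_tgt)] <- stats::runif(n_tgt, cfg$b_range[1L], cfg$b_range[2L])

  pat_offset <- matrix(stats::rnorm(cfg$n_patients * cfg$n_genes, sd = cfg$patient_sd),
                       cfg$n_genes, cfg$n_patients, dimnames = list(genes, patients))

  x <- matrix(stats::rnorm(cfg$n_genes * n_samples, sd = cfg$noise_sd),
              cfg$n_genes, n_samples)
  x <- x + mu_g + pat_offset[, match(design$patient_id, patients)]
  for (r in seq_len(cfg$n_regulators)) {
    tg <- which(!is.na(target_of) & target_of == r)
    x[tg, ] <- x[tg, ] + b[tg] %o% a[, r]
  }

  if (cfg$mixture_on) {
    ref <- simulate_reference(cfg)
    # per-sample cell proportions (Dirichlet via normalized gammas); bulk
    # marker expression shifts with the proportion of its cell of origin
    p <- matrix(stats::rgamma(n_samples * cfg$n_cell_types, shape = 5), n_samples)
    p <- p / rowSums(p)
    common <- intersect(rownames(ref$reference), genes)
    cent <- ref$reference[common, , drop = FALSE] - rowMeans(ref$reference[common, , drop = FALSE])
    x[common, ] <- x[common, ] + cent %*% t(p)
  }

  design$sample_id <- paste(design$patient_id, design$timepoint, sep = ".")
  dimnames(x) <- list(genes, design$sample_id)
  rownames(a) <- design$sample_id

  reg_names <- .regulator_names(cfg$n_regulators)
  gene_sets <- lapply(seq_len(cfg$n_regulators), function(r)
    genes[which(!is.na(target_of) & target_of == r)])
  names(gene_sets) <- reg_names
  attr(gene_sets, "directions") <- lapply(gene_sets, function(g)
    stats::setNames(rep("up", length(g)), g))

  list(expression = x,
       design = validate_design(design),
       gene_sets = gene_sets,
       truth = list(a = a, b = stats::setNames(b, genes),
                    coupling_alpha = stats::setNames(cfg$coupling_alpha, reg_names),
                    target_of = stats::setNames(target_of, genes),
                    z_madrs = stats::setNames(z_madrs, design$sample_id)))
}

#' Simulate a cell-type reference transcriptome
#'
#' Each cell type receives a disjoint block of marker genes elevated by a
#' fixed log2 offset over a common baseline, emulating flow-sorted reference
#' transcriptomes used for transcript origin analysis.
#'
#' @param cfg A [simulation_config()] (`n_cell_types`, `markers_per_type`,
#'   `marker_offset`, `n_genes`, `seed` are used).
#' @return List with `reference` (genes x cell-types log2 matrix) and
#'   `markers` (named list of marker gene blocks per cell type).
#' @export
simulate_reference <- function(cfg) {
  if (cfg$n_cell_types < 2L) stop("need at least 2 cell types")
  if (cfg$markers_per_type < 1L) stop("markers_per_type must be >= 1")
  n_marked <- cfg$n_cell_types * cfg$markers_per_type
  if (n_marked > cfg$n_genes) stop("marker blocks exceed n_genes")
  set.seed(cfg$seed + 7919L)  # independent sub-stream from the cohort draw
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  cells <- sprintf("CT%d", seq_len(cfg$n_cell_types))
  base <- stats::runif(cfg$n_genes, 4, 8)
  ref <- matrix(base, cfg$n_genes, cfg$n_cell_types, dimnames = list(genes, cells))
  # marker blocks start after the regulator target region when possible, so
  # TOA fixtures do not collide with TF targets by default
  start <- min(cfg$n_genes - n_marked,
               cfg$n_regulators * cfg$targets_per_regulator)
  markers <- list()
  for (k in seq_len(cfg$n_cell_types)) {
    rows <- start + (k - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)
    ref[rows, k] <- ref[rows, k] + cfg$marker_offset
    markers[[cells[k]]] <- genes[rows]
  }
  list(reference = ref, markers = markers)
}
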