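# Shared fixture builders. All fixtures are generated in code; simulation
# sizes are scaled down from the cohort defaults where a test only needs the
# statistical structure, not the full array.

# A design frame from parallel vectors, validated.
toy_design <- function(patient, group, timepoint, madrs = 10, ...) {
  validate_design(data.frame(patient_id = patient, group = group,
                             timepoint = timepoint, madrs = madrs, ...,
                             stringsAsFactors = FALSE))
}

# One-gene expression matrix over given sample ids.
one_gene <- function(values, sample_ids, gene = "G1") {
  matrix(values, nrow = 1, dimnames = list(gene, sample_ids))
}

# Small, fast simulation config (keeps the study's design and MADRS
# parameters; shrinks the gene panel).
quick_config <- function(seed, n_genes = 200L, ...) {
  simulation_config(seed = seed, n_genes = n_genes, ...)
}

# Composite score of one regulator straight from a simulated cohort.
sim_composite <- function(sim, regulator = "TP53") {
  f <- filter_expressed(sim$expression, min_median = 0, min_sd = 0)
  composite_scores(zscore_matrix(f$matrix), sim$gene_sets[regulator])
}
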