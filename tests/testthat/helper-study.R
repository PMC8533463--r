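# Shared fixtures, built once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

# A 2-cohort study small enough for io/pipeline tests.
small_config <- function(seed = 1) {
  sim_config(
    n_cohorts = 2, n_tumor = 24, n_normal = 8,
    n_mrna = 60, n_lncrna = 20, n_pseudogene = 10, n_mirna = 40,
    n_planted_triplets_shared = 3, n_planted_triplets_private = 1,
    seed = seed
  )
}

get_small_study <- function() {
  if (is.null(.study_cache$small)) {
    .study_cache$small <- generate_study(small_config())
  }
  .study_cache$small
}

# The default desk-scale study (5 cohorts, 60 + 10 samples, 300 genes,
# 100 miRNAs) used by the recovery tests.
get_default_study <- function() {
  if (is.null(.study_cache$default)) {
    .study_cache$default <- generate_study(sim_config())
  }
  .study_cache$default
}

# A study with every planted signal switched off: the global-null condition
# for calibration tests. Sized so that the background interaction map yields
# a candidate-pair pool of roughly 200 sponge-mRNA pairs.
null_config <- function(seed = 1) {
  sim_config(
    n_lncrna = 20, n_pseudogene = 10, n_mrna = 60, n_mirna = 100,
    background_density = 0.035,
    n_planted_triplets_shared = 0, n_planted_triplets_private = 0,
    repression_strength = 0, de_logfc = 0, hazard_beta = 0,
    seed = seed
  )
}

get_null_study <- function() {
  if (is.null(.study_cache$null)) {
    .study_cache$null <- generate_study(null_config())
  }
  .study_cache$null
}

# Normalised, filtered log-CPM plus gene-level DE calls for one cohort.
prep_cohort <- function(study, label) {
  co <- study$cohorts[[label]]
  g <- filter_low_expressed(log_cpm(co$gene_counts, tmm_factors(co$gene_counts)))
  m <- filter_low_expressed(log_cpm(co$mirna_counts, tmm_factors(co$mirna_counts)))
  list(
    cohort = co,
    gene_logcpm = g,
    mirna_logcpm = m,
    de_genes = call_differential(moderated_t_test(g, co$samples), study$biotypes),
    de_mirnas = call_differential(moderated_t_test(m, co$samples), study$biotypes)
  )
}

# Per-cohort triplet networks for a whole study, cached by study name.
study_networks <- function(study, cache_key) {
  slot <- paste0("nets_", cache_key)
  if (is.null(.study_cache[[slot]])) {
    nets <- lapply(names(study$cohorts), function(lb) {
      prep <- prep_cohort(study, lb)
      tr <- suppressMessages(suppressWarnings(infer_network(
        prep$gene_logcpm, prep$mirna_logcpm, prep$cohort$samples,
        de = prep$de_genes, map = study$map,
        seed = cernet:::derive_seed(study$config$seed, lb)
      )))
      tr$cohort <- lb
      tr
    })
    names(nets) <- names(study$cohorts)
    .study_cache[[slot]] <- nets
  }
  .study_cache[[slot]]
}
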