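#' Configuration for a synthetic multi-cohort ceRNA study
#'
#' Collects every knob of the synthetic-study generator in one validated
#' object. The defaults describe the desk-scale study used throughout the
#' package tests: 5 cohorts of 60 tumor and 10 normal samples, 300 genes
#' (200 mRNA, 60 lncRNA, 40 pseudogene) and 100 miRNAs, with 10 sponge
#' triplets planted in every cohort and 5 planted in a single cohort each.
#'
#' @param n_cohorts Number of cohorts to simulate.
#' @param n_tumor,n_normal Samples per cohort in each condition. At least 4
#'   each so the per-feature linear model keeps residual degrees of freedom.
#' @param n_mrna,n_lncrna,n_pseudogene,n_mirna Feature counts per biotype.
#' @param n_planted_triplets_shared Sponge-mRNA-miRNA triplets planted in
#'   every cohort (each with its own sponge/target pair).
#' @param n_planted_triplets_private Triplets planted in exactly one cohort
#'   (assigned round-robin across cohorts).
#' @param repression_strength Dimensionless slope of the decrease in a
#'   target's log2 mean per unit of standardized abundance of each targeting
#'   miRNA. Shared repressors induce positive sponge-target correlation.
#' @param shared_mre_count Number of miRNAs co-targeting each planted pair.
#' @param nb_dispersion Negative-binomial dispersion of the counts
#'   (variance = mu + dispersion * mu^2).
#' @param de_logfc Planted tumor-vs-normal log2 fold change.
#' @param libsize_range Length-2 range of the log-uniform per-sample library
#'   size multipliers; forces nontrivial TMM factors.
#' @param hazard_beta Log-hazard slope per unit standardized expression of a
#'   planted prognostic feature.
#' @param censor_rate Expected fraction of censored follow-up times,
#'   strictly inside (0, 1).
#' @param background_density Probability that a background miRNA-target edge
#'   is present in the interaction map.
#' @param decoy_de_rate Fraction of non-planted features given a planted
#'   tumor shift (random direction) in each cohort.
#' @param silent_rate Fraction of non-planted features simulated at
#'   near-zero abundance so the low-expression filter has work to do.
#' @param seed Master RNG seed; every stage derives its own stream from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cohorts = 2, n_tumor = 10, n_normal = 5)
#' cfg$n_cohorts
sim_config <- function(n_cohorts = 5,
                       n_tumor = 60,
                       n_normal = 10,
                       n_mrna = 200,
                       n_lncrna = 60,
                       n_pseudogene = 40,
                       n_mirna = 100,
                       n_planted_triplets_shared = 10,
                       n_planted_triplets_private = 5,
                       repression_strength = 0.35,
                       shared_mre_count = 6,
                       nb_dispersion = 0.1,
                       de_logfc = 2,
                       libsize_range = c(0.5, 2),
                       hazard_beta = 1.2,
                       censor_rate = 0.3,
                       background_density = 0.05,
                       decoy_de_rate = 0.1,
                       silent_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal),
    n_mrna = as.integer(n_mrna),
    n_lncrna = as.integer(n_lncrna),
    n_pseudogene = as.integer(n_pseudogene),
    n_mirna = as.integer(n_mirna),
    n_planted_triplets_shared = as.integer(n_planted_triplets_shared),
    n_planted_triplets_private = as.integer(n_planted_triplets_private),
    repression_strength = repression_strength,
    shared_mre_count = as.integer(shared_mre_count),
    nb_dispersion = nb_dispersion,
    de_logfc = de_logfc,
    libsize_range = libsize_range,
    hazard_beta = hazard_beta,
    censor_rate = censor_rate,
    background_density = background_density,
    decoy_de_rate = decoy_de_rate,
    silent_rate = silent_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_cohorts", "n_mrna", "n_lncrna", "n_pseudogene", "n_mirna")
  for (f in pos) {
    if (cfg[[f]] < 1L) abort(paste0("invalid config: ", f, " must be strictly positive"))
  }
  if (cfg$n_tumor < 4L || cfg$n_normal < 4L) {
    abort("invalid config: need n_tumor >= 4 and n_normal >= 4 (residual df for the DE model)")
  }
  if (cfg$censor_rate <= 0 || cfg$censor_rate >= 1) {
    abort("invalid config: censor_rate must lie strictly in (0, 1)")
  }
  if (cfg$nb_dispersion <= 0) abort("invalid config: nb_dispersion must be > 0")
  if (cfg$repression_strength < 0) abort("invalid config: repression_strength must be >= 0")
  if (cfg$shared_mre_count < 1L) abort("invalid config: shared_mre_count must be >= 1")
  if (cfg$shared_mre_count > cfg$n_mirna) {
    abort("invalid config: shared_mre_count exceeds the number of miRNAs")
  }
  if (length(cfg$libsize_range) != 2L || any(cfg$libsize_range <= 0) ||
      cfg$libsize_range[1] > cfg$libsize_range[2]) {
    abort("invalid config: libsize_range must be an increasing positive pair")
  }
  if (cfg$background_density < 0 || cfg$background_density > 1) {
    abort("invalid config: background_density must lie in [0, 1]")
  }
  if (cfg$n_planted_triplets_shared < 0L || cfg$n_planted_triplets_private < 0L) {
    abort("invalid config: planted triplet counts must be >= 0")
  }
  n_planted <- cfg$n_planted_triplets_shared + cfg$n_planted_triplets_private
  if (2L * n_planted > cfg$n_lncrna + cfg$n_pseudogene) {
    abort("invalid config: not enough lncRNAs/pseudogenes to host the planted sponges")
  }
  if (n_planted > cfg$n_mrna) {
    abort("invalid config: not enough mRNAs to host the planted targets")
  }
  invisible(cfg)
}

cohort_label <- function(i) sprintf("cohort%02d", as.integer(i))

feature_ids <- function(cfg) {
  list(
    mrna = sprintf("ENSGM%04d", seq_len(cfg$n_mrna)),
    lncrna = sprintf("ENSGL%04d", seq_len(cfg$n_lncrna)),
    pseudogene = sprintf("ENSGP%04d", seq_len(cfg$n_pseudogene)),
    mirna = sprintf("hsa-miR-%03d", seq_len(cfg$n_mirna))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cohorts, "cohorts,",
      x$n_tumor, "tumor /", x$n_normal, "normal samples,",
      x$n_mrna + x$n_lncrna + x$n_pseudogene, "genes,",
      x$n_mirna, "miRNAs\n")
  cat("  planted triplets:", x$n_planted_triplets_shared, "shared,",
      x$n_planted_triplets_private, "private; seed", x$seed, "\n")
  invisible(x)
}
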