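#' Simulate one cohort of a synthetic ceRNA study
#'
#' Draws gene and miRNA count matrices, a sample sheet and a clinical table
#' for a single cohort. The generative model follows the assumptions the
#' downstream inference exploits: per-sample miRNA abundances are log-normal;
#' each gene's log2 mean decreases linearly (slope `repression_strength`)
#' in the standardized abundance of every miRNA that targets it, so a sponge
#' and an mRNA wired to the same miRNAs pick up a shared latent component and
#' a positive pairwise correlation; planted differential features receive a
#' `de_logfc` shift in tumors; counts are negative-binomial with log-uniform
#' per-sample library-size multipliers; tumor survival times are exponential
#' with a proportional-hazards log-rate `hazard_beta` per standardized unit of
#' each planted prognostic feature, with independent exponential censoring
#' tuned to `censor_rate`.
#'
#' @param config A [sim_config()].
#' @param map The study [interaction_map()] built by [build_interaction_map()]
#'   (its `planted` attribute drives the DE and prognostic planting).
#' @param cohort_index 1-based cohort number, at most `config$n_cohorts`.
#' @return List with elements `label`, `gene_counts`, `mirna_counts` (wide
#'   tibbles, `feature_id` + one column per sample), `samples`
#'   (`sample_id`, `group`), `clinical` (`sample_id`, `time`, `event`, tumor
#'   samples only) and `truth` (cohort-level planted DE / prognostic tibbles).
#' @export
simulate_cohort <- function(config, map, cohort_index) {
  validate_sim_config(config)
  if (cohort_index < 1L || cohort_index > config$n_cohorts) {
    abort("cohort_index must lie in 1..n_cohorts")
  }
  label <- cohort_label(cohort_index)
  set.seed(derive_seed(config$seed, paste0("cohort-", label)))

  ids <- feature_ids(config)
  gene_ids <- c(ids$mrna, ids$lncrna, ids$pseudogene)
  n_genes <- length(gene_ids)
  n_s <- config$n_tumor + config$n_normal
  sample_ids <- c(sprintf("%s-T%03d", label, seq_len(config$n_tumor)),
                  sprintf("%s-N%03d", label, seq_len(config$n_normal)))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  is_tumor <- group == "tumor"

  planted <- attr(map, "planted") %||%
    tibble(sponge_id = character(), mrna_id = character(),
           mirnas = list(), mirna_id = character(),
           shared = logical(), cohort = character())
  active <- planted$shared | planted$cohort %in% label
  planted_genes_here <- unique(c(planted$sponge_id[active], planted$mrna_id[active]))
  planted_genes_all <- unique(c(planted$sponge_id, planted$mrna_id))
  planted_mirnas_all <- unique(unlist(planted$mirnas))

  # --- planted DE assignment -------------------------------------------------
  decoy_genes <- setdiff(gene_ids, planted_genes_all)
  n_decoy_de <- round(config$decoy_de_rate * length(decoy_genes))
  decoy_de_genes <- sample(decoy_genes, n_decoy_de)
  decoy_gene_dir <- sample(c(1, -1), n_decoy_de, replace = TRUE)

  free_mirnas <- setdiff(ids$mirna, planted_mirnas_all)
  n_decoy_de_mir <- round(config$decoy_de_rate * length(free_mirnas))
  decoy_de_mirnas <- sample(free_mirnas, n_decoy_de_mir)
  decoy_mir_dir <- sample(c(1, -1), n_decoy_de_mir, replace = TRUE)

  de_shift <- setNames(numeric(n_genes), gene_ids)
  de_shift[planted_genes_here] <- config$de_logfc
  de_shift[decoy_de_genes] <- decoy_gene_dir * config$de_logfc
  mir_shift <- setNames(numeric(config$n_mirna), ids$mirna)
  mir_shift[decoy_de_mirnas] <- decoy_mir_dir * config$de_logfc

  # --- silent (near-zero) features exercise the low-expression filter --------
  silent_pool <- setdiff(decoy_genes, decoy_de_genes)
  silent_genes <- sample(silent_pool, round(config$silent_rate * length(silent_pool)))
  silent_mir_pool <- setdiff(free_mirnas, decoy_de_mirnas)
  silent_mirnas <- sample(silent_mir_pool,
                          round(config$silent_rate * length(silent_mir_pool)))

  # --- miRNA layer -----------------------------------------------------------
  mir_mu <- rnorm(config$n_mirna, mean = 12, sd = 1)
  names(mir_mu) <- ids$mirna
  mir_mu[silent_mirnas] <- -1
  z <- matrix(rnorm(config$n_mirna * n_s), nrow = config$n_mirna) + mir_mu
  z <- z + outer(mir_shift, ifelse(is_tumor, 1, 0))
  rownames(z) <- ids$mirna
  z_std <- t(scale(t(z)))  # standardized latent abundance per miRNA

  # --- gene layer ------------------------------------------------------------
  base <- rnorm(n_genes, mean = 10, sd = 1.5)
  names(base) <- gene_ids
  base[silent_genes] <- -1

  logmean <- matrix(base, nrow = n_genes, ncol = n_s)
  rownames(logmean) <- gene_ids
  if (config$repression_strength > 0) {
    # indicator matrix genes x miRNAs of the targeting relation
    tgt <- matrix(0, nrow = n_genes, ncol = config$n_mirna,
                  dimnames = list(gene_ids, ids$mirna))
    in_genes <- map$edges$target_id %in% gene_ids
    tgt[cbind(map$edges$target_id[in_genes], map$edges$mirna_id[in_genes])] <- 1
    logmean <- logmean - config$repression_strength * (tgt %*% z_std)
  }
  logmean <- logmean + outer(de_shift, ifelse(is_tumor, 1, 0))

  # --- counts ----------------------------------------------------------------
  lib_gene <- exp(runif(n_s, log(config$libsize_range[1]), log(config$libsize_range[2])))
  lib_mir <- exp(runif(n_s, log(config$libsize_range[1]), log(config$libsize_range[2])))
  size <- 1 / config$nb_dispersion
  gene_counts <- matrix(
    rnbinom(n_genes * n_s, size = size,
            mu = 2^logmean * rep(lib_gene, each = n_genes)),
    nrow = n_genes, dimnames = list(gene_ids, sample_ids)
  )
  mirna_counts <- matrix(
    rnbinom(config$n_mirna * n_s, size = size,
            mu = 2^z * rep(lib_mir, each = config$n_mirna)),
    nrow = config$n_mirna, dimnames = list(ids$mirna, sample_ids)
  )

  # --- survival --------------------------------------------------------------
  prognostic <- prognostic_plan(planted)
  base_rate <- log(2) / 730  # median follow-up ~2 years in arbitrary day units
  risk <- numeric(config$n_tumor)
  if (nrow(prognostic) > 0L && config$hazard_beta != 0) {
    for (k in seq_len(nrow(prognostic))) {
      f <- prognostic$feature_id[k]
      x <- if (f %in% gene_ids) logmean[f, is_tumor] else z[f, is_tumor]
      risk <- risk + config$hazard_beta * prognostic$sign[k] *
        as.numeric(scale(x))
    }
  }
  event_time <- rexp(config$n_tumor, rate = base_rate * exp(risk))
  censor_rate <- base_rate * config$censor_rate / (1 - config$censor_rate)
  censor_time <- rexp(config$n_tumor, rate = censor_rate)
  clinical <- tibble(
    sample_id = sample_ids[is_tumor],
    time = round(pmin(event_time, censor_time), 2),
    event = as.integer(event_time <= censor_time)
  )

  truth <- cohort_truth(label, planted, active, decoy_de_genes, decoy_gene_dir,
                        decoy_de_mirnas, decoy_mir_dir, prognostic, config)

  list(
    label = label,
    gene_counts = matrix_to_expr(gene_counts),
    mirna_counts = matrix_to_expr(mirna_counts),
    samples = tibble(sample_id = sample_ids, group = group),
    clinical = clinical,
    truth = truth
  )
}

# Which planted features carry a survival signal: the mRNAs of the first three
# shared triplets (alternating risk direction) and the anchor miRNAs of the
# first two, identically in every cohort.
prognostic_plan <- function(planted) {
  shared <- planted[planted$shared, , drop = FALSE]
  genes <- head(shared$mrna_id, 3L)
  mirs <- head(shared$mirna_id, 2L)
  feats <- c(genes, mirs)
  if (length(feats) == 0L) {
    return(tibble(feature_id = character(), sign = numeric()))
  }
  tibble(feature_id = feats,
         sign = rep_len(c(1, -1), length(feats)))
}

cohort_truth <- function(label, planted, active, decoy_de_genes, decoy_gene_dir,
                         decoy_de_mirnas, decoy_mir_dir, prognostic, config) {
  de <- dplyr::bind_rows(
    tibble(feature_id = unique(c(planted$sponge_id[active], planted$mrna_id[active])),
           direction = "up"),
    tibble(feature_id = decoy_de_genes,
           direction = ifelse(decoy_gene_dir > 0, "up", "down")),
    tibble(feature_id = decoy_de_mirnas,
           direction = ifelse(decoy_mir_dir > 0, "up", "down"))
  )
  de$cohort <- label
  prog <- tibble(
    feature_id = prognostic$feature_id,
    hazard_direction = ifelse(prognostic$sign > 0, "up", "down"),
    cohort = label
  )
  if (config$hazard_beta == 0) prog <- prog[0, ]
  if (config$de_logfc == 0) de <- de[0, ]
  list(planted_de = de[c("cohort", "feature_id", "direction")],
       planted_prognostic = prog[c("cohort", "feature_id", "hazard_direction")])
}

#' Generate a complete synthetic multi-cohort study
#'
#' Builds one shared interaction map, simulates every cohort, assembles the
#' planted ground truth and writes a gene-set collection containing one set
#' enriched for the planted-triplet mRNAs plus random decoy sets.
#'
#' @param config A [sim_config()].
#' @return Object of class `cerna_study`: list with `config`, `map`,
#'   `cohorts` (named list, see [simulate_cohort()]), `biotypes`,
#'   `gene_sets` (tibble `set_id`, `description`, `members` list-column) and
#'   `truth` (list of tibbles `planted_triplets`, `planted_de`,
#'   `planted_prognostic`).
#' @export
#' @examples
#' study <- generate_study(sim_config(n_cohorts = 2, n_tumor = 8, n_normal = 4,
#'                                    n_mrna = 40, n_lncrna = 12,
#'                                    n_pseudogene = 8, n_mirna = 30,
#'                                    n_planted_triplets_shared = 2,
#'                                    n_planted_triplets_private = 1))
#' names(study$cohorts)
generate_study <- function(config) {
  validate_sim_config(config)
  map <- build_interaction_map(config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(i) {
    simulate_cohort(config, map, i)
  })
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "label")

  ids <- feature_ids(config)
  biotypes <- tibble(
    feature_id = c(ids$mrna, ids$lncrna, ids$pseudogene, ids$mirna),
    biotype = rep(c("mRNA", "lncRNA", "pseudogene", "miRNA"),
                  c(config$n_mrna, config$n_lncrna, config$n_pseudogene,
                    config$n_mirna))
  )

  planted <- attr(map, "planted")
  all_cohorts <- paste(cohort_label(seq_len(config$n_cohorts)), collapse = "|")
  planted_triplets <- tibble(
    sponge_id = planted$sponge_id,
    mrna_id = planted$mrna_id,
    mirna_id = planted$mirna_id,
    key = paste(planted$sponge_id, planted$mrna_id, planted$mirna_id, sep = "_"),
    shared = planted$shared,
    cohort_set = ifelse(planted$shared, all_cohorts, planted$cohort)
  )

  truth <- list(
    planted_triplets = planted_triplets,
    planted_de = dplyr::bind_rows(lapply(cohorts, function(co) co$truth$planted_de)),
    planted_prognostic = dplyr::bind_rows(
      lapply(cohorts, function(co) co$truth$planted_prognostic))
  )

  gene_sets <- make_gene_sets(config, planted_triplets, ids)
  for (i in seq_along(cohorts)) cohorts[[i]]$truth <- NULL

  structure(
    list(config = config, map = map, cohorts = cohorts, biotypes = biotypes,
         gene_sets = gene_sets, truth = truth),
    class = "cerna_study"
  )
}

# One set holding the planted shared-triplet mRNAs plus decoy sets of random
# mRNAs, mimicking a pathway collection in GMT layout.
make_gene_sets <- function(config, planted_triplets, ids) {
  set.seed(derive_seed(config$seed, "gene-sets"))
  planted_members <- sort(unique(planted_triplets$mrna_id[planted_triplets$shared]))
  decoys <- lapply(seq_len(10L), function(k) {
    sort(sample(ids$mrna, min(15L, config$n_mrna)))
  })
  sets <- tibble(
    set_id = c(if (length(planted_members) > 0) "PLANTED-TARGETS",
               sprintf("DECOY-%02d", seq_len(10L))),
    description = c(if (length(planted_members) > 0) "mRNAs of planted shared triplets",
                    rep("random decoy set", 10L)),
    members = c(if (length(planted_members) > 0) list(planted_members), decoys)
  )
  sets
}

#' @export
print.cerna_study <- function(x, ...) {
  cat("<cerna_study>", length(x$cohorts), "cohorts;",
      nrow(x$truth$planted_triplets), "planted triplets (",
      sum(x$truth$planted_triplets$shared), "shared )\n")
  invisible(x)
}
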