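#' Pipeline configuration
#'
#' Bundles the input/output locations and every stage threshold of the
#' end-to-end screen. Thresholds default to the study's canonical values:
#' differential expression at |logFC| > 1 and FDR < 0.01, hypergeometric
#' FDR < 0.05, Pearson r > 0.4, mscor adjusted p < 0.05, survival screen at
#' p < 0.05, and a one-way frequency equal to the number of cohorts.
#'
#' @param input_dir Study directory laid out as by [write_study()].
#' @param output_dir Where stage outputs are written (created if needed).
#' @param de_lfc,de_fdr Differential-expression gates.
#' @param min_logcpm,max_prop_below Low-expression filter settings.
#' @param hyper_fdr,pearson_min,mscor_alpha ceRNA-stage gates.
#' @param survival_alpha Logrank screen gate.
#' @param required_count One-way frequency for the shared network; `NULL`
#'   means all cohorts.
#' @param null_samples,cor_bin_width mscor null-calibration settings.
#' @param seed Master seed; each stage derives its own stream.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            de_lfc = 1, de_fdr = 0.01,
                            min_logcpm = 1, max_prop_below = 0.5,
                            hyper_fdr = 0.05, pearson_min = 0.4,
                            mscor_alpha = 0.05, survival_alpha = 0.05,
                            required_count = NULL,
                            null_samples = 1000, cor_bin_width = 0.1,
                            seed = 1L) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir,
    de_lfc = de_lfc, de_fdr = de_fdr,
    min_logcpm = min_logcpm, max_prop_below = max_prop_below,
    hyper_fdr = hyper_fdr, pearson_min = pearson_min,
    mscor_alpha = mscor_alpha, survival_alpha = survival_alpha,
    required_count = required_count,
    null_samples = null_samples, cor_bin_width = cor_bin_width,
    seed = as.integer(seed)
  )
  for (f in c("de_fdr", "hyper_fdr", "mscor_alpha", "survival_alpha")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      abort(paste0("invalid config: ", f, " must lie in (0, 1)"))
    }
  }
  if (cfg$pearson_min <= -1 || cfg$pearson_min >= 1) {
    abort("invalid config: pearson_min must lie in (-1, 1)")
  }
  if (cfg$de_lfc < 0) abort("invalid config: de_lfc must be >= 0")
  if (!is.null(cfg$required_count) && cfg$required_count < 1) {
    abort("invalid config: required_count must be >= 1")
  }
  if (!dir.exists(input_dir)) {
    abort(paste0("invalid config: input_dir does not exist: ", input_dir))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end shared-ceRNA screen
#'
#' Executes, in order: per-cohort TMM normalisation, log-CPM transformation,
#' low-expression filtering and moderated-t differential expression (genes
#' and miRNAs); per-cohort triplet inference; cross-cohort intersection via
#' the one-way frequency rule with Venn sharing counts; the median-split
#' logrank prognostic screen over shared-network features; and gene-set
#' over-representation of the shared-network mRNAs. Each stage writes its
#' table under `output_dir`, and a machine-readable `summary.json` plus a
#' `manifest.json` (configuration echo and per-stage row counts) conclude
#' the run. Fully deterministic given the input study and seed. On failure
#' the aborting stage is named and a `FAILED` marker is left in
#' `output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  study <- stage("read", read_study(config$input_dir))
  n_cohorts <- length(study$cohorts)
  required <- config$required_count %||% n_cohorts
  if (required > n_cohorts) {
    abort("invalid config: required_count exceeds the number of cohorts")
  }
  for (d in c("de", "networks", "shared", "survival", "enrichment")) {
    dir.create(file.path(out, d), showWarnings = FALSE)
  }

  log_stage <- function(...) inform(paste0("[cernet] ", ...))
  manifest_counts <- list()

  # --- differential expression ----------------------------------------------
  de_summaries <- list()
  cohort_data <- list()
  for (lb in names(study$cohorts)) {
    co <- study$cohorts[[lb]]
    dat <- stage(paste0("de/", lb), {
      g_lcpm <- filter_low_expressed(
        log_cpm(co$gene_counts, tmm_factors(co$gene_counts)),
        min_logcpm = config$min_logcpm, max_prop_below = config$max_prop_below)
      m_lcpm <- filter_low_expressed(
        log_cpm(co$mirna_counts, tmm_factors(co$mirna_counts)),
        min_logcpm = config$min_logcpm, max_prop_below = config$max_prop_below)
      de_g <- call_differential(moderated_t_test(g_lcpm, co$samples),
                                biotypes = study$biotypes,
                                lfc_threshold = config$de_lfc,
                                fdr_threshold = config$de_fdr)
      de_m <- call_differential(moderated_t_test(m_lcpm, co$samples),
                                biotypes = study$biotypes,
                                lfc_threshold = config$de_lfc,
                                fdr_threshold = config$de_fdr)
      readr::write_tsv(de_g, file.path(out, "de", paste0(lb, "_genes.tsv")))
      readr::write_tsv(de_m, file.path(out, "de", paste0(lb, "_mirnas.tsv")))
      list(gene_logcpm = g_lcpm, mirna_logcpm = m_lcpm,
           de = dplyr::bind_rows(de_g, de_m), samples = co$samples,
           clinical = co$clinical)
    })
    cohort_data[[lb]] <- dat
    cnt <- count_de_by_biotype(dat$de)
    cnt$cohort <- lb
    de_summaries[[lb]] <- cnt
    log_stage("DE ", lb, ": ", sum(dat$de$status != "ns"), " significant features")
    manifest_counts[[paste0("de/", lb)]] <- nrow(dat$de)
  }
  de_counts <- dplyr::bind_rows(de_summaries)[c("cohort", "biotype", "up", "down")]

  # --- per-cohort ceRNA networks --------------------------------------------
  networks <- list()
  for (lb in names(cohort_data)) {
    dat <- cohort_data[[lb]]
    trip <- stage(paste0("network/", lb), {
      tr <- infer_network(
        dat$gene_logcpm, dat$mirna_logcpm, dat$samples,
        de = dat$de[dat$de$biotype != "miRNA", ], map = study$map,
        hyper_fdr = config$hyper_fdr, pearson_min = config$pearson_min,
        mscor_alpha = config$mscor_alpha,
        null_samples = config$null_samples,
        cor_bin_width = config$cor_bin_width,
        seed = derive_seed(config$seed, paste0("null-", lb)))
      tr$cohort <- lb
      readr::write_tsv(tr, file.path(out, "networks", paste0(lb, "_triplets.tsv")))
      tr
    })
    networks[[lb]] <- trip
    log_stage("network ", lb, ": ", nrow(trip), " triplets")
    manifest_counts[[paste0("network/", lb)]] <- nrow(trip)
  }
  all_triplets <- dplyr::bind_rows(networks)

  # --- cross-cohort integration ---------------------------------------------
  shared <- stage("intersect", {
    sh <- shared_across(all_triplets, required_count = required)
    readr::write_tsv(sh, file.path(out, "shared", "shared_triplets.tsv"))
    readr::write_tsv(cytoscape_edges(sh),
                     file.path(out, "shared", "cytoscape_edges.tsv"))
    if (n_cohorts >= 2L && nrow(all_triplets) > 0L) {
      for (role in c("sponge_id", "mrna_id", "mirna_id")) {
        vc <- venn_counts(tibble(cohort = all_triplets$cohort,
                                 feature_id = all_triplets[[role]]))
        readr::write_tsv(vc, file.path(out, "shared",
                                       paste0("venn_", sub("_id$", "", role), ".tsv")))
      }
    }
    sh
  })
  log_stage("shared network: ", nrow(shared), " triplets at frequency ", required)
  manifest_counts[["shared"]] <- nrow(shared)

  # --- survival screen -------------------------------------------------------
  screen <- stage("survival", {
    feats <- unique(c(shared$sponge_id, shared$mrna_id, shared$mirna_id))
    surv_cohorts <- lapply(cohort_data, function(dat) {
      tumor <- dat$samples$sample_id[dat$samples$group == "tumor"]
      gm <- expr_to_matrix(dat$gene_logcpm)
      mm <- expr_to_matrix(dat$mirna_logcpm)
      list(expression = rbind(gm[, intersect(colnames(gm), tumor), drop = FALSE],
                              mm[, intersect(colnames(mm), tumor), drop = FALSE]),
           clinical = dat$clinical)
    })
    sc <- prognostic_screen(feats, surv_cohorts, alpha = config$survival_alpha)
    readr::write_tsv(sc, file.path(out, "survival", "prognostic_screen.tsv"))
    # K-M curve points for every significant feature-cohort combination
    if (nrow(sc) > 0L) {
      for (k in seq_len(nrow(sc))) {
        lb <- sc$cohort[k]; f <- sc$feature_id[k]
        expr <- surv_cohorts[[lb]]$expression
        clin <- surv_cohorts[[lb]]$clinical
        common <- intersect(colnames(expr), clin$sample_id)
        grp <- median_split(expr[f, common])
        km <- km_curve(tibble(
          time = clin$time[match(common, clin$sample_id)],
          event = clin$event[match(common, clin$sample_id)],
          group = unname(grp)))
        readr::write_tsv(km, file.path(out, "survival",
                                       paste0("km_", lb, "_", f, ".tsv")))
      }
    }
    sc
  })
  log_stage("prognostic screen: ", nrow(screen), " significant feature-cohort hits")
  manifest_counts[["survival"]] <- nrow(screen)

  # --- enrichment ------------------------------------------------------------
  enr <- stage("enrichment", {
    universe <- study$biotypes$feature_id[study$biotypes$biotype == "mRNA"]
    query <- intersect(unique(shared$mrna_id), universe)
    e <- ora_enrich(query, study$gene_sets, universe)
    readr::write_tsv(e, file.path(out, "enrichment", "ora.tsv"))
    e
  })
  manifest_counts[["enrichment"]] <- nrow(enr)

  # --- summary + manifest ----------------------------------------------------
  summary <- list(
    n_cohorts = n_cohorts,
    required_count = required,
    de_counts = de_counts,
    network_sizes = lapply(networks, nrow),
    shared_network = list(
      n_triplets = nrow(shared),
      n_sponges = dplyr::n_distinct(shared$sponge_id),
      n_mrnas = dplyr::n_distinct(shared$mrna_id),
      n_mirnas = dplyr::n_distinct(shared$mirna_id)
    ),
    prognostic = list(
      n_hits = nrow(screen),
      n_features = dplyr::n_distinct(screen$feature_id)
    ),
    enrichment_top = if (nrow(enr) > 0L) {
      list(set_id = enr$set_id[1], p_value = enr$p_value[1], fdr = enr$fdr[1])
    } else {
      NULL
    }
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    row_counts = manifest_counts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}
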