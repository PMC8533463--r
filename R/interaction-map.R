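#' Bipartite miRNA-target interaction map
#'
#' An `interaction_map` holds the miRNA -> target relation over mRNAs,
#' lncRNAs and pseudogenes, together with the miRNA universe used as `N` in
#' the hypergeometric shared-target test. Build one from an edge table with
#' [interaction_map()] or simulate one with [build_interaction_map()].
#'
#' @param edges Tibble with columns `mirna_id`, `target_id`; duplicated rows
#'   are collapsed (set semantics).
#' @param mirna_ids Optional character vector fixing the miRNA universe;
#'   defaults to the miRNAs present in `edges`. Must cover them.
#'
#' @return An object of class `interaction_map`.
#' @export
interaction_map <- function(edges, mirna_ids = NULL) {
  stopifnot(is.data.frame(edges), all(c("mirna_id", "target_id") %in% names(edges)))
  edges <- dplyr::distinct(as_tibble(edges[c("mirna_id", "target_id")]))
  edges <- dplyr::arrange(edges, .data$mirna_id, .data$target_id)
  mirna_ids <- sort(unique(mirna_ids %||% edges$mirna_id))
  if (length(mirna_ids) < 1L) abort("interaction map needs a nonempty miRNA universe")
  missing <- setdiff(edges$mirna_id, mirna_ids)
  if (length(missing) > 0L) {
    abort(paste0("edges reference miRNAs outside the declared universe: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  structure(
    list(edges = edges, mirna_ids = mirna_ids),
    class = "interaction_map"
  )
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("<interaction_map>", nrow(x$edges), "edges,",
      length(x$mirna_ids), "miRNAs,",
      dplyr::n_distinct(x$edges$target_id), "targets\n")
  invisible(x)
}

#' Number of miRNAs in the map universe
#' @param map An [interaction_map()].
#' @return Integer universe size (the `N` of the hypergeometric test).
#' @export
n_mirnas <- function(map) length(map$mirna_ids)

#' miRNAs targeting a feature / targets of a miRNA
#'
#' The two directions of the bipartite relation; they are mutually consistent
#' inverses by construction.
#'
#' @param map An [interaction_map()].
#' @param target_id,mirna_id Feature identifier to look up.
#' @return Character vector of ids (sorted, possibly empty).
#' @export
mirnas_of <- function(map, target_id) {
  sort(map$edges$mirna_id[map$edges$target_id %in% target_id])
}

#' @rdname mirnas_of
#' @export
targets_of <- function(map, mirna_id) {
  sort(map$edges$target_id[map$edges$mirna_id %in% mirna_id])
}

#' Simulate an interaction map with planted sponge-target pairs
#'
#' Stand-in for a curated miRNA-target database. Each planted sponge-mRNA
#' pair is wired to exactly `shared_mre_count` common miRNAs (and to nothing
#' else, so the pair's shared set is the full target set of both partners);
#' background edges between the remaining features and the miRNA universe are
#' drawn independently at `background_density`. When the planted pairs'
#' miRNA sets fit disjointly into the universe they are carved from a single
#' permutation, which keeps planted pairs from sharing repressors with each
#' other.
#'
#' @param config A [sim_config()].
#' @return An [interaction_map()] with a `planted` attribute: a tibble with
#'   one row per planted triplet (`sponge_id`, `mrna_id`, `mirna_id` anchor,
#'   `mirnas` list-column of the full shared set, `shared` flag, `cohort`).
#' @export
#' @examples
#' map <- build_interaction_map(sim_config(n_cohorts = 2))
#' n_mirnas(map)
build_interaction_map <- function(config) {
  validate_sim_config(config)
  ids <- feature_ids(config)
  set.seed(derive_seed(config$seed, "interaction_map"))

  n_shared <- config$n_planted_triplets_shared
  n_private <- config$n_planted_triplets_private
  n_planted <- n_shared + n_private
  mre <- config$shared_mre_count

  # Sponges alternate between the lncRNA and pseudogene pools so both sponge
  # biotypes exercise the same inference code path.
  sponge_pool <- character(n_planted)
  li <- 1L; pi <- 1L
  for (k in seq_len(n_planted)) {
    take_lnc <- (k %% 2L == 1L && li <= config$n_lncrna) || pi > config$n_pseudogene
    if (take_lnc) {
      sponge_pool[k] <- ids$lncrna[li]; li <- li + 1L
    } else {
      sponge_pool[k] <- ids$pseudogene[pi]; pi <- pi + 1L
    }
  }
  target_pool <- ids$mrna[seq_len(n_planted)]

  if (n_planted > 0L) {
    if (n_planted * mre <= config$n_mirna) {
      perm <- sample(ids$mirna)
      mirna_sets <- lapply(seq_len(n_planted), function(k) {
        sort(perm[((k - 1L) * mre + 1L):(k * mre)])
      })
    } else {
      mirna_sets <- lapply(seq_len(n_planted), function(k) {
        sort(sample(ids$mirna, mre))
      })
    }
    planted <- tibble(
      sponge_id = sponge_pool,
      mrna_id = target_pool,
      mirnas = mirna_sets,
      mirna_id = vapply(mirna_sets, `[[`, character(1), 1L),
      shared = rep(c(TRUE, FALSE), c(n_shared, n_private)),
      cohort = c(rep(NA_character_, n_shared),
                 cohort_label(((seq_len(n_private) - 1L) %% config$n_cohorts) + 1L))
    )
  } else {
    planted <- tibble(
      sponge_id = character(), mrna_id = character(),
      mirnas = list(), mirna_id = character(),
      shared = logical(), cohort = character()
    )
  }

  planted_genes <- c(planted$sponge_id, planted$mrna_id)
  background_targets <- setdiff(c(ids$mrna, ids$lncrna, ids$pseudogene), planted_genes)

  # Background edges: independent Bernoulli per (miRNA, target) pair.
  n_bg <- length(background_targets)
  bg <- matrix(
    runif(n_bg * config$n_mirna) < config$background_density,
    nrow = n_bg, ncol = config$n_mirna
  )
  idx <- which(bg, arr.ind = TRUE)
  bg_edges <- tibble(
    mirna_id = ids$mirna[idx[, 2]],
    target_id = background_targets[idx[, 1]]
  )

  if (n_planted > 0L) {
    planted_edges <- tidyr::unnest(
      tibble(
        target_id = c(planted$sponge_id, planted$mrna_id),
        mirna_id = rep(planted$mirnas, 2L)
      ),
      "mirna_id"
    )[c("mirna_id", "target_id")]
  } else {
    planted_edges <- tibble(mirna_id = character(), target_id = character())
  }

  map <- interaction_map(dplyr::bind_rows(planted_edges, bg_edges),
                         mirna_ids = ids$mirna)
  attr(map, "planted") <- planted
  map
}
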