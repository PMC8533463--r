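#' Canonical triplet key
#'
#' Collapses one sponge-mRNA-miRNA association into the canonical string
#' `"<sponge>_<mRNA>_<miRNA>"`. Because the underscore is the separator,
#' gene and miRNA ids must not contain one (miRNA names routinely contain
#' hyphens, which are fine); this is enforced so keys parse back uniquely.
#'
#' @param sponge_id,mrna_id,mirna_id Character vectors (recycled together).
#' @return Character vector of keys.
#' @seealso [parse_triplet_key()]
#' @export
#' @examples
#' triplet_key("ENSGSPONGE1", "ENSGTARGET1", "hsa-miR-31-5p")
triplet_key <- function(sponge_id, mrna_id, mirna_id) {
  ids <- c(sponge_id, mrna_id, mirna_id)
  if (any(!nzchar(ids))) abort("triplet ids must be non-empty")
  if (any(grepl("_", ids, fixed = TRUE))) {
    abort("triplet ids must not contain '_' (reserved as the key separator)")
  }
  paste(sponge_id, mrna_id, mirna_id, sep = "_")
}

#' @rdname triplet_key
#' @param key Character vector of canonical keys.
#' @return For `parse_triplet_key()`: tibble with columns `sponge_id`,
#'   `mrna_id`, `mirna_id`.
#' @export
parse_triplet_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    abort("malformed triplet key(s): expected exactly two '_' separators")
  }
  tibble(
    sponge_id = vapply(parts, `[[`, character(1), 1L),
    mrna_id = vapply(parts, `[[`, character(1), 2L),
    mirna_id = vapply(parts, `[[`, character(1), 3L)
  )
}

#' Triplets shared across cohorts by the one-way frequency rule
#'
#' Builds a one-way frequency table over canonical triplet keys (each triplet
#' counted at most once per cohort) and returns the triplets whose frequency
#' equals `required_count`. With `required_count` equal to the number of
#' cohorts - the default - this is exactly the intersection of the per-cohort
#' key sets: the shared ceRNA network.
#'
#' @param triplets Tibble with columns `cohort` and `key` (or the three id
#'   columns, from which keys are derived), e.g. row-bound results of
#'   [infer_network()]; alternatively a named list of per-cohort triplet
#'   tibbles.
#' @param required_count Required one-way frequency (>= 1); defaults to the
#'   number of distinct cohorts present.
#' @return Tibble `sponge_id`, `mrna_id`, `mirna_id`, `key`, `n_cohorts`.
#' @export
shared_across <- function(triplets, required_count = NULL) {
  if (is.list(triplets) && !is.data.frame(triplets)) {
    labels <- names(triplets) %||% as.character(seq_along(triplets))
    triplets <- dplyr::bind_rows(
      purrr::map2(triplets, labels, function(tb, lb) {
        tb$cohort <- lb
        tb
      })
    )
  }
  stopifnot(is.data.frame(triplets), "cohort" %in% names(triplets))
  if (!"key" %in% names(triplets)) {
    triplets$key <- triplet_key(triplets$sponge_id, triplets$mrna_id,
                                triplets$mirna_id)
  }
  n_cohorts <- dplyr::n_distinct(triplets$cohort)
  required_count <- required_count %||% n_cohorts
  if (required_count < 1L) abort("required_count must be >= 1")
  if (required_count > n_cohorts) {
    abort("required_count exceeds the number of cohorts present")
  }
  freq <- triplets |>
    dplyr::distinct(.data$cohort, .data$key) |>
    dplyr::count(.data$key, name = "n_cohorts") |>
    dplyr::filter(.data$n_cohorts == required_count)
  out <- dplyr::bind_cols(parse_triplet_key(freq$key), freq)
  dplyr::arrange(out, .data$key)
}

#' Venn-style cohort-membership counts
#'
#' For each nonempty subset of cohorts, counts the features whose cohort
#' membership is exactly that subset. Membership classes are labelled by the
#' sorted cohort names joined with `&`; counts over all classes sum to the
#' size of the feature union.
#'
#' @param features Tibble with columns `cohort` and `feature_id`, or a named
#'   list of per-cohort feature id vectors. Needs >= 2 cohorts.
#' @return Tibble `cohort_set`, `n`, sorted by descending class size.
#' @export
#' @examples
#' venn_counts(list(a = c("x", "y"), b = c("y", "z")))
venn_counts <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- dplyr::bind_rows(
      purrr::imap(features, function(ids, lb) tibble(cohort = lb, feature_id = ids))
    )
  }
  stopifnot(is.data.frame(features),
            all(c("cohort", "feature_id") %in% names(features)))
  if (dplyr::n_distinct(features$cohort) < 2L) {
    abort("venn_counts needs at least 2 cohorts")
  }
  features |>
    dplyr::distinct(.data$cohort, .data$feature_id) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      cohort_set = paste(sort(unique(.data$cohort)), collapse = "&"),
      .groups = "drop"
    ) |>
    dplyr::count(.data$cohort_set, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$cohort_set)
}

#' Edge table of a ceRNA network for Cytoscape import
#'
#' Flattens a triplet table into the three edge classes of the sponge
#' network: sponge-miRNA, miRNA-mRNA and sponge-mRNA. Duplicate edges are
#' collapsed.
#'
#' @param triplets Tibble with `sponge_id`, `mrna_id`, `mirna_id` columns.
#' @return Tibble `source`, `target`, `edge_type`.
#' @export
cytoscape_edges <- function(triplets) {
  dplyr::bind_rows(
    tibble(source = triplets$sponge_id, target = triplets$mirna_id,
           edge_type = "sponge-miRNA"),
    tibble(source = triplets$mirna_id, target = triplets$mrna_id,
           edge_type = "miRNA-mRNA"),
    tibble(source = triplets$sponge_id, target = triplets$mrna_id,
           edge_type = "sponge-mRNA")
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$edge_type, .data$source, .data$target)
}
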