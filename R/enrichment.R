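#' Gene-set over-representation analysis
#'
#' Hypergeometric over-representation of a query gene list against a GMT-style
#' collection of gene sets: for each set the p-value is `P(X >= overlap)` from
#' the same kernel as [hypergeom_pvalue()], with the universe as population,
#' the (universe-restricted) set as successes and the query as draws.
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query Character vector of gene ids; must be contained in `universe`.
#' @param gene_sets Tibble with columns `set_id`, (`description`,) and the
#'   list-column `members`, as returned by [read_gmt()], or a named list of
#'   id vectors.
#' @param universe Character vector defining the testable gene population.
#' @return Tibble `set_id`, `set_size` (after restriction to the universe),
#'   `query_size`, `overlap`, `p_value`, `fdr`.
#' @export
#' @examples
#' sets <- tibble::tibble(set_id = "s1", description = "",
#'                        members = list(c("a", "b", "c")))
#' ora_enrich(c("a", "b"), sets, universe = letters[1:10])
ora_enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort("query genes must be a subset of the universe")
  }
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(set_id = names(gene_sets), members = unname(gene_sets))
  }
  stopifnot(all(c("set_id", "members") %in% names(gene_sets)))

  N <- length(universe)
  n <- length(query)
  out <- purrr::map2(gene_sets$set_id, gene_sets$members, function(id, mem) {
    set <- intersect(unique(mem), universe)
    K <- length(set)
    m <- length(intersect(query, set))
    p <- if (K == 0L || n == 0L) 1 else hypergeom_pvalue(m, N = N, n = n, K = K)
    tibble(set_id = id, set_size = K, query_size = n, overlap = m, p_value = p)
  })
  out <- dplyr::bind_rows(out)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, .data$set_id)
}
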