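#' Hypergeometric shared-miRNA p-value
#'
#' Over-representation test for the number of miRNAs co-targeting a
#' sponge-mRNA pair. With a universe of `N` miRNAs, `n` targeting the sponge,
#' `K` targeting the mRNA and `m` shared, returns the upper tail
#' `P(X >= m)` for `X ~ Hypergeometric(N, K, n)`, i.e.
#' `1 - sum_{k=0}^{m-1} C(K,k) C(N-K,n-k) / C(N,n)`.
#' Set `as_printed = TRUE` for the variant whose finite sum runs to `m`
#' (`P(X > m)`); the default convention is the standard one for
#' over-representation, under which sharing every available miRNA is maximally
#' significant. Vectorised over all four arguments.
#'
#' @param m Number of shared miRNAs.
#' @param N miRNA universe size.
#' @param n Number of miRNAs targeting the sponge.
#' @param K Number of miRNAs targeting the mRNA.
#' @param as_printed Use the inclusive upper summation limit (`P(X > m)`).
#' @return p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_pvalue(3, N = 10, n = 4, K = 5)  # 55/210
hypergeom_pvalue <- function(m, N, n, K, as_printed = FALSE) {
  bad <- m < 0 | m > pmin(n, K) | n > N | K > N | n < 0 | K < 0 | N < 1
  if (any(bad)) {
    abort("domain error: need 0 <= m <= min(n, K) and n, K <= N with N >= 1")
  }
  upper <- if (as_printed) m else m - 1
  phyper(upper, K, N - K, n, lower.tail = FALSE)
}

#' Candidate sponge-mRNA pairs by shared-miRNA over-representation
#'
#' Scores every differential sponge x differential mRNA pair that shares at
#' least one miRNA in the interaction map with [hypergeom_pvalue()], adjusts
#' across all tested pairs with Benjamini-Hochberg, and keeps pairs below
#' `fdr_threshold`. Features absent from the map are skipped (a message
#' reports how many).
#'
#' @param de_sponges Character vector of differential lncRNA/pseudogene ids.
#' @param de_mrnas Character vector of differential mRNA ids.
#' @param map An [interaction_map()].
#' @param fdr_threshold BH-adjusted gate on the hypergeometric p-value; set
#'   to `NULL` to keep all tested pairs.
#' @return Tibble with one row per retained pair: `sponge_id`, `mrna_id`,
#'   `m`, `n`, `K`, `N`, `hyper_p`, `hyper_fdr` and the list-column
#'   `shared_mirnas`.
#' @export
candidate_pairs <- function(de_sponges, de_mrnas, map, fdr_threshold = 0.05) {
  de_sponges <- unique(de_sponges)
  de_mrnas <- unique(de_mrnas)
  empty <- tibble(
    sponge_id = character(), mrna_id = character(),
    m = integer(), n = integer(), K = integer(), N = integer(),
    hyper_p = numeric(), hyper_fdr = numeric(), shared_mirnas = list()
  )
  if (length(de_sponges) == 0L || length(de_mrnas) == 0L) return(empty)

  mapped <- unique(map$edges$target_id)
  n_unmapped <- sum(!de_sponges %in% mapped) + sum(!de_mrnas %in% mapped)
  if (n_unmapped > 0L) {
    inform(paste0("candidate_pairs: skipped ", n_unmapped,
                  " feature(s) absent from the interaction map"))
  }
  de_sponges <- intersect(de_sponges, mapped)
  de_mrnas <- intersect(de_mrnas, mapped)
  if (length(de_sponges) == 0L || length(de_mrnas) == 0L) return(empty)

  sets <- split(map$edges$mirna_id, map$edges$target_id)
  N <- n_mirnas(map)

  grid <- tidyr::expand_grid(sponge_id = de_sponges, mrna_id = de_mrnas)
  shared <- purrr::map2(grid$sponge_id, grid$mrna_id, function(s, t) {
    sort(intersect(sets[[s]], sets[[t]]))
  })
  grid$shared_mirnas <- shared
  grid$m <- lengths(shared)
  grid <- grid[grid$m >= 1L, , drop = FALSE]
  if (nrow(grid) == 0L) return(empty)

  grid$n <- lengths(sets[grid$sponge_id])
  grid$K <- lengths(sets[grid$mrna_id])
  grid$N <- N
  grid$hyper_p <- hypergeom_pvalue(grid$m, grid$N, grid$n, grid$K)
  grid$hyper_fdr <- p.adjust(grid$hyper_p, method = "BH")
  if (!is.null(fdr_threshold)) {
    grid <- grid[grid$hyper_fdr < fdr_threshold, , drop = FALSE]
  }
  as_tibble(grid[c("sponge_id", "mrna_id", "m", "n", "K", "N",
                   "hyper_p", "hyper_fdr", "shared_mirnas")])
}

#' Positive Pearson correlation filter for ceRNA pairs
#'
#' Computes the Pearson correlation of each pair on (tumor-sample) log-CPM
#' profiles and keeps pairs with `r > min_r` (strict: exactly `min_r` is
#' dropped). A sponge that sequesters the partners' common miRNAs raises the
#' target's expression, so genuine ceRNA pairs correlate positively.
#' Pairs with a zero-variance member are dropped with a warning.
#'
#' @param pairs Tibble from [candidate_pairs()].
#' @param logcpm Wide log2-CPM tibble or matrix holding both pair members,
#'   typically restricted to tumor samples; needs >= 3 samples.
#' @param min_r Correlation gate (strict lower bound).
#' @return `pairs` with a `pearson_r` column, filtered.
#' @export
pearson_pair_filter <- function(pairs, logcpm, min_r = 0.4) {
  if (nrow(pairs) == 0L) {
    pairs$pearson_r <- numeric(0)
    return(pairs)
  }
  m <- expr_to_matrix(logcpm)
  if (ncol(m) < 3L) abort("need at least 3 samples to correlate")
  present <- pairs$sponge_id %in% rownames(m) & pairs$mrna_id %in% rownames(m)
  if (any(!present)) {
    warn(paste0("pearson_pair_filter: dropped ", sum(!present),
                " pair(s) with members absent from the expression matrix"))
    pairs <- pairs[present, , drop = FALSE]
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- m[pairs$sponge_id[i], ]
    y <- m[pairs$mrna_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  if (anyNA(r)) {
    warn(paste0("pearson_pair_filter: dropped ", sum(is.na(r)),
                " pair(s) with zero-variance expression"))
  }
  pairs$pearson_r <- r
  pairs[!is.na(r) & r > min_r, , drop = FALSE]
}

#' Partial correlation given control variables
#'
#' Correlation of the residuals of `x` and `y` after least-squares projection
#' onto an intercept plus the columns of `z`. Used as the `pcor` term of the
#' multiple sensitivity correlation, with `z` the shared-miRNA expression
#' profiles.
#'
#' @param x,y Numeric vectors of length `n`.
#' @param z Numeric matrix with `n` rows and one column per control variable
#'   (a plain vector is treated as one column).
#' @return Partial correlation in `[-1, 1]`.
#' @export
#' @examples
#' n <- 100; zc <- rnorm(n)
#' x <- zc + rnorm(n); y <- zc + rnorm(n)
#' partial_correlation(x, y, zc)  # near 0 once z is controlled
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  n <- length(x)
  if (length(y) != n || nrow(z) != n) abort("x, y and z must have matching lengths")
  i <- ncol(z)
  if (n <= i + 2) abort("need more samples than controls + 2")
  design <- cbind(`(intercept)` = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    culprit <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    abort(paste0("collinear control variables (rank ", qrd$rank, " < ",
                 ncol(design), "): check ",
                 paste(culprit, collapse = ", ")))
  }
  rx <- qr.resid(qrd, x)
  ry <- qr.resid(qrd, y)
  cor(rx, ry)
}

#' Multiple sensitivity correlation (mscor) of one ceRNA pair
#'
#' `mscor(g1, g2, M) = cor(g1, g2) - pcor(g1, g2 | M)`: the drop in the
#' gene-gene Pearson correlation once the shared miRNA set `M` is controlled
#' for. With a single control miRNA this is the sensitivity correlation
#' (scor). A large positive mscor indicates that much of the pair's
#' co-expression is routed through the shared miRNAs - the ceRNA signature.
#'
#' @param g1,g2 Expression profiles (numeric vectors over samples).
#' @param m_expr Matrix of shared-miRNA expression profiles (samples x
#'   miRNAs), or a vector for a single miRNA.
#' @return One-row tibble: `cor`, `pcor`, `mscor`, `i` (number of controls),
#'   `n_samples`.
#' @export
mscor_statistic <- function(g1, g2, m_expr) {
  m_expr <- as.matrix(m_expr)
  cv <- cor(g1, g2)
  pc <- partial_correlation(g1, g2, m_expr)
  tibble(cor = cv, pcor = pc, mscor = cv - pc,
         i = ncol(m_expr), n_samples = length(g1))
}

#' mscor statistics for a table of candidate pairs
#'
#' Applies [mscor_statistic()] to every pair, controlling for the pair's
#' shared miRNAs. Shared miRNAs missing from `mirna_logcpm` (e.g. removed by
#' the expression filter) are excluded from the control set; pairs left with
#' no usable control are dropped with a warning.
#'
#' @param pairs Tibble from [pearson_pair_filter()] (needs `shared_mirnas`).
#' @param gene_logcpm,mirna_logcpm Wide log2-CPM tibbles or matrices over the
#'   same (tumor) samples.
#' @return `pairs` with columns `cor`, `pcor`, `mscor`, `i`, `n_samples` and
#'   list-column `mirnas_used`.
#' @export
compute_mscor <- function(pairs, gene_logcpm, mirna_logcpm) {
  gm <- expr_to_matrix(gene_logcpm)
  mm <- expr_to_matrix(mirna_logcpm)
  if (!identical(colnames(gm), colnames(mm))) {
    mm <- mm[, colnames(gm), drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, cor = numeric(0), pcor = numeric(0),
                         mscor = numeric(0), i = integer(0),
                         n_samples = integer(0), mirnas_used = list()))
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    use <- intersect(pairs$shared_mirnas[[k]], rownames(mm))
    if (length(use) == 0L) return(NULL)
    st <- mscor_statistic(gm[pairs$sponge_id[k], ], gm[pairs$mrna_id[k], ],
                          t(mm[use, , drop = FALSE]))
    st$mirnas_used <- list(use)
    st$.row <- k
    st
  })
  kept <- dplyr::bind_rows(rows)
  if (is.null(kept$.row) || nrow(kept) < nrow(pairs)) {
    warn(paste0("compute_mscor: dropped ",
                nrow(pairs) - (if (is.null(kept$.row)) 0 else nrow(kept)),
                " pair(s) with no expressed shared miRNA"))
  }
  if (is.null(kept$.row)) return(pairs[0, ])
  out <- dplyr::bind_cols(pairs[kept$.row, , drop = FALSE],
                          kept[setdiff(names(kept), ".row")])
  as_tibble(out)
}

#' Empirical null p-values for mscor
#'
#' Pairs are stratified by the rounded gene-gene correlation (bins of width
#' `cor_bin_width`, centers at odd multiples of half the width) and by the
#' number of control miRNAs `i`. For each stratum, `null_samples` datasets
#' are drawn at the observed sample size from a null in which the two genes
#' are bivariate normal with correlation equal to the bin center and the `i`
#' miRNAs are independent standard normals unrelated to either gene; the
#' stratum's null mscor values calibrate the observed ones:
#' `empirical_p = (1 + #(null >= observed)) / (null_samples + 1)`.
#' Benjamini-Hochberg across all pairs yields `adjusted_p`.
#'
#' @param results Tibble from [compute_mscor()].
#' @param null_samples Null datasets per stratum (>= 100 recommended; fewer
#'   triggers a warning about unstable tails).
#' @param cor_bin_width Width of the correlation strata.
#' @param seed Integer seed for the null draws.
#' @return `results` with `empirical_p` and `adjusted_p` columns.
#' @export
mscor_null_pvalues <- function(results, null_samples = 1000,
                               cor_bin_width = 0.1, seed = 1L) {
  if (null_samples < 100) {
    warn("null_samples < 100: empirical tail estimates will be unstable")
  }
  if (nrow(results) == 0L) {
    results$empirical_p <- numeric(0)
    results$adjusted_p <- numeric(0)
    return(results)
  }
  stopifnot(all(c("cor", "mscor", "i", "n_samples") %in% names(results)))
  if (any(!is.finite(results$mscor))) abort("non-finite mscor in results")

  half <- cor_bin_width / 2
  center <- floor(results$cor / cor_bin_width) * cor_bin_width + half
  center <- pmin(pmax(center, -1 + half), 1 - half)

  strata <- tibble(center = center, i = results$i, n = results$n_samples)
  key <- paste(format(strata$center, digits = 10), strata$i, strata$n)
  results$empirical_p <- NA_real_

  set.seed(as.integer(seed))
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    rho <- strata$center[rows[1]]
    i <- strata$i[rows[1]]
    n <- strata$n[rows[1]]
    null_mscor <- vapply(seq_len(null_samples), function(b) {
      g1 <- rnorm(n)
      g2 <- rho * g1 + sqrt(1 - rho^2) * rnorm(n)
      z <- matrix(rnorm(n * i), nrow = n)
      cor(g1, g2) - partial_correlation(g1, g2, z)
    }, numeric(1))
    results$empirical_p[rows] <- vapply(results$mscor[rows], function(obs) {
      (1 + sum(null_mscor >= obs)) / (null_samples + 1)
    }, numeric(1))
  }
  results$adjusted_p <- p.adjust(results$empirical_p, method = "BH")
  results
}

#' Per-cohort ceRNA triplet inference
#'
#' The full three-step screen for one cohort: (i) hypergeometric shared-miRNA
#' test over differential sponge x differential mRNA pairs (BH FDR <
#' `hyper_fdr`), (ii) positive Pearson filter (`r > pearson_min`) on tumor
#' log-CPM, (iii) multiple sensitivity correlation with empirical null
#' p-values (BH-adjusted < `mscor_alpha`). Surviving pairs are expanded into
#' one triplet per shared miRNA used in the mscor control set. lncRNA- and
#' pseudogene-sponged triplets flow through the identical code path.
#'
#' @param gene_logcpm,mirna_logcpm Wide log2-CPM tibbles (all samples;
#'   correlations use the tumor columns only).
#' @param samples Sample sheet (`sample_id`, `group`).
#' @param de Gene-level `de_result` from [call_differential()], carrying
#'   `biotype`; sponges are differential lncRNAs/pseudogenes, targets are
#'   differential mRNAs.
#' @param map An [interaction_map()].
#' @param hyper_fdr,pearson_min,mscor_alpha Stage thresholds.
#' @param null_samples,cor_bin_width Null-calibration settings, see
#'   [mscor_null_pvalues()].
#' @param seed Seed for the null draws.
#' @return Triplet tibble: `sponge_id`, `mrna_id`, `mirna_id`, `key`, pair
#'   statistics (`m`, `n`, `K`, `N`, `hyper_p`, `hyper_fdr`, `pearson_r`,
#'   `cor`, `pcor`, `mscor`, `empirical_p`, `adjusted_p`).
#' @export
infer_network <- function(gene_logcpm, mirna_logcpm, samples, de, map,
                          hyper_fdr = 0.05, pearson_min = 0.4,
                          mscor_alpha = 0.05, null_samples = 1000,
                          cor_bin_width = 0.1, seed = 1L) {
  stopifnot("biotype" %in% names(de))
  sponges <- de$feature_id[de$status != "ns" &
                             de$biotype %in% c("lncRNA", "pseudogene")]
  mrnas <- de$feature_id[de$status != "ns" & de$biotype == "mRNA"]

  gm <- expr_to_matrix(gene_logcpm)
  mm <- expr_to_matrix(mirna_logcpm)
  tumor_ids <- samples$sample_id[samples$group == "tumor"]
  gm_t <- gm[, intersect(colnames(gm), tumor_ids), drop = FALSE]
  mm_t <- mm[, intersect(colnames(mm), tumor_ids), drop = FALSE]

  pairs <- candidate_pairs(sponges, mrnas, map, fdr_threshold = hyper_fdr)
  pairs <- pearson_pair_filter(pairs, gm_t, min_r = pearson_min)
  res <- compute_mscor(pairs, gm_t, mm_t)
  res <- mscor_null_pvalues(res, null_samples = null_samples,
                            cor_bin_width = cor_bin_width, seed = seed)
  res <- res[res$adjusted_p < mscor_alpha, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(tibble(
      sponge_id = character(), mrna_id = character(), mirna_id = character(),
      key = character(), m = integer(), n = integer(), K = integer(),
      N = integer(), hyper_p = numeric(), hyper_fdr = numeric(),
      pearson_r = numeric(), cor = numeric(), pcor = numeric(),
      mscor = numeric(), empirical_p = numeric(), adjusted_p = numeric()
    ))
  }
  trip <- tidyr::unnest(
    dplyr::mutate(res, mirna_id = .data$mirnas_used),
    "mirna_id"
  )
  trip$key <- triplet_key(trip$sponge_id, trip$mrna_id, trip$mirna_id)
  as_tibble(trip[c("sponge_id", "mrna_id", "mirna_id", "key",
                   "m", "n", "K", "N", "hyper_p", "hyper_fdr", "pearson_r",
                   "cor", "pcor", "mscor", "empirical_p", "adjusted_p")])
}
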