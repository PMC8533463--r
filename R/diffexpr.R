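#' TMM normalisation factors
#'
#' Trimmed-mean-of-M-values scaling factors for between-sample normalisation
#' of count libraries. Gene-wise log2 ratios (M) and average log2 abundances
#' (A) are computed against a reference sample on library-size-normalised
#' counts; M is trimmed 30 percent on each side, A 5 percent; the surviving
#' M values are averaged with inverse delta-method variance weights; factors
#' are rescaled so that their geometric mean is 1. The reference is the
#' sample whose 75th percentile of library-normalised counts is closest to
#' the mean of those percentiles. A pure depth difference between samples
#' yields factors of 1: library size itself is carried by the effective
#' library size in [log_cpm()], not by the factor.
#'
#' @param counts Wide count tibble (`feature_id` first column, one column per
#'   sample) or an integer matrix with feature rownames.
#' @return Tibble with columns `sample_id`, `norm_factor`.
#' @export
#' @examples
#' m <- matrix(rpois(60, 50), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' tmm_factors(m)
tmm_factors <- function(counts) {
  m <- expr_to_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  f75 <- apply(m, 2, quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), norm_factor = f)
}

# Factor of one observation column against the reference column, following
# the published TMM recipe (30% two-sided trim on M, 5% on A, precision
# weights from the binomial delta method).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  2^f
}

#' Log2 counts per million
#'
#' `log2((count + 0.5) / (effective library size + 1) * 1e6)` where the
#' effective library size is the column total multiplied by that sample's
#' normalisation factor.
#'
#' @inheritParams tmm_factors
#' @param factors Tibble from [tmm_factors()] (or a numeric vector named by
#'   sample). All factors must be positive.
#' @return Wide tibble of log2-CPM values, same shape as `counts`.
#' @export
log_cpm <- function(counts, factors = NULL) {
  m <- expr_to_matrix(counts)
  if (is.null(factors)) {
    f <- rep(1, ncol(m))
  } else if (is.data.frame(factors)) {
    idx <- match(colnames(m), factors$sample_id)
    if (anyNA(idx)) abort("factors table does not cover every sample")
    f <- factors$norm_factor[idx]
  } else {
    if (length(factors) != ncol(m)) {
      abort("length of factors does not match the number of samples")
    }
    f <- if (!is.null(names(factors))) factors[colnames(m)] else factors
  }
  if (any(!is.finite(f)) || any(f <= 0)) abort("normalisation factors must be positive")
  eff <- colSums(m) * f
  out <- log2(sweep(m + 0.5, 2, eff + 1, "/") * 1e6)
  matrix_to_expr(out)
}

#' Remove low-expressed features
#'
#' A feature is dropped when strictly more than `max_prop_below` of its
#' samples fall below `min_logcpm` log2-CPM; a feature sitting exactly at the
#' boundary (e.g. half the samples below 1) is kept.
#'
#' @param logcpm Wide log2-CPM tibble or matrix, as from [log_cpm()].
#' @param min_logcpm Expression floor in log2-CPM units.
#' @param max_prop_below Largest tolerated fraction of samples below the floor.
#' @return `logcpm` restricted to the retained features.
#' @export
filter_low_expressed <- function(logcpm, min_logcpm = 1, max_prop_below = 0.5) {
  m <- expr_to_matrix(logcpm)
  if (any(!is.finite(m))) abort("log-CPM matrix contains non-finite values")
  keep <- rowMeans(m < min_logcpm) <= max_prop_below
  if (is_tibble(logcpm) || is.data.frame(logcpm)) {
    logcpm[keep, , drop = FALSE]
  } else {
    m[keep, , drop = FALSE]
  }
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Fits a per-feature two-group linear model (tumor minus normal) on log-CPM
#' values and shrinks the residual variances toward a common prior:
#' the posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)` with the prior
#' degrees of freedom `d0` and prior variance `s0^2` estimated by matching
#' the moments of `log(s^2)` through digamma/trigamma identities. The
#' moderated t is the fold change over the posterior standard error, with
#' `d0 + d` degrees of freedom (capped at the pooled residual df across
#' features when the prior df estimate is infinite).
#'
#' @param logcpm Wide log2-CPM tibble or matrix (>= 2 features).
#' @param samples Sample sheet tibble (`sample_id`, `group` with levels
#'   `tumor`/`normal`), >= 2 samples per group.
#' @return A `moderated_fit` tibble with columns `feature_id`, `logFC`
#'   (log2 tumor minus normal), `t`, `p_value`, plus attributes `df_prior`,
#'   `s2_prior`, `df_residual`. Use [tidy()] / [glance()] to extract them.
#' @export
moderated_t_test <- function(logcpm, samples) {
  m <- expr_to_matrix(logcpm)
  if (nrow(m) < 2L) abort("variance shrinkage needs at least 2 features")
  grp <- sample_groups(samples, colnames(m))
  bad <- setdiff(unique(grp), c("tumor", "normal"))
  if (length(bad) > 0) abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  n1 <- sum(grp == "tumor"); n2 <- sum(grp == "normal")
  if (n1 < 2L || n2 < 2L) abort("need at least 2 samples per group")
  d <- n1 + n2 - 2L
  if (d < 1L) abort("zero residual degrees of freedom")

  mt <- m[, grp == "tumor", drop = FALSE]
  mn <- m[, grp == "normal", drop = FALSE]
  mean_t <- rowMeans(mt)
  mean_n <- rowMeans(mn)
  logfc <- mean_t - mean_n
  ss <- rowSums((mt - mean_t)^2) + rowSums((mn - mean_n)^2)
  s2 <- pmax(ss / d, 1e-12)  # floor guards all-constant features

  eb <- squeeze_variances(s2, d)
  se <- sqrt(eb$s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(logfc == 0, 0, logfc / se)
  df_total <- min(eb$df_prior + d, length(s2) * d)
  p <- 2 * pt(-abs(tstat), df = df_total)

  out <- tibble(
    feature_id = rownames(m),
    logFC = unname(logfc),
    t = unname(tstat),
    p_value = unname(p)
  )
  structure(out,
            class = c("moderated_fit", class(out)),
            df_prior = eb$df_prior, s2_prior = eb$s2_prior,
            df_residual = d, df_total = df_total)
}

# Method-of-moments fit of the scaled inverse-chi-square prior on the
# residual variances, on the log scale.
squeeze_variances <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    df_prior <- Inf
    s2_prior <- exp(emean)
    s2_post <- rep(s2_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + d * s2) / (df_prior + d)
  }
  list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
}

# Newton solve of trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Call differentially expressed features
#'
#' Benjamini-Hochberg adjustment over all tested features, then the
#' two-threshold rule: `up` when `logFC > lfc_threshold` and
#' `fdr < fdr_threshold`, `down` when `logFC < -lfc_threshold` and
#' `fdr < fdr_threshold`, `ns` otherwise.
#'
#' @param fit A [moderated_t_test()] result (or any tibble with `feature_id`,
#'   `logFC`, `t`, `p_value`).
#' @param biotypes Optional tibble (`feature_id`, `biotype`) joined onto the
#'   result.
#' @param lfc_threshold Absolute log2-fold-change gate.
#' @param fdr_threshold FDR gate.
#' @return A `de_result` tibble with columns `feature_id`, (`biotype`,)
#'   `logFC`, `t`, `p_value`, `fdr`, `status`.
#' @export
call_differential <- function(fit, biotypes = NULL,
                              lfc_threshold = 1, fdr_threshold = 0.01) {
  stopifnot(all(c("feature_id", "logFC", "p_value") %in% names(fit)))
  if (any(fit$p_value < 0 | fit$p_value > 1)) abort("p-values must lie in [0, 1]")
  out <- as_tibble(fit)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$status <- dplyr::case_when(
    out$logFC > lfc_threshold & out$fdr < fdr_threshold ~ "up",
    out$logFC < -lfc_threshold & out$fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  )
  if (!is.null(biotypes)) {
    out <- dplyr::left_join(out, biotypes[c("feature_id", "biotype")],
                            by = "feature_id")
    out <- dplyr::relocate(out, "biotype", .after = "feature_id")
  }
  class(out) <- c("de_result", class(tibble()))
  out
}

#' Differential-expression counts per biotype
#'
#' Summarises a [call_differential()] table into up/down counts per biotype,
#' the layout in which multi-cohort DE screens are usually reported.
#'
#' @param de A `de_result` tibble carrying a `biotype` column.
#' @return Tibble with columns `biotype`, `up`, `down`.
#' @export
count_de_by_biotype <- function(de) {
  stopifnot("biotype" %in% names(de))
  de |>
    dplyr::filter(.data$status != "ns") |>
    dplyr::count(.data$biotype, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    (\(x) {
      for (col in c("up", "down")) if (!col %in% names(x)) x[[col]] <- 0L
      x[c("biotype", "up", "down")]
    })()
}
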