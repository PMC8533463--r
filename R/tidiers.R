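# broom-style tidiers for the package's fitted objects.

#' Tidy a moderated-t fit
#'
#' @param x A [moderated_t_test()] result.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature_id`, `logFC`, `t`,
#'   `p_value`.
#' @export
tidy.moderated_fit <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' Glance at a moderated-t fit
#'
#' @inheritParams tidy.moderated_fit
#' @return One-row tibble: `n_features`, `df_prior`, `s2_prior`,
#'   `df_residual`, `df_total`.
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    df_prior = attr(x, "df_prior"),
    s2_prior = attr(x, "s2_prior"),
    df_residual = attr(x, "df_residual"),
    df_total = attr(x, "df_total")
  )
}

#' Tidy a logrank test
#'
#' @param x A [logrank_test()] result.
#' @param ... Unused.
#' @return One-row tibble: `chi2`, `df`, `p_value`, `hazard_ratio`, `n_low`,
#'   `n_high`, `obs_low`, `obs_high`, `exp_low`, `exp_high`.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(
    chi2 = x$chi2, df = x$df, p_value = x$p_value,
    hazard_ratio = x$hazard_ratio,
    n_low = x$n_low, n_high = x$n_high,
    obs_low = x$obs[["low"]], obs_high = x$obs[["high"]],
    exp_low = x$exp[["low"]], exp_high = x$exp[["high"]]
  )
}

#' @rdname tidy.logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy.logrank_test(x)
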