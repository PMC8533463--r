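#' Median split of an expression profile
#'
#' Labels samples `low` when their value is at or below the median and
#' `high` when strictly above (ties go to the low group, which keeps the
#' split deterministic).
#'
#' @param values Numeric vector (>= 4 samples).
#' @return Character vector of `"low"` / `"high"` labels, named like
#'   `values` if it carries names.
#' @export
#' @examples
#' median_split(c(1, 2, 2, 3))  # low, low, low, high
median_split <- function(values) {
  if (length(values) < 4L) abort("median split needs at least 4 samples")
  if (any(!is.finite(values))) abort("median split requires finite values")
  med <- median(values)
  out <- ifelse(values <= med, "low", "high")
  if (all(out == "low")) abort("degenerate split: expression is constant")
  names(out) <- names(values)
  out
}

as_surv_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("time", "event", "group") %in% names(table)))
  if (any(table$time < 0)) abort("follow-up times must be nonnegative")
  if (!all(table$event %in% c(0L, 1L))) abort("event indicator must be 0/1")
  if (!all(table$group %in% c("low", "high"))) {
    abort("group labels must be 'low'/'high'")
  }
  table
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function per expression group:
#' at each distinct event time the curve is multiplied by
#' `1 - d_j / n_j` (events over at-risk). Computed via
#' [survival::survfit()].
#'
#' @param table Survival tibble with columns `time`, `event` (1 = event,
#'   0 = censored) and `group` (`low`/`high`); both groups may also be a
#'   single group.
#' @return A `km_fit` tibble with columns `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`. Plot with [autoplot()].
#' @export
km_curve <- function(table) {
  table <- as_surv_table(table)
  fits <- lapply(split(table, table$group), function(tb) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tb)
    tibble(group = tb$group[1], time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  })
  out <- dplyr::bind_rows(fits)
  class(out) <- c("km_fit", class(tibble()))
  out
}

#' Logrank (Mantel-Haenszel) test with an O/E hazard ratio
#'
#' Compares the event pattern of the `low` and `high` groups by accumulating
#' observed and expected events (and their hypergeometric variance) over the
#' distinct event times. The statistic `(O - E)^2 / V` is chi-square with
#' one degree of freedom; the hazard ratio of high versus low is the ratio
#' of the groups' observed/expected ratios,
#' `(O_high / E_high) / (O_low / E_low)`. Computed via
#' [survival::survdiff()]. Since only event ranks enter, the result is
#' invariant under strictly monotone transformations of time.
#'
#' @inheritParams km_curve
#' @return A `logrank_test` object: list with `chi2`, `df` (= 1), `p_value`,
#'   `hazard_ratio` (high vs low), `n_low`, `n_high`, `obs`, `exp`.
#'   [tidy()] and [glance()] return it as a one-row tibble.
#' @export
logrank_test <- function(table) {
  table <- as_surv_table(table)
  if (length(unique(table$group)) < 2L) abort("both groups must be nonempty")
  if (sum(table$event) < 1L) abort("need at least one event")
  table$group <- factor(table$group, levels = c("low", "high"))
  sdiff <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group, data = table),
    error = function(e) abort(paste0("logrank test undefined: ", conditionMessage(e)))
  )
  v <- if (is.matrix(sdiff$var)) sdiff$var[1, 1] else sdiff$var[1]
  if (!is.finite(sdiff$chisq) || v <= 0) {
    abort("logrank test undefined: zero total variance across risk sets")
  }
  obs <- as.numeric(sdiff$obs)
  expd <- as.numeric(sdiff$exp)
  hr <- if (all(expd > 0) && obs[1] > 0) {
    (obs[2] / expd[2]) / (obs[1] / expd[1])
  } else {
    NA_real_
  }
  structure(
    list(
      chi2 = unname(sdiff$chisq), df = 1L,
      p_value = pchisq(unname(sdiff$chisq), df = 1, lower.tail = FALSE),
      hazard_ratio = hr,
      n_low = sum(table$group == "low"), n_high = sum(table$group == "high"),
      obs = setNames(obs, c("low", "high")),
      exp = setNames(expd, c("low", "high"))
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Logrank test: chi2 =", format(x$chi2, digits = 4),
      "(1 df), p =", format(x$p_value, digits = 4),
      "| HR (high vs low) =", format(x$hazard_ratio, digits = 4), "\n")
  invisible(x)
}

#' Median-split prognostic screen over shared-network features
#'
#' For every feature and cohort: tumor samples are split at the median
#' expression, survival of the two groups is compared by [logrank_test()],
#' and rows with `p < alpha` are reported. The `direction` column names the
#' expression group (`low`/`high`) with the better survival, i.e. the group
#' whose observed/expected event ratio is smaller. A feature is prognostic
#' when it is significant in at least one cohort.
#'
#' @param features Character vector of feature ids to screen.
#' @param cohorts Named list; each element a list with `expression` (wide
#'   log2-CPM tibble or matrix over tumor samples, genes and/or miRNAs) and
#'   `clinical` (tibble `sample_id`, `time`, `event`).
#' @param alpha Significance gate on the logrank p-value.
#' @return Tibble `cohort`, `feature_id`, `n_low`, `n_high`, `hazard_ratio`,
#'   `chi2`, `p_value`, `direction`, restricted to significant rows.
#' @export
prognostic_screen <- function(features, cohorts, alpha = 0.05) {
  features <- unique(features)
  rows <- list()
  n_skipped <- 0L
  for (lb in names(cohorts)) {
    expr <- expr_to_matrix(cohorts[[lb]]$expression)
    clin <- cohorts[[lb]]$clinical
    stopifnot(all(c("sample_id", "time", "event") %in% names(clin)))
    common <- intersect(colnames(expr), clin$sample_id)
    clin <- clin[match(common, clin$sample_id), , drop = FALSE]
    for (f in features) {
      if (!f %in% rownames(expr)) {
        n_skipped <- n_skipped + 1L
        next
      }
      x <- expr[f, common]
      grp <- tryCatch(median_split(x), error = function(e) NULL)
      if (is.null(grp)) {
        n_skipped <- n_skipped + 1L
        next
      }
      tab <- tibble(time = clin$time, event = clin$event, group = unname(grp))
      lr <- tryCatch(logrank_test(tab), error = function(e) NULL)
      if (is.null(lr)) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble(
        cohort = lb, feature_id = f,
        n_low = lr$n_low, n_high = lr$n_high,
        hazard_ratio = lr$hazard_ratio, chi2 = lr$chi2, p_value = lr$p_value,
        direction = if (is.na(lr$hazard_ratio)) NA_character_ else
          if (lr$hazard_ratio < 1) "high" else "low"
      )
    }
  }
  if (n_skipped > 0L) {
    warn(paste0("prognostic_screen: skipped ", n_skipped,
                " feature-cohort combination(s) (absent, constant, or test undefined)"))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(cohort = character(), feature_id = character(),
                  n_low = integer(), n_high = integer(),
                  hazard_ratio = numeric(), chi2 = numeric(),
                  p_value = numeric(), direction = character()))
  }
  dplyr::arrange(out[out$p_value < alpha, , drop = FALSE],
                 .data$cohort, .data$p_value)
}
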