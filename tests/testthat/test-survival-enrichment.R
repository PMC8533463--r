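test_that("median split applies the tie-to-low rule", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_equal(unname(median_split(c(1, 2, 2, 3))), c("low", "low", "low", "high"))
  expect_error(median_split(rep(5, 6)), "constant")
  expect_error(median_split(c(1, 2, 3)), "at least 4")
})

test_that("Kaplan-Meier curves match hand-computed product limits", {
  # all censored: survival stays at 1
  all_cens <- tibble::tibble(time = 1:4, event = 0L, group = "low")
  expect_true(all(km_curve(all_cens)$surv == 1))
  # two subjects, events at 1 and 2
  two <- tibble::tibble(time = c(1, 2), event = 1L, group = "low")
  km <- km_curve(two)
  expect_equal(km$surv, c(0.5, 0))
  # n = 5 with censoring: events at 1, 3; censored at 2, 4, 5
  five <- tibble::tibble(time = c(1, 2, 3, 4, 5),
                         event = c(1L, 0L, 1L, 0L, 0L), group = "low")
  km5 <- km_curve(five)
  expect_equal(km5$surv[km5$time == 1], 4 / 5)
  expect_equal(km5$surv[km5$time == 3], 8 / 15, tolerance = 1e-12)
})

test_that("Kaplan-Meier equals a brute-force product over risk sets", {
  brute_km <- function(time, event, at) {
    s <- 1
    for (tj in sort(unique(time[event == 1]))) {
      if (tj > at) break
      d <- sum(time == tj & event == 1)
      n <- sum(time >= tj)
      s <- s * (1 - d / n)
    }
    s
  }
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    tb <- tibble::tibble(time = round(rexp(n), 2),
                         event = rbinom(n, 1, 0.7), group = "low")
    if (sum(tb$event) == 0) next
    km <- km_curve(tb)
    for (r in seq_len(nrow(km))) {
      expect_equal(km$surv[r], brute_km(tb$time, tb$event, km$time[r]),
                   tolerance = 1e-12)
    }
  }
})

test_that("logrank matches the worked example and its symmetry/invariance properties", {
  # identical event patterns in both groups
  same <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = rep(1L, 6),
                         group = rep(c("low", "high"), each = 3))
  lr0 <- logrank_test(same)
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)
  expect_equal(lr0$hazard_ratio, 1)
  # low group events at (1, 2); high group events at (1.5, 3); no censoring
  tb <- tibble::tibble(time = c(1, 2, 1.5, 3), event = 1L,
                       group = c("low", "low", "high", "high"))
  lr <- logrank_test(tb)
  expect_equal(lr$chi2, 8 / 13, tolerance = 1e-12)
  expect_equal(lr$obs[["low"]], 2)
  expect_equal(lr$exp[["low"]], 4 / 3, tolerance = 1e-12)
  # HR of the early-event (low) group vs the other is 2
  expect_equal(1 / lr$hazard_ratio, 2, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE))
  # doubling every time (unit change) and any monotone transform change nothing
  tb2 <- tb; tb2$time <- tb$time * 2
  tb3 <- tb; tb3$time <- exp(tb$time)
  expect_equal(tidy(logrank_test(tb2)), tidy(logrank_test(tb)))
  expect_equal(tidy(logrank_test(tb3)), tidy(logrank_test(tb)))
})

test_that("degenerate survival inputs are rejected", {
  one_group <- tibble::tibble(time = c(1, 2), event = 1L, group = "low")
  expect_error(logrank_test(one_group), "both groups")
  no_event <- tibble::tibble(time = c(1, 2), event = 0L,
                             group = c("low", "high"))
  expect_error(logrank_test(no_event), "event")
  # the only event happens when a single subject remains at risk
  undef <- tibble::tibble(time = c(0.5, 1), event = c(0L, 1L),
                          group = c("low", "high"))
  expect_error(logrank_test(undef), "undefined")
})

test_that("logrank holds its nominal size under a null median split", {
  set.seed(51)
  rej <- 0
  n_rep <- 400
  for (b in seq_len(n_rep)) {
    grp <- median_split(rnorm(40))
    ev <- rexp(40)
    cn <- rexp(40, 3 / 7)
    tab <- tibble::tibble(time = pmin(ev, cn), event = as.integer(ev <= cn),
                          group = unname(grp))
    if (logrank_test(tab)$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.025)
  expect_lte(rej / n_rep, 0.075)
})

test_that("the prognostic screen finds planted hazards with the right direction", {
  study <- get_default_study()
  truth <- study$truth$planted_prognostic
  cohorts <- lapply(study$cohorts, function(co) {
    g <- filter_low_expressed(log_cpm(co$gene_counts, tmm_factors(co$gene_counts)))
    m <- filter_low_expressed(log_cpm(co$mirna_counts, tmm_factors(co$mirna_counts)))
    tum <- co$samples$sample_id[co$samples$group == "tumor"]
    list(expression = rbind(cernet:::expr_to_matrix(g)[, tum],
                            cernet:::expr_to_matrix(m)[, tum]),
         clinical = co$clinical)
  })
  sc <- suppressWarnings(prognostic_screen(unique(truth$feature_id), cohorts))
  # every planted prognostic feature significant in at least one cohort
  expect_setequal(unique(sc$feature_id), unique(truth$feature_id))
  # direction semantics: higher expression -> higher hazard means the
  # low-expression group survives better
  mg <- dplyr::inner_join(sc, truth, by = c("cohort", "feature_id"))
  expect_gt(nrow(mg), 0)
  expect_true(all((mg$hazard_direction == "up") == (mg$direction == "low")))
  # an absent feature is skipped with a warning, not an error
  expect_warning(prognostic_screen("NOT-A-FEATURE", cohorts), "skipped")
})

test_that("over-representation uses the exact hypergeometric tail", {
  sets <- tibble::tibble(set_id = c("hit", "none"),
                         description = "",
                         members = list(paste0("g", 1:5), paste0("g", 50:54)))
  universe <- paste0("g", 1:20)
  res <- ora_enrich(paste0("g", c(1:4, 10)), sets, universe)
  hit <- res[res$set_id == "hit", ]
  expect_equal(hit$overlap, 4L)
  expect_equal(hit$p_value,
               (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hit$p_value, 76 / 15504, tolerance = 1e-12)
  # zero overlap after universe restriction: p = 1
  expect_equal(res$p_value[res$set_id == "none"], 1)
  # degenerate: query is the whole universe and the whole set
  deg <- ora_enrich(paste0("g", 1:5),
                    tibble::tibble(set_id = "s", members = list(paste0("g", 1:5))),
                    universe = paste0("g", 1:5))
  expect_equal(deg$p_value, 1)
  expect_error(ora_enrich("g1", sets, character()), "universe")
  expect_error(ora_enrich("not-there", sets, universe), "subset")
  # kernel identity with the pair-level test
  expect_equal(hit$p_value, hypergeom_pvalue(4, N = 20, n = 5, K = 5),
               tolerance = 1e-15)
})
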