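make_counts <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("TMM factors are 1 for identical and purely depth-scaled libraries", {
  a <- c(5, 10, 20, 40, 80, 7, 13, 55)
  same <- make_counts(cbind(a, a, a))
  expect_equal(tmm_factors(same)$norm_factor, rep(1, 3))
  # column B = 2 * column A elementwise: all M values are zero once library
  # size is divided out, so the composition factors are exactly 1 and the
  # depth difference is carried by the effective library sizes instead
  scaled <- make_counts(cbind(A = a, B = 2 * a))
  expect_equal(tmm_factors(scaled)$norm_factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the reference implementation and is permutation-equivariant", {
  skip_if_not_installed("edgeR")
  set.seed(20)
  for (rep in 1:5) {
    m <- make_counts(matrix(rnbinom(50 * 6, mu = exp(runif(300, 2, 6)), size = 5),
                            nrow = 50))
    f <- tmm_factors(m)
    ref <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(f$norm_factor, unname(ref), tolerance = 1e-8)
    perm <- sample(ncol(m))
    fp <- tmm_factors(m[, perm])
    expect_equal(fp$norm_factor, f$norm_factor[perm], tolerance = 1e-12)
    expect_equal(exp(mean(log(f$norm_factor))), 1, tolerance = 1e-12)
  }
})

test_that("an all-zero library is rejected by name", {
  m <- make_counts(cbind(a = c(1, 2, 3), b = c(0, 0, 0)))
  expect_error(tmm_factors(m), "b")
})

test_that("log-CPM matches its closed form", {
  # single zero count in a library of 1e6
  m <- matrix(c(0, 999999, 1), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  lc <- cernet:::expr_to_matrix(log_cpm(m, c(s1 = 1)))
  expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["g1", "s1"], -1.0000014, tolerance = 1e-6)
  # direct hand evaluation on a 3x3 matrix with factors
  m3 <- make_counts(matrix(c(10, 20, 30, 5, 0, 95, 40, 40, 20), nrow = 3))
  f <- c(s1 = 1.2, s2 = 0.8, s3 = 1)
  lc3 <- cernet:::expr_to_matrix(log_cpm(m3, f))
  lib <- colSums(m3) * f
  for (i in 1:3) for (j in 1:3) {
    expect_equal(lc3[i, j], unname(log2((m3[i, j] + 0.5) / (lib[j] + 1) * 1e6)),
                 tolerance = 1e-12)
  }
  # monotone in the count within a fixed column
  expect_true(all(diff(order(lc3[, 1])) == diff(order(m3[, 1]))))
  expect_error(log_cpm(m3, c(1, 2)), "does not match")
})

test_that("the low-expression filter applies the strict majority rule", {
  mk <- function(n_below) {
    make_counts(matrix(c(rep(0.5, n_below), rep(2, 10 - n_below)), nrow = 1))
  }
  expect_equal(nrow(filter_low_expressed(mk(6))), 0L)  # 6/10 below: removed
  expect_equal(nrow(filter_low_expressed(mk(5))), 1L)  # exactly half: kept
  expect_equal(nrow(filter_low_expressed(mk(0))), 1L)  # all above: kept
})

test_that("moderated t reduces to sensible limits", {
  samples <- tibble::tibble(sample_id = paste0("s", 1:8),
                            group = rep(c("tumor", "normal"), each = 4))
  # identical per-group values, equal means: logFC = 0, t = 0, p = 1
  row <- c(3, 3, 3, 3, 3, 3, 3, 3)
  m <- make_counts(rbind(row, row, row))
  fit <- moderated_t_test(m, samples)
  expect_equal(fit$logFC, rep(0, 3))
  expect_equal(fit$t, rep(0, 3))
  expect_equal(fit$p_value, rep(1, 3))
  # all gene variances equal: prior df estimated infinite, moderated t equals
  # the ordinary t with the common pooled variance
  set.seed(30)
  base <- matrix(rnorm(5 * 8), nrow = 5)
  delta <- c(1, -1, 1, -1)
  m2 <- make_counts(t(apply(matrix(rnorm(5 * 2), ncol = 2), 1, function(mu) {
    c(mu[1] + delta / 2, mu[2] + delta / 2)  # per-group variance identical
  })))
  fit2 <- moderated_t_test(m2, samples)
  expect_equal(glance(fit2)$df_prior, Inf)
  s2_common <- glance(fit2)$s2_prior
  ord_t <- fit2$logFC / sqrt(s2_common * (1 / 4 + 1 / 4))
  expect_equal(fit2$t, ord_t, tolerance = 1e-10)
})

test_that("moderated t agrees with the independent empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(31)
  m <- make_counts(matrix(rnorm(200 * 12, sd = rep(sqrt(rchisq(200, 4) / 4), 12)),
                          nrow = 200))
  m[1:20, 1:6] <- m[1:20, 1:6] + 1.5
  samples <- tibble::tibble(sample_id = paste0("s", 1:12),
                            group = rep(c("tumor", "normal"), each = 6))
  fit <- moderated_t_test(m, samples)
  design <- cbind(intercept = 1, tumor = rep(c(1, 0), each = 6))
  ref <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$logFC, unname(ref$coefficients[, "tumor"]), tolerance = 1e-10)
  expect_equal(fit$t, unname(ref$t[, "tumor"]), tolerance = 1e-8)
  expect_equal(fit$p_value, unname(ref$p.value[, "tumor"]), tolerance = 1e-8)
  expect_equal(glance(fit)$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(glance(fit)$s2_prior, ref$s2.prior, tolerance = 1e-8)
})

test_that("moderated t holds its nominal size on simulated null data", {
  set.seed(32)
  m <- make_counts(matrix(rnorm(2000 * 20, sd = rep(sqrt(rchisq(2000, 6) / 6), 20)),
                          nrow = 2000))
  samples <- tibble::tibble(sample_id = paste0("s", 1:20),
                            group = rep(c("tumor", "normal"), each = 10))
  fit <- moderated_t_test(m, samples)
  rate <- mean(fit$p_value < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("BH adjustment equals its brute-force definition", {
  # hand example
  fit <- tibble::tibble(feature_id = paste0("g", 1:4),
                        logFC = c(2, 2, 2, 2), t = 1,
                        p_value = c(0.01, 0.02, 0.03, 0.04))
  de <- call_differential(fit)
  expect_equal(de$fdr, rep(0.04, 4))
  # brute force: min over j >= i of p(j) * m / j, mapped back to input order
  set.seed(33)
  p <- runif(200)^2
  brute <- {
    o <- order(p)
    ps <- p[o]
    mfac <- length(p) / seq_along(ps)
    adj <- rev(cummin(rev(ps * mfac)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(p.adjust(p, method = "BH"), brute, tolerance = 1e-12)
  expect_true(all(brute >= 0 & brute <= 1))
})

test_that("differential status obeys both the fold-change and FDR gates", {
  fit <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    logFC = c(0.9, -2, 1.5, 3),
    t = c(5, -5, 5, 0.1),
    p_value = c(1e-6, 1e-6, 1e-6, 0.9)
  )
  de <- call_differential(fit)
  expect_equal(de$status, c("ns", "down", "up", "ns"))
  # invariant: status == up iff logFC > 1 and fdr < 0.01
  expect_equal(de$status == "up", de$logFC > 1 & de$fdr < 0.01)
  expect_equal(de$status == "down", de$logFC < -1 & de$fdr < 0.01)
  bio <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        biotype = c("mRNA", "mRNA", "lncRNA", "miRNA"))
  counts <- count_de_by_biotype(call_differential(fit, bio))
  expect_equal(counts$up[counts$biotype == "lncRNA"], 1L)
  expect_equal(counts$down[counts$biotype == "mRNA"], 1L)
})
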