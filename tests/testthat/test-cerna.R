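# Exact finite-sum evaluation of the upper-tail hypergeometric probability,
# written directly from the counting definition (independent of phyper).
hyper_tail_oracle <- function(m, N, n, K) {
  if (m <= 0) return(1)
  ks <- m:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("hypergeometric p-value matches worked examples and boundaries", {
  expect_equal(hypergeom_pvalue(0, N = 10, n = 4, K = 5), 1)
  expect_equal(hypergeom_pvalue(3, N = 10, n = 4, K = 5), 55 / 210,
               tolerance = 1e-12)
  # full universe on both sides: the shared count is deterministic
  expect_equal(hypergeom_pvalue(7, N = 7, n = 7, K = 7), 1)
  # the inclusive-upper-limit variant is P(X > m)
  expect_equal(hypergeom_pvalue(3, 10, 4, 5, as_printed = TRUE),
               hypergeom_pvalue(4, 10, 4, 5), tolerance = 1e-12)
  expect_error(hypergeom_pvalue(5, N = 10, n = 4, K = 5), "domain")
  expect_error(hypergeom_pvalue(1, N = 3, n = 4, K = 2), "domain")
})

test_that("hypergeometric p-value equals subset-enumeration for small universes", {
  # exhaustive draw enumeration at a handful of (N, n, K): count, over all
  # C(N, n) sponge target sets, how many share >= m miRNAs with a fixed
  # K-element target set
  for (N in c(5, 8, 9)) {
    for (n in 1:N) {
      draws <- utils::combn(N, n)
      for (K in 1:N) {
        overlap <- colSums(draws <= K)
        for (m in 0:min(n, K)) {
          expect_equal(hypergeom_pvalue(m, N, n, K), mean(overlap >= m),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("candidate pairs are screened by shared count and BH-adjusted", {
  # toy universe of 10 miRNAs; one heavily shared planted pair among decoys
  edges <- tibble::tibble(
    mirna_id = c(paste0("mir-", 1:6), paste0("mir-", 1:6),  # planted pair
                 "mir-7", "mir-8", "mir-8", "mir-9", "mir-10"),
    target_id = c(rep("SPONGE-A", 6), rep("TARGET-A", 6),
                  "SPONGE-B", "SPONGE-B", "TARGET-B", "TARGET-B", "TARGET-C")
  )
  map <- interaction_map(edges, mirna_ids = paste0("mir-", 1:10))
  pairs <- candidate_pairs(c("SPONGE-A", "SPONGE-B"),
                           c("TARGET-A", "TARGET-B", "TARGET-C"),
                           map, fdr_threshold = NULL)
  # disjoint pair SPONGE-A x TARGET-B is never tested
  expect_false(any(pairs$sponge_id == "SPONGE-A" & pairs$mrna_id == "TARGET-B"))
  planted <- pairs[pairs$sponge_id == "SPONGE-A" & pairs$mrna_id == "TARGET-A", ]
  expect_equal(planted$m, 6L)
  expect_equal(planted$hyper_p, min(pairs$hyper_p))
  expect_equal(planted$hyper_p,
               hyper_tail_oracle(6, 10, 6, 6), tolerance = 1e-12)
  # single tested pair: fdr equals p
  single <- candidate_pairs("SPONGE-B", "TARGET-B", map, fdr_threshold = NULL)
  expect_equal(single$hyper_fdr, single$hyper_p)
  # empty inputs give an empty result, not an error
  expect_equal(nrow(candidate_pairs(character(), "TARGET-A", map)), 0L)
})

test_that("the Pearson filter keeps strictly positive correlations above the gate", {
  x <- c(2, 1, 0, -1, -2)
  e <- c(1, -2, 0, 2, -1)           # centered, orthogonal to x
  m <- rbind(S1 = x + 10, T1 = x + 10,          # r = 1
             S2 = 3 * x + 4 * e, T2 = x,        # r(S2, T2) = 0.6 exactly
             S3 = -x, T3 = x)                   # r = -1
  colnames(m) <- paste0("s", 1:5)
  mk_pairs <- function(s, t) {
    tibble::tibble(sponge_id = s, mrna_id = t, m = 1L, n = 1L, K = 1L, N = 1L,
                   hyper_p = 0.01, hyper_fdr = 0.01,
                   shared_mirnas = list("mir-1"))
  }
  expect_equal(pearson_pair_filter(mk_pairs("S1", "T1"), m)$pearson_r, 1)
  # boundary: r exactly equal to the gate is dropped (strict inequality)
  expect_equal(nrow(pearson_pair_filter(mk_pairs("S2", "T2"), m, min_r = 0.6)), 0L)
  expect_equal(nrow(pearson_pair_filter(mk_pairs("S2", "T2"), m, min_r = 0.59)), 1L)
  expect_equal(nrow(pearson_pair_filter(mk_pairs("S3", "T3"), m)), 0L)
  # zero-variance member: dropped with a warning
  m2 <- rbind(m, Z = rep(5, 5))
  expect_warning(out <- pearson_pair_filter(mk_pairs("Z", "T1"), m2),
                 "zero-variance")
  expect_equal(nrow(out), 0L)
})

test_that("partial correlation matches the closed form and the precision-matrix route", {
  skip_if_not_installed("MASS")
  # exact sample correlations via empirical = TRUE
  sigma <- matrix(c(1, 0.6, 0.5,
                    0.6, 1, 0.5,
                    0.5, 0.5, 1), nrow = 3)
  d <- MASS::mvrnorm(50, mu = c(0, 0, 0), Sigma = sigma, empirical = TRUE)
  pc <- partial_correlation(d[, 1], d[, 2], d[, 3])
  expect_equal(pc, (0.6 - 0.25) / sqrt(0.75 * 0.75), tolerance = 1e-10)
  st <- mscor_statistic(d[, 1], d[, 2], d[, 3, drop = FALSE])
  expect_equal(st$mscor, 0.6 - 0.4666667, tolerance = 1e-6)
  expect_equal(st$mscor, st$cor - st$pcor)   # identity, exact
  expect_equal(st$i, 1L)

  # residual-regression route vs inversion of the (2 + i) correlation matrix
  set.seed(40)
  for (rep in 1:25) {
    n <- 50
    i <- sample(1:5, 1)
    z <- matrix(rnorm(n * i), nrow = n)
    x <- as.numeric(rnorm(n) + z %*% runif(i, -1, 1))
    y <- as.numeric(rnorm(n) + z %*% runif(i, -1, 1))
    pc1 <- partial_correlation(x, y, z)
    cm <- cor(cbind(x, y, z))
    prec <- solve(cm)
    pc2 <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
    expect_equal(pc1, pc2, tolerance = 1e-10)
    expect_true(abs(pc1) <= 1)
  }
})

test_that("degenerate controls raise a collinearity error", {
  x <- rnorm(20)
  y <- rnorm(20)
  expect_error(partial_correlation(x, y, cbind(mirA = x, mirB = x)),
               "collinear")
  expect_error(partial_correlation(x, y, matrix(rnorm(20 * 18), nrow = 20)),
               "samples")
})

test_that("mscor vanishes for independent controls and is affine-invariant", {
  set.seed(41)
  n <- 1000
  g1 <- rnorm(n); g2 <- 0.5 * g1 + rnorm(n)
  z <- matrix(rnorm(n * 3), nrow = n)
  st <- mscor_statistic(g1, g2, z)
  expect_lt(abs(st$mscor), 0.05)
  # invariance under separate affine rescaling of g1, g2, and the controls
  st2 <- mscor_statistic(3 * g1 - 7, -0.5 * g2 + 2, z %*% diag(c(2, -4, 0.1)))
  expect_equal(abs(st2$mscor), abs(st$mscor), tolerance = 1e-10)
  expect_equal(st2$cor, -st$cor, tolerance = 1e-10)
  # bounds: mscor within [cor - 1, cor + 1]
  expect_true(st$mscor <= st$cor + 1 && st$mscor >= st$cor - 1)
})

test_that("empirical p-values respect the add-one estimator bounds", {
  res <- tibble::tibble(cor = c(0.05, 0.05), mscor = c(10, -10),
                        i = c(2L, 2L), n_samples = c(30L, 30L))
  out <- mscor_null_pvalues(res, null_samples = 200, seed = 1)
  expect_equal(out$empirical_p[1], 1 / 201)    # larger than every null draw
  expect_equal(out$empirical_p[2], 1)          # smaller than every null draw
  expect_warning(mscor_null_pvalues(res, null_samples = 50, seed = 1),
                 "unstable")
})

test_that("empirical p-values are uniform when the observations come from the null", {
  # self-consistency: observed statistics drawn from the null model itself
  set.seed(42)
  n <- 60
  obs <- purrr::map_dfr(1:200, function(b) {
    rho <- runif(1, -0.2, 0.2)
    i <- sample(1:4, 1)
    g1 <- rnorm(n)
    g2 <- rho * g1 + sqrt(1 - rho^2) * rnorm(n)
    z <- matrix(rnorm(n * i), nrow = n)
    mscor_statistic(g1, g2, z)
  })
  out <- mscor_null_pvalues(obs, null_samples = 400, seed = 43)
  ks <- suppressWarnings(stats::ks.test(out$empirical_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  rate <- mean(out$empirical_p < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.09)
})

test_that("network inference recovers planted triplets and every emitted triplet re-passes its gates", {
  study <- get_small_study()
  nets <- study_networks(study, "small")
  net <- nets[[1]]
  expect_gt(nrow(net), 0)
  # a planted pair surviving all filters emits one triplet per shared miRNA
  planted <- attr(study$map, "planted")
  for (k in which(planted$shared)) {
    rows <- net[net$sponge_id == planted$sponge_id[k] &
                  net$mrna_id == planted$mrna_id[k], ]
    if (nrow(rows) > 0) {
      expect_equal(nrow(rows), study$config$shared_mre_count)
      expect_setequal(rows$mirna_id, planted$mirnas[[k]])
    }
  }
  # post-hoc audit of the three thresholds on the reported statistics
  expect_true(all(net$hyper_fdr < 0.05))
  expect_true(all(net$pearson_r > 0.4))
  expect_true(all(net$adjusted_p < 0.05))
  expect_equal(net$mscor, net$cor - net$pcor)
  # m is the size of the map-level shared set, re-derived independently
  for (r in seq_len(min(nrow(net), 10))) {
    shared <- intersect(mirnas_of(study$map, net$sponge_id[r]),
                        mirnas_of(study$map, net$mrna_id[r]))
    expect_equal(net$m[r], length(shared))
    expect_equal(net$hyper_p[r],
                 hyper_tail_oracle(net$m[r], net$N[r], net$n[r], net$K[r]),
                 tolerance = 1e-12)
  }
  # no pair surviving: empty network, no error
  de_empty <- study$truth$planted_de[0, ]
  prep <- prep_cohort(study, names(study$cohorts)[1])
  de_none <- prep$de_genes
  de_none$status <- "ns"
  empty <- suppressMessages(infer_network(
    prep$gene_logcpm, prep$mirna_logcpm, prep$cohort$samples,
    de = de_none, map = study$map, seed = 1))
  expect_equal(nrow(empty), 0L)
})
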