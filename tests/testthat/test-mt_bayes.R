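# The Gibbs conditionals are validated against closed-form posteriors where
# they exist (the fixed-variance SNP-BLUP sub-model), and the full sampler
# against simulated truth; per-draw algebraic identities are asserted on the
# stored chain.

test_that("mcmc_config bookkeeping matches the reference protocol", {
  cfg <- mcmc_config(50000, 20000, 20)
  expect_identical(retained_samples(cfg), 1500L)
  expect_error(mcmc_config(1000, 2000, 10), "burn_in")
  expect_error(mcmc_config(1000, 100, 0), "thin")
})

test_that("with fixed variances and no shared channel the sampler reproduces the ridge posterior", {
  set.seed(42)
  n <- 30; m <- 8
  W <- matrix(rnorm(n * m), n, m)
  y1 <- drop(W %*% rnorm(m, 0, 0.5)) + rnorm(n, 2, 1)
  y2 <- drop(W %*% rnorm(m, 0, 0.5)) + rnorm(n, -1, 1)
  d1 <- runif(n, 0.5, 2); d2 <- runif(n, 0.5, 2)
  s2e <- c(1.3, 0.8); s2a <- c(0.3, 0.5)
  set.seed(99)
  core <- mtregvar:::.gibbs_core(W, W, y1, y2, d1, d2, rep(1L, m), 1L,
                                 1, 1, 1, 40000L, 5000L, 5L,
                                 FALSE, FALSE, FALSE,
                                 s2e, s2a, c(0, 0), c(0.1, 0.1), 1e12)
  # closed-form joint posterior mean of (u, a): weighted ridge regression
  oracle <- function(y, d, s2e, s2a) {
    X <- cbind(1, W)
    Rinv <- diag(1 / (d * s2e))
    prior <- diag(c(0, rep(1 / s2a, m)))
    drop(solve(t(X) %*% Rinv %*% X + prior, t(X) %*% Rinv %*% y))
  }
  o1 <- oracle(y1, d1, s2e[1], s2a[1])
  o2 <- oracle(y2, d2, s2e[2], s2a[2])
  expect_equal(mean(core$samples[, "u1"]), o1[1], tolerance = 0.02)
  expect_equal(mean(core$samples[, "u2"]), o2[1], tolerance = 0.02)
  expect_lt(max(abs(core$post_mean_a1 - o1[-1])), 0.02)
  expect_lt(max(abs(core$post_mean_a2 - o2[-1])), 0.02)
})

test_that("chains are bit-identical under a fixed seed and data", {
  sim <- tiny_world(55, n = c(60L, 60L), chr = 1L, mpc = 40L)
  mc <- fast_mcmc(55, 600, 200, 2)
  ch1 <- gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc)
  ch2 <- gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc)
  expect_identical(ch1$samples, ch2$samples)
  het1 <- gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                              sim$partition, mc)
  het2 <- gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                              sim$partition, mc)
  expect_identical(het1$samples, het2$samples)
  expect_identical(nrow(ch1$samples), as.integer(retained_samples(mc)))
})

test_that("per-draw identities hold exactly in stored chains", {
  sim <- tiny_world(66, n = c(80L, 80L), chr = 2L, mpc = 50L)
  ch <- gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                            sim$partition, fast_mcmc(66, 1200, 400, 2))
  S <- ch$samples
  for (j in seq_len(ch$n_regions)) {
    expect_equal(S[, paste0("var_a1_", j)],
                 S[, "r1"]^2 + S[, paste0("r1j_", j)]^2 + S[, "sigma2_a1"],
                 tolerance = 1e-12)
    expect_equal(S[, paste0("cov_a_", j)],
                 S[, "r1"] * S[, "r2"] +
                   S[, paste0("r1j_", j)] * S[, paste0("r2j_", j)],
                 tolerance = 1e-12)
    # Cauchy-Schwarz: |R| <= 1 whenever both variances are positive
    R <- S[, paste0("cov_", j)] /
      sqrt(S[, paste0("vg1_", j)] * S[, paste0("vg2_", j)])
    expect_true(all(abs(R) <= 1 + 1e-12))
  }
})

test_that("homogeneous sampler recovers null and positive correlation truths", {
  # zero cross-population covariance: posterior median near 0
  cfg0 <- simulation_config(effect_cor = 0, seed = 301L)
  sim0 <- simulate_dataset(cfg0)
  ch0 <- gibbs_homogeneous(sim0$panels, list(sim0$drp1, sim0$drp2),
                           mcmc_config(4000, 1500, 5, seed = 301))
  expect_lt(abs(totals_and_h2(ch0)$corr), 0.15)
  # correlation 0.6 truth recovered within posterior uncertainty
  sim6 <- simulate_dataset(simulation_config(seed = 302L))
  ch6 <- gibbs_homogeneous(sim6$panels, list(sim6$drp1, sim6$drp2),
                           mcmc_config(4000, 1500, 5, seed = 302))
  rep6 <- totals_and_h2(ch6)
  expect_lt(abs(rep6$corr - 0.6), max(0.1, 3 * rep6$corr_se))
})

test_that("heterogeneous model with one region matches the homogeneous model", {
  sim <- tiny_world(77, n = c(150L, 150L), chr = 1L, mpc = 120L,
                    region_mode = "all_snp")
  mc <- fast_mcmc(77, 3000, 1000, 4)
  hom <- gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc)
  het <- gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                             sim$partition, mc)
  th <- totals_and_h2(hom); te <- totals_and_h2(het)
  expect_lt(abs(th$va1 - te$va1), th$va1_se + te$va1_se)
  expect_lt(abs(th$va2 - te$va2), th$va2_se + te$va2_se)
  expect_lt(abs(th$cov - te$cov), th$cov_se + te$cov_se)
})

test_that("mirrored initializations of r give the same variance functionals", {
  sim <- tiny_world(88, n = c(120L, 120L), chr = 1L, mpc = 80L)
  mc_pos <- mcmc_config(2500, 1000, 3, seed = 88,
                        start = list(r = c(0.3, 0.3)))
  mc_neg <- mcmc_config(2500, 1000, 3, seed = 88,
                        start = list(r = c(-0.3, -0.3)))
  ch_p <- gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc_pos)
  ch_n <- gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc_neg)
  tp <- totals_and_h2(ch_p); tn <- totals_and_h2(ch_n)
  expect_lt(abs(tp$va1 - tn$va1), 2 * (tp$va1_se + tn$va1_se))
  expect_lt(abs(tp$cov - tn$cov), 2 * (tp$cov_se + tn$cov_se))
})

test_that("input contracts are enforced", {
  sim <- tiny_world(91, n = c(30L, 30L), chr = 1L, mpc = 20L)
  mc <- fast_mcmc(91, 200, 100, 1)
  # mismatched maps
  other <- random_panel(30, 20, seed = 1)
  expect_error(gibbs_homogeneous(list(sim$panels[[1]], other),
                                 list(sim$drp1, sim$drp2), mc),
               "harmonize")
  # partition from a different map
  foreign <- partition_regions(random_panel(5, 7, 2)$map, "all_snp")
  expect_error(gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                                   foreign, mc), "partition")
  expect_error(gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                                   NULL, mc), "requires a partition")
})

test_that("the divergence guard aborts with diagnostics", {
  sim <- tiny_world(92, n = c(30L, 30L), chr = 1L, mpc = 20L)
  mc <- mcmc_config(500, 100, 1, seed = 92, var_ceiling = 1e-9)
  expect_error(gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc),
               "divergence guard")
})

test_that("sample_deviance matches a hand-computed Gaussian log density", {
  # 5-record toy, population split 3 + 2
  res <- list(c(0.5, -1, 2), c(1, -0.5))
  w <- list(c(1, 2, 0.5), c(1, 1))
  s2 <- c(2, 0.7)
  hand <- 0
  for (i in 1:2) for (n in seq_along(res[[i]]))
    hand <- hand - 2 * dnorm(res[[i]][n], 0, sqrt(w[[i]][n] * s2[i]),
                             log = TRUE)
  expect_equal(sample_deviance(res, w, s2), hand, tolerance = 1e-12)
  # doubling sigma2_e at zero residuals shifts deviance by n log 2 per pop
  zero <- list(rep(0, 7), rep(0, 4))
  w0 <- list(rep(1, 7), rep(1, 4))
  d1 <- sample_deviance(zero, w0, c(1, 1))
  d2 <- sample_deviance(zero, w0, c(2, 1))
  expect_equal(d2 - d1, 7 * log(2), tolerance = 1e-12)
})
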