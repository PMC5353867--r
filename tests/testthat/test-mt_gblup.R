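test_that("build_grm reproduces the single-marker hand computation", {
  panel <- toy_panel(matrix(c(0, 1, 2), ncol = 1))
  grm <- build_grm(panel)
  expect_equal(grm$scaling, 0.5)                      # 2 * 0.5 * 0.5
  expect_equal(diag(grm$G), c(2, 0, 2), ignore_attr = TRUE)
  expect_equal(grm$G[1, 3], -2)
  expect_equal(grm$G, t(grm$G))
})

test_that("mean diagonal of G is near 1 under Hardy-Weinberg equilibrium", {
  panels <- simulate_genotypes(
    simulation_config(n_animals = c(400L, 400L), n_chromosomes = 1L,
                      markers_per_chr = 1000L, freq_perturb_sd = 0,
                      seed = 23L))
  grm <- build_grm(panels)
  expect_lt(abs(mean(diag(grm$G)) - 1), 0.05)
  ev <- eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))                 # PSD up to noise
})

test_that("duplicated animals give identical G rows and monomorphism errors", {
  g <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 0, 1, 1))
  grm <- build_grm(toy_panel(g))
  expect_equal(grm$G[1, ], grm$G[2, ], ignore_attr = TRUE)
  expect_equal(grm$G[, 1], grm$G[, 2], ignore_attr = TRUE)
  expect_error(build_grm(toy_panel(matrix(c(2, 2, 2), ncol = 1))),
               "monomorphic")
})

test_that("restricted likelihood differences match a contrast-space oracle on a 12-animal toy", {
  set.seed(7)
  p1 <- random_panel(6, 30, seed = 71, pop = "A")
  p2 <- random_panel(6, 30, seed = 72, pop = "B")
  rownames(p2$genotypes) <- paste0("B", 1:6)
  grm <- build_grm(list(p1, p2))
  grm$G <- grm$G + diag(0.05, 12)   # keep the toy well-conditioned
  d1 <- drp_table(rownames(p1$genotypes), rnorm(6, 5), rep(0.6, 6), "A")
  d2 <- drp_table(rownames(p2$genotypes), rnorm(6, -3), rep(0.8, 6), "B")
  y <- c(d1$drp, d2$drp)
  X <- cbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
  K <- qr.Q(qr(X), complete = TRUE)[, 3:12]   # orthonormal, K'X = 0
  oracle_rll <- function(theta) {
    V <- mtregvar:::reml_build_V(theta, list(G11 = grm$G[1:6, 1:6],
                                             G22 = grm$G[7:12, 7:12],
                                             G12 = grm$G[1:6, 7:12]),
                                 d1$weight, d2$weight, 6, 6)
    S <- crossprod(K, V %*% K)
    z <- drop(crossprod(K, y))
    -0.5 * (determinant(S)$modulus + drop(t(z) %*% solve(S, z)))
  }
  mine_rll <- function(theta) {
    V <- mtregvar:::reml_build_V(theta, list(G11 = grm$G[1:6, 1:6],
                                             G22 = grm$G[7:12, 7:12],
                                             G12 = grm$G[1:6, 7:12]),
                                 d1$weight, d2$weight, 6, 6)
    Vinv <- chol2inv(chol(V))
    XtVX <- crossprod(X, Vinv %*% X)
    P <- Vinv - Vinv %*% X %*% solve(XtVX, crossprod(X, Vinv))
    -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
              drop(t(y) %*% P %*% y))
  }
  t1 <- c(2, 0.3, 1, 1.5, 0.8)
  t2 <- c(1, -0.2, 2, 0.9, 1.4)
  # the two likelihoods differ by a parameter-free constant only
  expect_equal(mine_rll(t1) - mine_rll(t2), oracle_rll(t1) - oracle_rll(t2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("REML recovers null covariance and reports a non-decreasing likelihood", {
  panels <- simulate_genotypes(
    simulation_config(n_animals = c(250L, 250L), n_chromosomes = 2L,
                      markers_per_chr = 200L, seed = 29L))
  grm <- build_grm(panels)
  G0 <- matrix(c(50, 0, 0, 40), 2)
  simd <- simulate_gblup_dataset(grm, G0, sigma2_e = c(60, 8), seed = 29L)
  fit <- reml_bivariate(grm, list(simd$drp1, simd$drp2))
  expect_lt(abs(fit$correlation), 2 * fit$se["corr"])
  expect_true(all(diff(fit$trajectory) >= -1e-8))
  expect_false(fit$boundary)
})

test_that("non-convergence raises an error carrying the trajectory", {
  panels <- simulate_genotypes(
    simulation_config(n_animals = c(40L, 40L), n_chromosomes = 1L,
                      markers_per_chr = 50L, seed = 31L))
  grm <- build_grm(panels)
  simd <- simulate_gblup_dataset(grm, matrix(c(5, 1, 1, 4), 2),
                                 sigma2_e = c(5, 2), seed = 31L)
  err <- tryCatch(reml_bivariate(grm, list(simd$drp1, simd$drp2),
                                 max_iter = 1L, tol = 1e-12),
                  error = identity)
  expect_s3_class(err, "simpleError")
  expect_true(is.numeric(err$trajectory))
})

test_that("GEBV solutions match a dense mixed-model-equation oracle on a 12-animal toy", {
  p1 <- random_panel(6, 40, seed = 81, pop = "A")
  p2 <- random_panel(6, 40, seed = 82, pop = "B")
  rownames(p2$genotypes) <- paste0("B", 1:6)
  grm <- build_grm(list(p1, p2))
  grm$G <- grm$G + diag(0.05, 12)
  set.seed(83)
  d1 <- drp_table(rownames(p1$genotypes), rnorm(6, 2, 2), rep(0.7, 6), "A")
  d2 <- drp_table(rownames(p2$genotypes), rnorm(6, -1, 2), rep(0.9, 6), "B")
  comp <- structure(list(G0 = matrix(c(2, 0.8, 0.8, 1.5), 2),
                         sigma2_e = c(1.2, 0.6)),
                    class = "variance_components")
  gebv <- gebv_from_components(grm, comp, list(d1, d2))
  # oracle: dense MME with a = (a_trait1, a_trait2), each over all animals
  R <- diag(c(d1$weight * 1.2, d2$weight * 0.6))
  Z <- matrix(0, 12, 24)
  Z[cbind(1:6, 1:6)] <- 1          # trait-1 records on animals 1..6
  Z[cbind(7:12, 12 + 7:12)] <- 1   # trait-2 records on animals 7..12
  X <- cbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
  Ginv <- solve(comp$G0 %x% grm$G)
  y <- c(d1$drp, d2$drp)
  LHS <- rbind(cbind(t(X) %*% solve(R, X), t(X) %*% solve(R, Z)),
               cbind(t(Z) %*% solve(R, X), t(Z) %*% solve(R, Z) + Ginv))
  RHS <- c(t(X) %*% solve(R, y), t(Z) %*% solve(R, y))
  sol <- solve(LHS, RHS)
  expect_equal(gebv$gebv_trait1, unname(sol[3:14]), tolerance = 1e-8)
  expect_equal(gebv$gebv_trait2, unname(sol[15:26]), tolerance = 1e-8)
})

test_that("with diagonal G0 the trait-1 GEBV ignore trait-2 records", {
  p1 <- random_panel(5, 30, seed = 91, pop = "A")
  p2 <- random_panel(5, 30, seed = 92, pop = "B")
  rownames(p2$genotypes) <- paste0("B", 1:5)
  grm <- build_grm(list(p1, p2))
  grm$G <- grm$G + diag(0.05, 10)
  set.seed(93)
  d1 <- drp_table(rownames(p1$genotypes), rnorm(5), rep(0.6, 5), "A")
  d2a <- drp_table(rownames(p2$genotypes), rnorm(5), rep(0.6, 5), "B")
  d2b <- drp_table(rownames(p2$genotypes), rnorm(5) + 10, rep(0.6, 5), "B")
  comp <- structure(list(G0 = diag(c(2, 1)), sigma2_e = c(1, 1)),
                    class = "variance_components")
  ga <- gebv_from_components(grm, comp, list(d1, d2a))
  gb <- gebv_from_components(grm, comp, list(d1, d2b))
  expect_equal(ga$gebv_trait1, gb$gebv_trait1, tolerance = 1e-10)
  # a pop-2 animal unrelated to every pop-1 animal has trait-1 GEBV 0
  # (its only path to trait 1 is the zero G0 covariance)
  grm2 <- grm
  grm2$G[10, 1:5] <- 0; grm2$G[1:5, 10] <- 0
  g0 <- gebv_from_components(grm2, comp, list(d1, d2a))
  expect_equal(g0$gebv_trait1[10], 0, tolerance = 1e-12)
})
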