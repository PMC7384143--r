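fake_spcov <- function(Sa, Sb = Sa) {
  structure(list(Sigma_a = Sa, Sigma_b = Sb, breaks = NULL,
                 class_autocorr = NULL, n_merged = 0L),
            class = "spatial_covariance")
}

test_that("identity spatial correlation recovers the classical t-test", {
  n <- 30
  set.seed(2)
  a <- rnorm(n); b <- rnorm(n)
  res <- modified_t_test(a, b, spcov = fake_spcov(diag(n)))
  expect_equal(res$M_hat, n)
  expect_equal(res$df, n - 2)
  expect_equal(res$p, cor.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("effective sample size matches the matrix-trace oracle", {
  S <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3)
  # independent oracle: explicit centering-matrix products
  n <- 3; B <- diag(n) - matrix(1 / n, n, n)
  M_oracle <- 1 + sum(diag(B %*% S))^2 / sum(diag(B %*% S %*% B %*% S))
  expect_equal(M_oracle, 2.849057, tolerance = 1e-6)

  res <- modified_t_test(c(1, 2, 4), c(2, 1, 5), spcov = fake_spcov(S))
  expect_equal(res$M_hat, M_oracle, tolerance = 1e-12)
})

test_that("correlogram covariance estimates behave at the null and limits", {
  fac <- grf_pair_factory(15, 1e-6)      # effectively white noise
  set.seed(31)
  offdiag_means <- replicate(10, {
    a <- fac$draw()
    sp <- estimate_spatial_covariance(a, fac$draw(), fac$coords)
    mean(sp$Sigma_a[upper.tri(sp$Sigma_a)])
  })
  expect_lt(abs(mean(offdiag_means)), 0.05)

  expect_error(
    estimate_spatial_covariance(rep(1, 20), rnorm(20),
                                cbind(1:20, 0)), "constant")

  sp1 <- estimate_spatial_covariance(rnorm(20), rnorm(20),
                                     cbind(1:20, 0), n_classes = 1)
  off <- sp1$Sigma_a[upper.tri(sp1$Sigma_a)]
  expect_equal(length(unique(round(off, 12))), 1L)
})

test_that("positively autocorrelated surfaces shrink the effective n", {
  fac <- grf_pair_factory(12, 4)
  set.seed(41)
  M <- replicate(50, {
    modified_t_test(fac$draw(), fac$draw(), fac$coords)$M_hat
  })
  expect_gte(mean(M < 144), 0.95)
})

test_that("hierarchical partitioning reproduces its subset-ledger formula", {
  set.seed(8)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n)
  hp <- hierarchical_partition(y, cbind(x1 = x1, x2 = x2))
  led <- hp$ledger
  r2_of <- function(s) led$r2[led$subset == s]
  # k = 2 closed form: I1 = R2({1})/2 + (R2({1,2}) - R2({2}))/2
  expect_equal(hp$effects$independent[1],
               r2_of("x1") / 2 + (r2_of("x1+x2") - r2_of("x2")) / 2,
               tolerance = 1e-12)
  expect_equal(hp$effects$joint[1],
               r2_of("x1") - hp$effects$independent[1], tolerance = 1e-12)
  expect_equal(sum(hp$effects$independent), hp$full_r2, tolerance = 1e-12)

  # k = 1: the independent effect is the marginal R2
  hp1 <- hierarchical_partition(y, cbind(x1 = x1))
  expect_equal(hp1$effects$independent, r2_of("x1"), tolerance = 1e-12)
  expect_equal(hp1$effects$joint, 0)
})

test_that("independent effects match the ordering-enumeration oracle", {
  set.seed(9)
  for (k in c(3, 5)) {
    n <- 150
    X <- matrix(rnorm(n * k), n, k) %*%
      (diag(k) + matrix(0.4, k, k))       # correlated design
    y <- X %*% runif(k, -1, 1) + rnorm(n)
    hp <- hierarchical_partition(y, X)
    expect_equal(hp$effects$independent, oracle_shapley_r2(y, X),
                 tolerance = 1e-10)
    expect_equal(sum(hp$effects$independent), hp$full_r2,
                 tolerance = 1e-10)
  }
})

test_that("orthogonal designs have pure independent effects", {
  Q <- orthogonal_design(100, 3, seed = 4)
  y <- Q %*% c(1, 2, 3) + orthogonal_design(100, 1, seed = 5)
  hp <- hierarchical_partition(y, Q)
  expect_equal(hp$effects$independent, hp$effects$marginal_r2,
               tolerance = 1e-10)
  expect_equal(hp$effects$joint, rep(0, 3), tolerance = 1e-10)
})

test_that("three-way commonality components follow inclusion-exclusion", {
  Q <- orthogonal_design(200, 3, seed = 6)
  set.seed(6)
  y <- drop(Q %*% c(1, 1.5, 2)) + rnorm(200, 0, 0.5)
  vp <- venn_partition3(y, Q[, 1], Q[, 2], Q[, 3])
  expect_equal(unname(vp$components[c("unique_A", "unique_B", "unique_C")]),
               unname(vp$subset_r2[c("A", "B", "C")]), tolerance = 1e-10)
  expect_equal(unname(vp$components[4:7]), rep(0, 4), tolerance = 1e-10)
  expect_equal(sum(vp$components), vp$full_r2, tolerance = 1e-12)

  # duplicated predictor: no unique shares, all common
  set.seed(7)
  A <- rnorm(120); C <- rnorm(120); y2 <- A + 0.5 * C + rnorm(120)
  vp2 <- venn_partition3(y2, A, A, C)
  expect_equal(unname(vp2$components["unique_A"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp2$components["unique_B"]), 0, tolerance = 1e-10)
  expect_equal(sum(vp2$components), vp2$full_r2, tolerance = 1e-12)

  # random correlated design: decomposition always reassembles full R2
  set.seed(10)
  for (i in 1:5) {
    X <- matrix(rnorm(80 * 3), 80, 3) %*% (diag(3) + 0.5)
    y3 <- X %*% c(1, -1, 0.5) + rnorm(80)
    vp3 <- venn_partition3(y3, X[, 1], X[, 2], X[, 3])
    expect_equal(sum(vp3$components), vp3$full_r2, tolerance = 1e-10)
  }
})

test_that("soil PCA composites behave at correlation extremes", {
  set.seed(12)
  z <- rnorm(100)
  perfect <- soil_pca(z, 2 * z, -3 * z)
  expect_equal(perfect$variance_fraction, 1, tolerance = 1e-12)

  big <- soil_pca(rnorm(1e5), rnorm(1e5), rnorm(1e5))
  expect_equal(big$variance_fraction, 1 / 3, tolerance = 0.02)

  a <- rnorm(200); b <- 0.5 * a + rnorm(200); c2 <- 0.3 * a + rnorm(200)
  p1 <- soil_pca(a, b, c2)
  p2 <- soil_pca(-a, b, c2)
  expect_gte(p1$loadings[["oc"]], 0)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
  expect_equal(p1$loadings[["ph"]], -p2$loadings[["ph"]], tolerance = 1e-10)

  expect_error(soil_pca(rep(1, 10), rnorm(10), rnorm(10)), "zero-variance")
})
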