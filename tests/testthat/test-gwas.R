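test_that("IBS kinship is PSD with unit entries for identical samples", {
  g <- random_geno(15, 400, seed = 51)
  g$calls[2, ] <- g$calls[1, ]
  K <- kinship_ibs(ibs_matrix(g))
  expect_equal(K["s001", "s002"], 1.0)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("with K = identity the scan reproduces OLS t-test p-values", {
  set.seed(52)
  n <- 50
  g <- random_geno(n, 40)
  y <- rnorm(n) + 0.7 * g$calls[, 11]
  X0 <- matrix(1, n, 1)
  K <- diag(n)
  dimnames(K) <- list(g$samples, g$samples)
  sc <- single_marker_scan(y, X0, K, g)
  ols <- ols_scan_pvals(y, g$calls)
  expect_equal(sc$p, ols, tolerance = 1e-8)
  expect_equal(sc$marker[which.min(sc$p)], "m0011")
})

test_that("restricted likelihood at K = identity matches the OLS closed form", {
  set.seed(53)
  n <- 40
  y <- rnorm(n, 5, 2)
  X0 <- cbind(1, rnorm(n))
  K <- diag(n)
  vc <- reml_variance_components(y, X0, K)
  q <- 2
  rss <- sum(stats::lm.fit(X0, y)$residuals^2)
  ll <- 0.5 * (n - q) * (log((n - q) / (2 * pi)) - 1 - log(rss))
  expect_equal(vc$loglik, ll, tolerance = 1e-6)
  expect_equal(vc$vg + vc$ve, rss / (n - q), tolerance = 1e-4)
})

test_that("rotated GLS equals a direct full-covariance solve", {
  cfg <- sim_config(seed = 54, n_markers = 200, n_offspring = 30, n_sires = 3,
                    n_dams = 30)
  hub <- simulate_hub_population(cfg)
  K <- kinship_ibs(ibs_matrix(hub$geno))
  n <- n_samples(hub$geno)
  set.seed(55)
  y <- as.numeric(chol(K + diag(n) * 0.5) %*% rnorm(n))
  X0 <- matrix(1, n, 1)
  vc <- reml_variance_components(y, X0, K)
  sc <- single_marker_scan(y, X0, K, hub$geno, vc = vc)
  V <- vc$vg * K + vc$ve * diag(n)
  Vi <- solve(V)
  for (j in c(3, 50, 120)) {
    X <- cbind(X0, dosage_matrix(hub$geno)[, j])
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(sc$ase[j], beta[2], tolerance = 1e-8)
  }
})

test_that("variance components are recovered at the boundaries", {
  set.seed(56)
  n <- 100
  g <- random_geno(n, 500)
  K <- kinship_ibs(ibs_matrix(g))
  # pure-noise responses: genetic share should be near zero most of the time
  low <- vapply(1:10, function(i) {
    y <- rnorm(n)
    vc <- reml_variance_components(y, matrix(1, n, 1), K)
    vc$h2
  }, numeric(1))
  expect_gte(sum(low < 0.1), 7)

  # almost pure polygenic signal: high heritability estimates
  ch <- chol(K + diag(n) * 1e-6)
  high <- vapply(1:10, function(i) {
    y <- as.numeric(t(ch) %*% rnorm(n)) + rnorm(n, sd = 0.05)
    reml_variance_components(y, matrix(1, n, 1), K)$h2
  }, numeric(1))
  expect_gte(sum(high > 0.8), 7)
})

test_that("markers collinear with a covariate or monomorphic give NA results", {
  set.seed(57)
  n <- 40
  g <- random_geno(n, 10)
  g$calls[, 4] <- 0L                      # monomorphic
  X0 <- cbind(1, g$calls[, 7])            # marker 7 duplicates a covariate
  y <- rnorm(n)
  K <- diag(n)
  dimnames(K) <- list(g$samples, g$samples)
  sc <- single_marker_scan(y, X0, K, g)
  expect_true(is.na(sc$p[4]))
  expect_true(is.na(sc$p[7]))
  expect_false(anyNA(sc$p[c(1:3, 5, 6, 8:10)]))
})

test_that("BH q-values match the hand step-up and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(numeric(0)), numeric(0))

  set.seed(58)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))  # monotone along sorted p
  perm <- sample(200)
  expect_equal(bh_fdr(p[perm]), q[perm])    # order invariance
})

test_that("mlmm with max_cofactors = 0 reduces to the single-marker scan", {
  set.seed(59)
  n <- 60
  g <- random_geno(n, 80)
  K <- kinship_ibs(ibs_matrix(g))
  y <- rnorm(n) + 0.6 * g$calls[, 9]
  X0 <- matrix(1, n, 1)
  fit <- mlmm_stepwise(y, X0, K, g, max_cofactors = 0)
  vc <- reml_variance_components(y, X0, K)
  sc <- single_marker_scan(y, X0, K, g, vc = vc)
  expect_equal(length(fit$cofactors), 0)
  expect_equal(fit$results$p, sc$p)
  expect_equal(fit$results$ase, sc$ase)
})

test_that("stepwise selection recovers two independent planted QTLs", {
  set.seed(60)
  hits <- 0
  for (r in 1:5) {
    n <- 150
    g <- random_geno(n, 300, q = runif(300, 0.2, 0.5))
    d1 <- scale(g$calls[, 40])[, 1]
    d2 <- scale(g$calls[, 220])[, 1]
    y <- sqrt(0.15) * d1 + sqrt(0.15) * d2 + sqrt(0.7) * rnorm(n)
    K <- kinship_ibs(ibs_matrix(g))
    fit <- mlmm_stepwise(y, matrix(1, n, 1), K, g, max_cofactors = 5)
    hits <- hits + all(c("m0040", "m0220") %in% fit$cofactors)
  }
  expect_gte(hits, 4)
})

test_that("null data rarely select any cofactor", {
  set.seed(61)
  none <- vapply(1:5, function(r) {
    n <- 100
    g <- random_geno(n, 200)
    K <- kinship_ibs(ibs_matrix(g))
    fit <- mlmm_stepwise(rnorm(n), matrix(1, n, 1), K, g, max_cofactors = 5)
    length(fit$cofactors) == 0
  }, logical(1))
  expect_gte(sum(none), 4)
})

test_that("covariate design reduces dates to year cohorts with dummies", {
  samples <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    birth_date = c("2012-05-01", "2012-11-30", "2013-01-01", "2013-06-15"),
    birth_place = c("f1", "f2", "f1", "f2")
  )
  X <- covariate_design(samples, c("a", "b", "c", "d"))
  expect_equal(ncol(X), 3)  # intercept + year2013 + placef2
  expect_equal(unname(X[, "birth_year2013"]), c(0, 0, 1, 1))
  expect_error(covariate_design(samples, c("a", "zz")), "missing for sample")
})
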