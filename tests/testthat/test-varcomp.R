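test_that("rank-normalization maps to the expected normal quantiles", {
  z <- rank_normalize(c(5, 1, 9))
  expect_equal(z, c(0, qnorm(1 / 6), qnorm(5 / 6)), tolerance = 1e-12)
  expect_equal(round(z[2:3], 4), c(-0.9674, 0.9674))
  # invariance under strictly monotone transforms
  x <- c(0.3, 2.5, 0.01, 7, 1.1)
  expect_equal(rank_normalize(x), rank_normalize(exp(x)))
  expect_equal(rank_normalize(x), rank_normalize(rank(x)))
  # ties get equal z-values
  zt <- rank_normalize(c(1, 1, 2))
  expect_equal(zt[1], zt[2])
  # missing propagated, degenerate input rejected
  expect_true(is.na(rank_normalize(c(1, NA, 2, 3))[2]))
  expect_error(rank_normalize(c(2, 2, 2)), "identical")
  # alternative conventions
  expect_equal(rank_normalize(c(5, 1, 9), offset = "waerden"),
               qnorm(c(2, 1, 3) / 4))
})

test_that("with no genetic variance the fit reduces to ordinary least squares", {
  set.seed(50)
  ped <- ped_two_families()
  phi <- kinship_matrix(ped)
  n <- nrow(phi)
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- drop(X %*% c(2, 1)) + rnorm(n)
  f0 <- fit_polygenic(y, X, phi = phi, h2_fixed = 0)
  q <- qr(X)
  s2 <- sum(qr.resid(q, y)^2) / n
  ll_ols <- sum(dnorm(y - qr.fitted(q, y), 0, sqrt(s2), log = TRUE))
  expect_equal(f0$loglik, ll_ols, tolerance = 1e-10)
  expect_equal(f0$h2, 0)
  expect_equal(unname(f0$beta), unname(qr.coef(q, y)), tolerance = 1e-10)
})

test_that("unrelated individuals drive the heritability to the boundary", {
  set.seed(51)
  n <- 40
  phi <- diag(0.5, n)
  dimnames(phi) <- list(paste0("u", 1:n), paste0("u", 1:n))
  y <- rnorm(n)
  X <- cbind(intercept = rep(1, n))
  fit <- fit_polygenic(y, X, phi = phi)
  # 2*phi = I: h2 unidentifiable, profile flat; fit completes and both
  # likelihoods coincide
  f0 <- fit_polygenic(y, X, phi = phi, h2_fixed = 0)
  expect_equal(fit$loglik, f0$loglik, tolerance = 1e-6)
})

test_that("the ML fit matches the explicit-inverse oracle on small data", {
  set.seed(52)
  for (rep in 1:3) {
    ped <- ped_two_families()
    phi <- kinship_matrix(ped)
    K <- 2 * phi
    n <- nrow(K)
    X <- cbind(intercept = 1, x = rnorm(n))
    y <- drop(chol(0.6 * K + 0.4 * diag(n)) %*% rnorm(n)) +
      drop(X %*% c(1, 0.5))
    fit <- fit_polygenic(y, X, phi = phi)
    orc <- gls_oracle(y, X, K)
    # the oracle is a grid search; agree to within its resolution
    expect_lt(abs(fit$h2 - orc$h2), 2e-3)
    expect_lt(abs(fit$loglik - max(orc$ll_grid)), 1e-3)
    expect_gte(fit$loglik, max(orc$ll_grid) - 1e-10)
    expect_lt(max(abs(unname(fit$beta) - unname(orc$beta))), 5e-3)
  }
})

test_that("heritability LRT uses the boundary chi-square mixture", {
  f <- structure(list(loglik = -10, n = 20L, df_fixed = 2L),
                 class = "polygenic_fit")
  f0 <- structure(list(loglik = -10 - 3.8415 / 2, n = 20L, df_fixed = 2L),
                  class = "polygenic_fit")
  ht <- heritability_test(f, f0)
  expect_equal(ht$statistic, 3.8415)
  expect_equal(ht$p_value, 0.025, tolerance = 1e-4)
  ht0 <- heritability_test(f, f)
  expect_equal(ht0$p_value, 1)
  fbad <- structure(list(loglik = -9, n = 21L, df_fixed = 2L),
                    class = "polygenic_fit")
  expect_error(heritability_test(f, fbad), "mismatched")
})

test_that("association recovers a planted regression effect", {
  set.seed(53)
  n <- 400
  phi <- diag(0.5, n)
  dimnames(phi) <- list(paste0("u", 1:n), paste0("u", 1:n))
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  X <- cbind(intercept = rep(1, n))
  at <- association_test(y, X, phi = phi, x_focal = x)
  expect_true(abs(at$beta - 0.5) < 3 * at$se)
  expect_lt(at$p_value, 1e-10)
  expect_equal(at$variance_explained, at$beta^2 * var(x) / var(y),
               tolerance = 1e-12)
  expect_error(association_test(y, X, phi = phi, x_focal = rep(1, n)),
               "constant")
})

test_that("adding a covariate never decreases the log-likelihood", {
  set.seed(54)
  co <- simulate_cohort(small_cohort_config(seed = 54L),
                        measurement = FALSE)
  eig <- kinship_eigen(co$phi)
  X <- make_covariate_design(co$covariates$age, co$covariates$sex)
  y <- rank_normalize(co$meth_true[, "9"])
  ll_by_width <- vapply(2:ncol(X), function(k)
    fit_polygenic(y, X[, 1:k, drop = FALSE], eig = eig)$loglik, numeric(1))
  expect_true(all(diff(ll_by_width) >= -1e-6))
})

test_that("covariate scan reports fraction-scale effects and h2 together", {
  co <- simulate_cohort(small_cohort_config(seed = 55L),
                        measurement = FALSE)
  eig <- kinship_eigen(co$phi)
  X <- make_covariate_design(co$covariates$age, co$covariates$sex)
  y_raw <- co$meth_true[, "9"]
  sc <- covariate_scan(rank_normalize(y_raw), X, eig = eig,
                       meth_raw_sd = sd(y_raw))
  expect_true(sc$h2 >= 0 && sc$h2 <= 1)
  expect_true(sc$p_h2 > 0 && sc$p_h2 <= 1)
  # unit 9 has a strong positive generative age slope (2.9e-4 per year)
  expect_gt(sc$beta_age, 0)
  expect_true(all(c(sc$ve_age, sc$ve_sex) >= 0))
})

test_that("effects back-transform to raw trait units per 1% methylation", {
  expect_equal(back_transform_effect(0, 10, 0.05), 0)
  expect_equal(back_transform_effect(1, 10, 0.01), 10)
  expect_equal(back_transform_effect(0.3, 8, 0.04),
               2 * back_transform_effect(0.3, 8, 0.08))
  expect_error(back_transform_effect(1, 0, 0.1), "positive")
})

test_that("expression normalization equalizes sample distributions", {
  set.seed(56)
  m <- matrix(rlnorm(200, meanlog = 6), 50, 4,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
  nm <- normalize_expression(m)
  # all samples share one sorted value multiset
  ref <- sort(nm[, 1])
  for (j in 2:4) expect_equal(sort(nm[, j]), ref, ignore_attr = TRUE)
  # within-sample order preserved
  for (j in 1:4) expect_equal(order(nm[, j]), order(m[, j]))
  # two samples with identical sorted intensities normalize identically
  m2 <- cbind(a = c(1, 5, 3), b = c(3, 1, 5))
  nm2 <- normalize_expression(m2)
  expect_equal(sort(nm2[, "a"]), sort(nm2[, "b"]), ignore_attr = TRUE)
  expect_error(normalize_expression(cbind(c(1, -2, 3))), "non-positive")
})
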