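# Group-level structures: priors, Gibbs full conditionals, and implied
# covariance/correlation algebra.

test_that("log prior of the multivariate-normal state matches the closed form", {
  nm <- paste0("x", 1:3)
  pr <- group_prior(nm)
  g <- mvn_group(setNames(pr$mu0, nm), diag(3))
  # independent oracle: normal + inverse-Wishart + inverse-gamma densities
  p <- 3; nu <- 2
  lp_mu <- sum(dnorm(g$mu, pr$mu0, 1, log = TRUE))
  S <- 2 * nu * diag(1 / g$a, p)
  d <- nu + p - 1
  ldet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  lp_S <- 0.5 * d * ldet(S) - 0.5 * d * p * log(2) -
    (0.25 * p * (p - 1) * log(pi) +
       sum(lgamma(d / 2 + (1 - seq_len(p)) / 2))) -
    0.5 * (d + p + 1) * ldet(g$Sigma) -
    0.5 * sum(diag(S %*% solve(g$Sigma)))
  lp_a <- sum(0.5 * log(1) - lgamma(0.5) - 1.5 * log(g$a) - 1 / g$a)
  expect_equal(log_prior(g, pr), lp_mu + lp_S + lp_a)
  # prior means by parameter kind, mapped through the transforms
  lay <- param_layout("rl_rev")
  pr2 <- group_prior(lay$names, lay$transforms)
  expect_equal(unname(pr2$mu0[c("delta", "V0", "t0", "B")]),
               c(2, 1, log(0.2), log(2)))
  expect_equal(unname(pr2$mu0["alpha_learn"]), 0)
})

test_that("factor-state prior rejects constraint violations", {
  nm <- paste0("x", 1:4)
  pr <- group_prior(nm)
  L <- matrix(c(0.5, 0.3, 0.2, 0.1, 0, 0.4, 0.2, 0.3), 4, 2)
  g <- factor_group(setNames(rep(0, 4), nm), L, rep(0.1, 4),
                    eta = matrix(0, 2, 2))
  expect_true(is.finite(log_prior(g, pr)))
  gbad <- g
  gbad$eps[2] <- -0.1
  expect_identical(log_prior(gbad, pr), -Inf)
  gfix <- g
  gfix$Lambda[1, 2] <- 0.05 # perturbing the fixed zero
  expect_identical(log_prior(gfix, pr), -Inf)
  expect_error(factor_group(g$mu, gfix$Lambda, g$eps), "must be exactly 0")
  expect_error(factor_group(g$mu, -L, g$eps), "nonnegative")
})

test_that("multivariate-normal Gibbs recovers a known group and is reproducible", {
  set.seed(3)
  p <- 3
  mu_star <- c(1, -0.5, 2)
  S_star <- diag(c(0.4, 0.2, 0.3)) + 0.1
  alpha <- MASS::mvrnorm(400, mu_star, S_star)
  pr <- group_prior(paste0("x", 1:p))
  pr$mu0[] <- 0
  g <- mvn_group(setNames(rep(0, p), paste0("x", 1:p)), diag(p))
  mus <- matrix(NA, 300, p)
  Ss <- array(NA, c(p, p, 300))
  for (i in 1:500) {
    g <- gibbs_update_mvn(g, alpha, pr)
    if (i > 200) { mus[i - 200, ] <- g$mu; Ss[, , i - 200] <- g$Sigma }
  }
  # with n = 400 the posterior concentrates near the empirical moments
  expect_lt(max(abs(colMeans(mus) - mu_star)), 3 * sqrt(max(diag(S_star)) / 400) * 3)
  expect_lt(max(abs(apply(Ss, c(1, 2), mean) - S_star)), 0.12)
  g1 <- gibbs_update_mvn(g, alpha, pr, seed = 5)
  g2 <- gibbs_update_mvn(g, alpha, pr, seed = 5)
  expect_identical(g1, g2)
  expect_error(gibbs_update_mvn(g, alpha[1, , drop = FALSE], pr),
               "at least 2 subjects")
})

test_that("one-dimensional covariance Gibbs matches a hand-coded normal-inverse-gamma chain", {
  set.seed(9)
  n <- 60
  alpha <- matrix(rnorm(n, 1.2, 0.7))
  pr <- group_prior("x")
  pr$mu0[] <- 0
  # hand-coded oracle with the same hierarchical prior in one dimension:
  # sigma2 | a ~ IG(nu/2, nu/a), a ~ IG(1/2, 1), mu ~ N(0,1)
  nu <- 2
  oracle <- function(iters, seed) {
    set.seed(seed)
    mu <- 0; s2 <- 1; a <- 1
    out <- matrix(NA, iters, 2)
    for (i in seq_len(iters)) {
      prec <- 1 + n / s2
      mu <- rnorm(1, (sum(alpha) / s2) / prec, sqrt(1 / prec))
      s2 <- 1 / rgamma(1, (nu + n) / 2,
                       rate = nu / a + sum((alpha - mu)^2) / 2)
      a <- 1 / rgamma(1, (nu + 1) / 2, rate = nu / s2 + 1)
      out[i, ] <- c(mu, s2)
    }
    out
  }
  oc <- oracle(4000, 21)
  g <- mvn_group(c(x = 0), matrix(1))
  draws <- matrix(NA, 4000, 2)
  for (i in 1:4000) {
    g <- gibbs_update_mvn(g, alpha, pr)
    draws[i, ] <- c(g$mu, g$Sigma[1, 1])
  }
  burn <- 500
  expect_equal(mean(draws[-(1:burn), 1]), mean(oc[-(1:burn), 1]),
               tolerance = 0.02)
  expect_equal(mean(draws[-(1:burn), 2]), mean(oc[-(1:burn), 2]),
               tolerance = 0.05 * mean(oc[-(1:burn), 2]) + 0.02)
  expect_equal(sd(draws[-(1:burn), 2]), sd(oc[-(1:burn), 2]),
               tolerance = 0.15)
})

test_that("factor Gibbs recovers loadings, keeps constraints, and reconstructs the covariance", {
  set.seed(2)
  p <- 6; k <- 2; n <- 250
  L <- matrix(0, p, k)
  L[1:3, 1] <- 0.5
  L[4:6, 2] <- 0.6
  mu <- rnorm(p)
  eta <- matrix(rnorm(n * k), n, k)
  alpha <- sweep(eta %*% t(L) + matrix(rnorm(n * p, 0, 0.3), n, p), 2, mu, "+")
  pr <- group_prior(paste0("x", 1:p))
  g <- factor_group(setNames(rep(0, p), paste0("x", 1:p)),
                    matrix(c(rep(0.1, p), 0, rep(0.1, p - 1)), p, k) *
                      rdmjoint:::factor_free_mask(p, k),
                    rep(0.1, p), matrix(0, n, k))
  Ls <- array(NA, c(p, k, 300))
  for (i in 1:500) {
    g <- gibbs_update_factor(g, alpha, pr)
    # algebraic identity and constraints hold at every draw
    expect_identical(g$Lambda[1, 2], 0)
    expect_true(all(diag(g$Lambda[1:k, ]) >= 0))
    expect_equal(implied_cov(g),
                 g$Lambda %*% t(g$Lambda) + diag(g$eps, p))
    if (i > 200) Ls[, , i - 200] <- g$Lambda
  }
  med <- apply(Ls, c(1, 2), median)
  expect_lt(max(abs(med - L)), 0.12)
  expect_error(factor_group(g$mu, matrix(0.1, p, p + 1), rep(0.1, p)),
               "smaller than the parameter count")
  # reproducibility
  g1 <- gibbs_update_factor(g, alpha, pr, seed = 31)
  g2 <- gibbs_update_factor(g, alpha, pr, seed = 31)
  expect_identical(g1, g2)
})

test_that("data generated without factor structure give loadings concentrated at zero", {
  set.seed(12)
  p <- 5; n <- 200
  alpha <- matrix(rnorm(n * p, 0, 0.3), n, p)
  pr <- group_prior(paste0("x", 1:p))
  g <- factor_group(setNames(rep(0, p), paste0("x", 1:p)),
                    matrix(c(0.1, rep(0.1, p - 1)), p, 1), rep(0.1, p),
                    matrix(0, n, 1))
  Ls <- matrix(NA, 300, p)
  for (i in 1:500) {
    g <- gibbs_update_factor(g, alpha, pr)
    if (i > 200) Ls[i - 200, ] <- g$Lambda[, 1]
  }
  ci <- apply(Ls, 2, quantile, c(0.025, 0.975))
  # free unconstrained loadings should overwhelmingly cover zero
  covers <- ci[1, -1] <= 0 & ci[2, -1] >= 0
  expect_gte(mean(covers), 0.75)
  expect_lt(max(abs(apply(Ls, 2, median))), 0.15)
})

test_that("implied correlations normalise the implied covariance", {
  g <- mvn_group(c(a = 0, b = 0), diag(2))
  expect_equal(implied_correlations(g), diag(2))
  gf <- factor_group(c(a = 0, b = 0), matrix(c(1, 1)), c(1, 1))
  expect_equal(implied_correlations(gf)[1, 2], 0.5)
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4))
  gm <- mvn_group(setNames(rep(0, 4), letters[1:4]), A)
  D <- diag(1 / sqrt(diag(A)))
  expect_equal(unname(implied_correlations(gm)), D %*% A %*% D)
  bad <- mvn_group(c(a = 0, b = 0), matrix(c(0, 0, 0, 1), 2))
  expect_error(implied_correlations(bad), "variance")
})
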