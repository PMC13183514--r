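test_that("collapsed inclusion update reduces to the prior without data", {
  # no rows with t != 0: Bernoulli probability is the prior pi
  for (pi in c(0.1, 0.5, 0.9)) {
    u <- inclusion_update(0, 0, sigma2 = 1, theta = 0.3, s2 = 2, pi = pi)
    expect_equal(u$p1, pi, tolerance = 1e-12)
  }
  # degenerate slab: spike and slab indistinguishable
  u <- inclusion_update(5, 1.2, sigma2 = 1, theta = 0, s2 = 1e-12,
                        pi = 0.4)
  expect_equal(u$p1, 0.4, tolerance = 1e-4)
})

test_that("marginalized inclusion probability matches quadrature", {
  set.seed(21)
  for (i in 1:6) {
    n <- 30
    t <- rnorm(n)
    lam0 <- c(0, 0.8, 0.3, 1.5, 0, 0.6)[i]
    sigma <- c(0.5, 1, 0.3, 1, 2, 0.7)[i]
    r <- lam0 * t + rnorm(n, 0, sigma)
    theta <- c(0, 0, 0.5, 0, 1, 0.2)[i]
    s2 <- c(30, 5, 1, 30, 2, 10)[i]
    pi <- 0.5
    upd <- inclusion_update(sum(t^2), sum(t * r), sigma^2, theta, s2, pi)
    # numerical oracle: integrate the likelihood ratio against the
    # truncated-normal slab
    loglik_ratio <- function(l)
      vapply(l, function(li)
        sum(dnorm(r, li * t, sigma, log = TRUE)) -
          sum(dnorm(r, 0, sigma, log = TRUE)), numeric(1))
    num <- integrate(function(l)
      exp(loglik_ratio(l)) * dtnorm_pos(l, theta, sqrt(s2)),
      0, Inf, rel.tol = 1e-10)$value
    p_oracle <- pi * num / (pi * num + (1 - pi))
    expect_equal(upd$p1, p_oracle, tolerance = 1e-6)
  }
})

test_that("positive truncated-normal draws follow the target density", {
  set.seed(22)
  x <- replicate(4000, mixbart:::rtnorm_pos(-0.5, 1))
  expect_true(all(x > 0))
  # analytic CDF of N(-0.5, 1) truncated to (0, Inf)
  cdf <- function(q) (pnorm(q, -0.5, 1) - pnorm(0, -0.5, 1)) /
    (1 - pnorm(0, -0.5, 1))
  expect_gt(ks.test(x, cdf)$p.value, 0.001)
  # deep-tail branch stays finite and positive
  y <- replicate(200, mixbart:::rtnorm_pos(-8, 1))
  expect_true(all(y > 0 & is.finite(y)))
})

test_that("gamma full conditional matches the scalar conjugate oracle", {
  # Q = 2: one free entry; hand-derived univariate normal posterior
  set.seed(23)
  n <- 20
  U <- matrix(rnorm(n), n, 1)
  r2 <- 0.6 * U[, 1] + rnorm(n, 0, 0.5)
  gp <- gamma_posterior(U, r2, sigma2 = 0.25, r0_scale = 0.5, g0 = 0.1)
  prec <- sum(U^2) / 0.25 + 1 / 0.5
  mean_hand <- (sum(U * r2) / 0.25 + 0.1 / 0.5) / prec
  expect_equal(gp$mean, mean_hand)
  expect_equal(gp$chol_prec[1, 1]^2, prec)
  # degenerate prior pins gamma at its prior mean
  gp0 <- gamma_posterior(U, r2, 0.25, r0_scale = 1e-12, g0 = 0.1)
  expect_equal(gp0$mean, 0.1, tolerance = 1e-6)
})

test_that("cluster-effect draws match the scalar conjugate posterior", {
  # one cluster, Q = 1: closed-form normal posterior
  set.seed(24)
  nk <- 10
  z <- matrix(1, nk, 1)
  r <- rnorm(nk, 1, 0.5)
  lambda <- 0.7; sigma2 <- 0.25
  Szz <- matrix(nk, 1, 1)              # Z'Z for the intercept column
  Zr <- matrix(sum(r), 1, 1)
  LG <- matrix(lambda, 1, 1)
  draws <- replicate(4000, mixbart:::.sample_b(Szz, Zr, LG, sigma2)[1, 1])
  prec <- lambda^2 * nk / sigma2 + 1
  mean_hand <- lambda * sum(r) / sigma2 / prec
  expect_lt(abs(mean(draws) - mean_hand), 4 * sqrt(1 / prec / 4000))
  expect_lt(abs(var(draws) / (1 / prec) - 1), 0.1)
  # with lambda = 0 the posterior is the standard-normal prior
  d0 <- replicate(2000, mixbart:::.sample_b(Szz, Zr, matrix(0, 1, 1),
                                            sigma2)[1, 1])
  expect_lt(abs(mean(d0)), 0.1)
  expect_lt(abs(var(d0) - 1), 0.15)
})

test_that("sigma2 draws follow the scaled inverse-chi-squared posterior", {
  # trees off, random effects off: each retained draw is an exact
  # independent draw from Inv-chi2(nu + n, (nu tau2 + SSR)/(nu + n))
  set.seed(25)
  n <- 80
  y <- rnorm(n, 0, 1.3)
  d <- hier_data(y, matrix(rnorm(n * 2), n, 2))
  nu <- 3; tau2 <- 2
  tr <- unified_fit(d, n_iter = 1500, n_keep = 1500,
                    control = bart_control(n_trees = 0),
                    hyper = model_hyper(nu = nu, tau2 = tau2),
                    standardize = FALSE, seed = 26)
  ssr <- sum(y^2)     # f = 0, no random effects
  cdf <- function(q) 1 - pchisq((nu * tau2 + ssr) / q, nu + n)
  expect_gt(ks.test(tr$sigma2, cdf)$p.value, 0.01)
  # prior-only numerator at zero residuals: mean close to nu tau2/(nu+n-2)
  y0 <- rep(0, n)
  d0 <- hier_data(y0, matrix(rnorm(n * 2), n, 2))
  tr0 <- unified_fit(d0, n_iter = 800, n_keep = 800,
                     control = bart_control(n_trees = 0),
                     hyper = model_hyper(nu = nu, tau2 = tau2),
                     standardize = FALSE, seed = 27)
  expect_equal(mean(tr0$sigma2), nu * tau2 / (nu + n - 2),
               tolerance = 0.02)
})

test_that("intercept posterior matches its closed form with trees off", {
  # lambda and sigma2 frozen: the per-cluster intercept coefficient
  # lambda * b_k is an independent normal draw each iteration
  set.seed(28)
  K <- 6; nk <- 30
  ci <- factor(rep(1:K, each = nk))
  u <- rnorm(K, 0, 0.8)
  y <- u[ci] + rnorm(K * nk, 0, 0.5)
  d <- hier_data(y, matrix(rnorm(K * nk), ncol = 1), cluster = ci,
                 Z = matrix(1, K * nk, 1))
  lam <- 0.8; s2 <- 0.25
  tr <- unified_fit(d, n_iter = 1200, n_keep = 1200,
                    control = bart_control(n_trees = 0),
                    standardize = FALSE, sigma2_fixed = s2,
                    lambda_fixed = lam, seed = 29, keep_coef = TRUE)
  for (k in c(1, 4)) {
    prec <- lam^2 * nk / s2 + 1
    mu_k <- lam * sum(y[ci == k]) / s2 / prec
    cdf <- function(q) pnorm(q, lam * mu_k, lam * sqrt(1 / prec))
    expect_gt(ks.test(tr$coef1[, k], cdf)$p.value, 0.01)
  }
})

test_that("inclusion frequencies behave under null and strong signal", {
  # global null: the collapsed update is conservative -- the diffuse
  # slab keeps null inclusion rates low but nonzero, far from the
  # sticky extremes
  incl <- c()
  for (s in 1:6) {
    d <- make_cluster_data(K = 12, nk = 6, lambda_true = c(0, 0),
                           sigma = 1, seed = 400 + s, P = 2)
    tr <- unified_fit(d, n_iter = 500, n_keep = 250,
                      control = bart_control(n_trees = 5),
                      seed = 500 + s)
    incl <- rbind(incl, colMeans(tr$v))
  }
  expect_true(all(colMeans(incl) > 0 & colMeans(incl) < 0.5))

  # strong intercept signal, null slope: v = (1, *) with the first
  # entry nearly always on and the slope not dominating
  hit1 <- c(); hit2 <- c()
  for (s in 1:10) {
    d <- make_cluster_data(K = 20, nk = 10, lambda_true = c(1.5, 0),
                           sigma = 0.4, seed = 600 + s, P = 2)
    tr <- unified_fit(d, n_iter = 500, n_keep = 250,
                      control = bart_control(n_trees = 5),
                      seed = 700 + s)
    hit1 <- c(hit1, mean(tr$v[, 1]))
    hit2 <- c(hit2, mean(tr$v[, 2]))
  }
  expect_true(all(hit1 >= 0.95))
  expect_lt(mean(hit2), 0.5)
})

test_that("spike-and-slab state is internally consistent", {
  d <- make_cluster_data(K = 10, nk = 8, seed = 31)
  tr <- unified_fit(d, n_iter = 300, n_keep = 200,
                    control = bart_control(n_trees = 5), seed = 32)
  # constraint: lambda = 0 exactly when v = 0, lambda > 0 when v = 1
  expect_true(all(tr$lambda[tr$v == 0L] == 0))
  expect_true(all(tr$lambda[tr$v == 1L] > 0))
  expect_true(all(tr$lambda >= 0))
})

test_that("chains are deterministic given the seed", {
  d <- make_cluster_data(K = 8, nk = 6, seed = 33)
  tr1 <- unified_fit(d, n_iter = 150, n_keep = 80, seed = 34)
  tr2 <- unified_fit(d, n_iter = 150, n_keep = 80, seed = 34)
  expect_identical(tr1$sigma2, tr2$sigma2)
  expect_identical(tr1$counts, tr2$counts)
  expect_identical(tr1$v, tr2$v)
  expect_identical(tr1$coef_mean, tr2$coef_mean)
  tr3 <- unified_fit(d, n_iter = 150, n_keep = 80, seed = 35)
  expect_false(identical(tr1$sigma2, tr3$sigma2))
})

test_that("beta-bernoulli feedback is symmetric under a flat likelihood", {
  # with L1 = L0 the stationary inclusion frequency under the
  # pi -> v -> pi chain is the Beta(0.5, 0.5) mean of 0.5
  set.seed(36)
  v <- 1L
  hits <- 0L
  n_it <- 20000
  for (i in seq_len(n_it)) {
    pi <- rbeta(1, 0.5 + v, 0.5 + 1 - v)
    v <- as.integer(runif(1) < inclusion_update(0, 0, 1, 0, 30, pi)$p1)
    hits <- hits + v
  }
  expect_lt(abs(hits / n_it - 0.5), 0.03)
})
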