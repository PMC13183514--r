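test_that("linear step 1 matches the mixed-model shrinkage oracle", {
  skip_if_not_installed("lme4")
  set.seed(51)
  K <- 40; nk <- 25
  ci <- factor(rep(seq_len(K), each = nk))
  x <- rnorm(K * nk)
  u <- rnorm(K, 0, 1)
  y <- 0.5 * x + u[ci] + rnorm(K * nk)
  d <- hier_data(y, matrix(x, ncol = 1), cluster = ci)
  est <- fit_step1_linear(d, seed = 52)
  # independent oracle: REML BLUPs
  fit <- lme4::lmer(y ~ x + (1 | ci))
  blup <- lme4::ranef(fit)$ci[, 1]
  expect_gt(cor(est$beta_hat, blup), 0.99)
  expect_lt(max(abs(est$beta_hat - blup)), 0.15)
  expect_lt(max(abs(est$beta_hat - blup)) / sd(blup), 0.2)
  # determinism
  est2 <- fit_step1_linear(d, seed = 52)
  expect_identical(est$beta_hat, est2$beta_hat)
  # rank-deficient design is an informative failure
  X2 <- cbind(a = x, b = x)
  d2 <- hier_data(y, X2, cluster = ci)
  expect_error(fit_step1_linear(d2, seed = 1), "rank deficient")
})

test_that("BART step 1 recovers a planted cluster effect", {
  hits <- 0
  for (s in 1:5) {
    set.seed(60 + s)
    K <- 10; nk <- 15
    ci <- factor(rep(seq_len(K), each = nk))
    X <- matrix(rnorm(K * nk * 3), ncol = 3)
    y <- X[, 1] + 5 * (ci == "1") + rnorm(K * nk, 0, 0.5)
    d <- hier_data(y, X, cluster = ci)
    est <- fit_step1_bart(d, n_iter = 400, n_keep = 200,
                          control = bart_control(n_trees = 10),
                          seed = 70 + s)
    hits <- hits + unname(which.max(est$beta_hat) == 1)
  }
  expect_equal(hits, 5)
})

test_that("step 1 shrinks toward zero without between-cluster variance", {
  set.seed(53)
  K <- 12; nk <- 10
  ci <- factor(rep(seq_len(K), each = nk))
  y <- rnorm(K * nk)
  d <- hier_data(y, matrix(rnorm(K * nk), ncol = 1), cluster = ci)
  est <- fit_step1_bart(d, n_iter = 400, n_keep = 200,
                        control = bart_control(n_trees = 5), seed = 54)
  nopool <- tapply(y, ci, mean)
  expect_lt(max(abs(est$beta_hat)), max(abs(nopool - mean(y))))
})

test_that("the step 2 table is the cluster-level view of the data", {
  sim <- generate_scenario(scenario_config("unbalanced", K = 8,
                                           z_structure = "constant",
                                           seed = 55))
  d <- sim$data
  est <- structure(list(beta_hat = setNames(rnorm(8), levels(d$cluster)),
                        sd = rep(0, 8), clusters = levels(d$cluster),
                        source = "oracle"), class = "cluster_effects")
  ct <- build_step2_dataset(est, d)
  expect_equal(length(ct$y), 8)
  expect_equal(unname(ct$y), unname(est$beta_hat))
  # predictors equal the generator's cluster-level values
  first <- match(levels(d$cluster), as.character(d$cluster))
  expect_equal(unname(ct$X), unname(d$Z[first, -1]))
  expect_equal(ct$x_group, d$z_group)
  # row order of the individual-level data is irrelevant
  perm <- sample(length(d$y))
  d2 <- hier_data(d$y[perm], d$X[perm, ], cluster = d$cluster[perm],
                  Z = d$Z[perm, ], x_type = d$x_type,
                  z_group = d$z_group)
  ct2 <- build_step2_dataset(est, d2)
  expect_equal(ct2$X, ct$X)
  # a varying "constant" column is a named error
  d3 <- d
  d3$Z[1, "z_1"] <- d3$Z[1, "z_1"] + 1
  expect_error(build_step2_dataset(est, d3), "cluster '1'")
})

test_that("step 1 implementations are interchangeable for step 2", {
  sim <- generate_scenario(scenario_config("unbalanced", K = 12,
                                           z_structure = "constant",
                                           seed = 56))
  e1 <- fit_step1_linear(sim$data, n_iter = 600, n_keep = 300, seed = 57)
  e2 <- fit_step1_bart(sim$data, n_iter = 200, n_keep = 100,
                       control = bart_control(n_trees = 5), seed = 57)
  c1 <- build_step2_dataset(e1, sim$data)
  c2 <- build_step2_dataset(e2, sim$data)
  # identical predictor matrices and schema; only the response differs
  expect_identical(c1$X, c2$X)
  expect_identical(c1$x_group, c2$x_group)
  expect_identical(c1$x_type, c2$x_type)
})

test_that("spike-and-slab step 2 calibrates on null and finds signal", {
  # planted dominant coefficient
  set.seed(58)
  K <- 50
  Z <- matrix(rnorm(K * 4), K, 4,
              dimnames = list(NULL, paste0("z_", 1:4)))
  y <- 2 * Z[, 1] + rnorm(K, 0, 0.4)
  ct <- hier_data(y, Z)
  ss <- select_step2_spike_slab(ct, seed = 59)
  expect_gt(ss$group_pip["z_1"], 0.9)
  expect_true("z_1" %in% ss$selected)
  # pure noise: inclusion below 0.5 nearly always
  false_any <- 0
  for (s in 1:20) {
    set.seed(80 + s)
    y0 <- rnorm(K)
    ss0 <- select_step2_spike_slab(hier_data(y0, Z), n_iter = 1500,
                                   n_keep = 800, seed = 90 + s)
    false_any <- false_any + (length(ss0$selected) > 0)
  }
  expect_lte(false_any, 2)
  # degenerate slab: inclusion probabilities collapse to the prior
  ssd <- select_step2_spike_slab(ct, tau2_slab = 1e-10, seed = 61)
  expect_true(all(abs(ssd$pip - 0.5) < 0.08))
})

test_that("BART step 2 selects a planted linear signal", {
  hits <- 0
  for (s in 1:8) {
    set.seed(300 + s)
    K <- 50
    Z <- matrix(rnorm(K * 4), K, 4,
                dimnames = list(NULL, paste0("z_", 1:4)))
    y <- 2.5 * Z[, 1] + rnorm(K, 0, 0.3)
    ct <- hier_data(y, Z)
    dec <- select_step2_bart(ct, selection_config(L = 15, L_rep = 2,
                                                  criterion = "mi"),
                             n_iter = 600, n_keep = 300,
                             control = bart_control(n_trees = 10),
                             seed = 310 + s)
    hits <- hits + ("z_1" %in% dec$selected_x)
  }
  expect_gte(hits, 7)
})

test_that("step 2 permutation decision is invariant to affine rescaling", {
  # positive affine maps leave the internal [-0.5, 0.5] standardization
  # of the response, and hence the whole chain, exactly unchanged
  set.seed(62)
  K <- 30
  Z <- matrix(rnorm(K * 3), K, 3,
              dimnames = list(NULL, paste0("z_", 1:3)))
  y <- 1.5 * Z[, 2] + rnorm(K, 0, 0.5)
  cfg <- selection_config(L = 8, L_rep = 2, criterion = "vip")
  d1 <- suppressWarnings(
    select_step2_bart(hier_data(y, Z), cfg, n_iter = 300, n_keep = 150,
                      control = bart_control(n_trees = 8), seed = 63))
  d2 <- suppressWarnings(
    select_step2_bart(hier_data(2 * y + 10, Z), cfg, n_iter = 300,
                      n_keep = 150, control = bart_control(n_trees = 8),
                      seed = 63))
  expect_identical(d1$selected_x, d2$selected_x)
  expect_identical(d1$observed_x, d2$observed_x)
})

test_that("two-step wrapper is deterministic end to end", {
  sim <- generate_scenario(scenario_config("unbalanced", K = 12,
                                           z_structure = "constant",
                                           seed = 64))
  run <- function() two_step(
    sim$data, step1 = "bart", step2 = "bart",
    selection = selection_config(L = 5, L_rep = 2, criterion = "mi",
                                 z_mode = "constant"),
    n_iter = 200, n_keep = 100, step2_n_iter = 200, step2_n_keep = 100,
    control = bart_control(n_trees = 5), seed = 65)
  t1 <- suppressWarnings(run())
  t2 <- suppressWarnings(run())
  expect_identical(t1$selected_z, t2$selected_z)
  expect_identical(t1$step1$beta_hat, t2$step1$beta_hat)
})
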