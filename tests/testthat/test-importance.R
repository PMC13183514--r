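test_that("VIP matches the direct-summation oracle", {
  tr <- make_trace(rbind(c(2, 2), c(0, 0), c(3, 1)))
  # draw 1: (.5, .5); draw 2 has no splits: uniform; draw 3: (.75, .25)
  expect_equal(unname(compute_vip(tr)),
               c(mean(c(0.5, 0.5, 0.75)), mean(c(0.5, 0.5, 0.25))))
  # all splits on one covariate
  tr <- make_trace(rbind(c(0, 4, 0), c(0, 2, 0)))
  expect_equal(unname(compute_vip(tr)), c(0, 1, 0))
  # arbitrary 5-draw table vs hand summation
  set.seed(41)
  cts <- matrix(rpois(5 * 4, 2), 5, 4)
  tr <- make_trace(cts)
  byhand <- colMeans(t(apply(cts, 1, function(r)
    if (sum(r) == 0) rep(0.25, 4) else r / sum(r))))
  expect_equal(unname(compute_vip(tr)), byhand)
  expect_equal(sum(compute_vip(tr)), 1)
})

test_that("within-type VIP normalizes inside each covariate type", {
  # all continuous: identical to plain VIP
  tr <- make_trace(rbind(c(2, 2), c(3, 1)))
  expect_equal(compute_vip_type(tr), compute_vip(tr))
  # mixed types: binary covariate with the only binary split scores 1
  cts <- rbind(c(5, 3, 2), c(1, 0, 4))
  tr <- make_trace(cts, x_type = c("continuous", "continuous", "binary"))
  byhand <- rbind(c(5 / 8, 3 / 8, 1), c(1, 0, 1))
  expect_equal(unname(compute_vip_type(tr)), colMeans(byhand))
  # a type with zero splits contributes zero, not NaN
  cts <- rbind(c(2, 0), c(3, 0))
  tr <- make_trace(cts, x_type = c("continuous", "binary"))
  expect_equal(unname(compute_vip_type(tr)), c(1, 0))
})

test_that("MI matches the direct-summation oracle", {
  # recorded (sum of acceptance, count) per covariate over 4 draws
  mi_sum <- rbind(c(0.9, 0.1), c(0, 0.5), c(0, 0), c(0.6, 0.6))
  mi_cnt <- rbind(c(1, 1), c(0, 1), c(0, 0), c(2, 1))
  tr <- make_trace(mi_cnt, mi_sum = mi_sum, mi_cnt = mi_cnt)
  perdraw <- rbind(c(0.9, 0.1) / 1, c(0, 0.5), c(0, 0), c(0.3, 0.6))
  norm <- t(apply(perdraw, 1, function(r)
    if (sum(r) == 0) c(0.5, 0.5) else r / sum(r)))
  expect_equal(unname(compute_mi(tr)), colMeans(norm))
  expect_equal(sum(compute_mi(tr)), 1)
  # single covariate ever split
  tr <- make_trace(rbind(c(2, 0)), mi_sum = rbind(c(1.4, 0)),
                   mi_cnt = rbind(c(2, 0)))
  expect_equal(unname(compute_mi(tr)), c(1, 0))
  # identical acceptance histories give equal scores
  tr <- make_trace(rbind(c(3, 3)), mi_sum = rbind(c(1.2, 1.2)),
                   mi_cnt = rbind(c(3, 3)))
  expect_equal(unname(compute_mi(tr)), c(0.5, 0.5))
})

test_that("LPS tallies submodel frequencies with dummy groups merged", {
  z_names <- c("(Intercept)", "z_1", "z_2.a", "z_2.b")
  z_group <- list(z_1 = "z_1", z_2 = c("z_2.a", "z_2.b"))
  v <- rbind(c(1, 1, 1, 0),
             c(0, 1, 0, 1),
             c(1, 1, 0, 0),
             c(1, 0, 0, 0))
  colnames(v) <- z_names
  tr <- make_trace(matrix(0, 4, 2), v = v, z_names = z_names,
                   z_group = z_group)
  lps <- compute_lps(tr)
  expect_equal(sum(lps), 1)
  # draws 1 and 2 both activate {z_1, z_2} (any dummy counts)
  expect_equal(unname(lps["11"]), 0.5)
  expect_equal(unname(lps["10"]), 0.25)
  expect_equal(unname(lps["00"]), 0.25)
  expect_equal(mixbart:::mask_to_groups("11", names(z_group)),
               c("z_1", "z_2"))
  # degenerate: every draw the same submodel
  v1 <- v; v1[] <- rep(c(1, 1, 0, 0), each = 4)
  tr1 <- make_trace(matrix(0, 4, 2), v = v1, z_names = z_names,
                    z_group = z_group)
  expect_equal(unname(compute_lps(tr1)["10"]), 1)
})

test_that("categorical aggregation sums and conserves scores", {
  sc <- c(a = 0.1, b1 = 0.1, b2 = 0.2, b3 = 0.05, c = 0.55)
  gr <- list(a = "a", b = c("b1", "b2", "b3"), c = "c")
  ag <- aggregate_categorical(sc, gr)
  expect_equal(unname(ag["b"]), 0.35)
  expect_equal(sum(ag), sum(sc))
  # identity when no categoricals
  gr0 <- list(a = "a", c = "c")
  expect_equal(unname(aggregate_categorical(sc, gr0)),
               unname(sc[c("a", "c")]))
  expect_error(aggregate_categorical(sc, list(a = "a", b = "a")),
               "overlap")
})

test_that("elbow cutoff finds the largest drop", {
  expect_equal(elbow_cutoff(c(0.4, 0.35, 0.05, 0.05)), 2L)
  expect_equal(elbow_cutoff(c(0.9, 0.05, 0.05)), 1L)
  expect_equal(elbow_cutoff(c(0.3, 0.3, 0.3)), 0L)
  expect_error(elbow_cutoff(c(0.1, 0.5)), "descending")
  # invariant to trailing zeros below the elbow (brute-force check)
  set.seed(43)
  for (i in 1:50) {
    p <- sort(runif(sample(3:8, 1)), decreasing = TRUE)
    k <- elbow_cutoff(p)
    if (k >= 1 && min(p) > 0)
      expect_equal(elbow_cutoff(c(p, 0, 0)),
                   if (p[length(p)] - 0 > max(-diff(p))) length(p)
                   else k)
  }
})

test_that("within-cluster permutation preserves the right structure", {
  sim <- generate_scenario(scenario_config("balanced", K = 6,
                                           cluster_size = 8, seed = 44))
  d <- sim$data
  set.seed(45)
  pv <- permute_dataset(d, "variant")
  # X untouched, cluster labels untouched, y multiset preserved per cluster
  expect_identical(pv$X, d$X)
  expect_identical(pv$cluster, d$cluster)
  for (rows in split(seq_along(d$y), d$cluster)) {
    expect_equal(sort(pv$y[rows]), sort(d$y[rows]))
    # column means of Z per cluster invariant under joint row permutation
    expect_equal(colMeans(pv$Z[rows, -1]), colMeans(d$Z[rows, -1]))
  }
  # constant mode leaves Z identical
  pc <- permute_dataset(d, "constant")
  expect_identical(pc$Z, d$Z)
  # singleton clusters: identity
  d1 <- hier_data(1:3, matrix(rnorm(3), 3, 1),
                  cluster = factor(1:3), Z = cbind(1, rnorm(3)))
  p1 <- permute_dataset(d1, "variant")
  expect_identical(p1$y, d1$y)
  expect_equal(attr(p1, "singletons"), 3L)
})

test_that("within-cluster y permutations are uniform over orderings", {
  # one 5-row cluster: all 120 orderings equally likely
  d <- hier_data(1:5, matrix(0, 5, 1), cluster = factor(rep(1, 5)),
                 Z = matrix(1, 5, 1))
  set.seed(46)
  n_rep <- 12000
  codes <- integer(n_rep)
  for (i in seq_len(n_rep))
    codes[i] <- sum(permute_dataset(d, "constant")$y * 10^(0:4))
  tab <- table(codes)
  expect_equal(length(tab), 120L)
  expected <- n_rep / 120
  expect_true(all(abs(tab - expected) < 4 * sqrt(expected)))
})

test_that("the quantile decision rule is conservative and monotone", {
  null_x <- cbind(a = seq(0.01, 1, length.out = 100),
                  b = seq(0.01, 1, length.out = 100))
  dec <- structure(list(
    observed_x = c(a = 1.5, b = 0.5), null_x = null_x,
    null_lps = NULL, n_keep = 100, z_group = NULL,
    selection = selection_config(L = 100), dropped_chains = 0L),
    class = "selection_decision")
  d05 <- apply_selection(dec, 0.05)
  # a exceeds every null draw; b equals the null median: not selected
  expect_equal(d05$selected_x, "a")
  expect_equal(unname(d05$null_quantile_x["a"]),
               sort(null_x[, "a"])[95])
  # monotonicity in alpha: selected sets are nested
  prev <- character()
  for (alpha in c(0.01, 0.05, 0.1, 0.3, 0.5)) {
    sel <- apply_selection(dec, alpha)$selected_x
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})

test_that("permutation selection is reproducible and sums check out", {
  d <- make_cluster_data(K = 8, nk = 6, lambda_true = c(1, 0.6),
                         sigma = 0.5, seed = 47)
  cfg <- selection_config(L = 4, L_rep = 2, criterion = "vip",
                          z_mode = "variant")
  dec1 <- suppressWarnings(
    permutation_select(d, cfg, n_iter = 150, n_keep = 80,
                       control = bart_control(n_trees = 5), seed = 48))
  dec2 <- suppressWarnings(
    permutation_select(d, cfg, n_iter = 150, n_keep = 80,
                       control = bart_control(n_trees = 5), seed = 48))
  expect_identical(dec1$selected_x, dec2$selected_x)
  expect_identical(dec1$selected_z, dec2$selected_z)
  expect_identical(dec1$observed_x, dec2$observed_x)
  expect_identical(dec1$null_x, dec2$null_x)
  # score normalizations on the real decision
  expect_equal(sum(dec1$observed$vip), 1, tolerance = 1e-12)
  expect_equal(sum(dec1$observed$mi), 1, tolerance = 1e-12)
  expect_equal(sum(dec1$observed$lps), 1, tolerance = 1e-12)
  # reproducible decision record: selected Z reconstructable from masks
  expect_equal(dec1$selected_z,
               mixbart:::mask_to_groups(dec1$selected_mask,
                                        names(d$z_group)))
})
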