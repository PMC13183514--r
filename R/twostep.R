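#' Step 1 (BART): estimate cluster random intercepts
#'
#' Fits the unified model with a random-intercept-only structure
#' (Q = 1, the spike-and-slab machinery retained) and extracts the
#' posterior mean of each cluster's intercept effect.
#'
#' @param data a \code{\link{hier_data}} with a cluster assignment (its
#'   Z design, if any, is replaced by the intercept-only column).
#' @param n_iter,n_keep chain length.
#' @param control,hyper model settings.
#' @param seed integer seed.
#' @return A \code{cluster_effects} list: \code{beta_hat} (posterior
#'   mean intercepts, one per cluster, on the outcome scale),
#'   \code{sd} (posterior standard deviations, for diagnostics),
#'   \code{clusters}, and \code{source = "bart_step1"}.
#' @export
fit_step1_bart <- function(data, n_iter = 10000, n_keep = 5000,
                           control = bart_control(),
                           hyper = model_hyper(), seed = NULL) {
  stopifnot(inherits(data, "hier_data"), !is.null(data$cluster))
  d1 <- hier_data(data$y, data$X, cluster = data$cluster,
                  Z = matrix(1, length(data$y), 1,
                             dimnames = list(NULL, "(Intercept)")),
                  x_type = data$x_type, x_group = data$x_group,
                  z_group = list())
  tr <- unified_fit(d1, n_iter, n_keep, control, hyper, seed = seed)
  structure(list(beta_hat = setNames(tr$coef_mean[, 1],
                                     tr$cluster_levels),
                 sd = setNames(tr$coef_sd[, 1], tr$cluster_levels),
                 clusters = tr$cluster_levels,
                 source = "bart_step1", trace = tr),
            class = "cluster_effects")
}

#' Step 1 (Bayesian linear): estimate cluster random intercepts
#'
#' Gibbs sampler for the Gaussian linear mixed model
#' \code{y = alpha0 + X alpha + u_k + eps}, with weakly informative
#' conjugate priors: N(0, 100) coefficients on the internally
#' standardized outcome, inverse-gamma(0.001, 0.001) variance
#' components. Returns posterior-mean random intercepts.
#'
#' @param data a \code{\link{hier_data}}.
#' @param n_iter,n_keep chain length (defaults 4000 / 2000).
#' @param seed integer seed.
#' @return A \code{cluster_effects} list with
#'   \code{source = "linear_step1"}.
#' @export
fit_step1_linear <- function(data, n_iter = 4000, n_keep = 2000,
                             seed = NULL) {
  stopifnot(inherits(data, "hier_data"), !is.null(data$cluster))
  if (!is.null(seed)) set.seed(seed)
  ysd <- sd(data$y); if (ysd == 0) ysd <- 1
  ym <- mean(data$y)
  ys <- (data$y - ym) / ysd
  Xd <- cbind(1, data$X)
  if (qr(Xd)$rank < ncol(Xd))
    stop("fixed-effects design is rank deficient")
  n <- length(ys)
  ci <- as.integer(data$cluster)
  K <- nlevels(data$cluster)
  nk <- tabulate(ci, K)
  XtX <- crossprod(Xd)
  p <- ncol(Xd)
  tau_a2 <- 100           # coefficient prior variance (standardized y)
  a0 <- b0 <- 1e-3        # inverse-gamma shape/rate for variances

  alpha <- numeric(p)
  u <- numeric(K)
  psi <- 0.5
  sigma2 <- 0.5
  usum <- numeric(K); usq <- numeric(K)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    r_u <- ys - u[ci]
    Vinv <- XtX / sigma2 + diag(1 / tau_a2, p)
    ch <- chol(Vinv)
    mvec <- backsolve(ch, forwardsolve(t(ch), crossprod(Xd, r_u) / sigma2))
    alpha <- as.vector(mvec + backsolve(ch, rnorm(p)))
    r_a <- ys - as.vector(Xd %*% alpha)
    postv <- 1 / (nk / sigma2 + 1 / psi)
    postm <- postv * (rowsum(r_a, ci)[, 1] / sigma2)
    u <- rnorm(K, postm, sqrt(postv))
    psi <- 1 / rgamma(1, a0 + K / 2, b0 + sum(u^2) / 2)
    ssr <- sum((r_a - u[ci])^2)
    sigma2 <- 1 / rgamma(1, a0 + n / 2, b0 + ssr / 2)
    if (it > n_iter - n_keep) {
      kept <- kept + 1L
      usum <- usum + u
      usq <- usq + u^2
    }
  }
  bh <- usum / kept * ysd
  bsd <- sqrt(pmax(usq / kept - (usum / kept)^2, 0)) * ysd
  structure(list(beta_hat = setNames(bh, levels(data$cluster)),
                 sd = setNames(bsd, levels(data$cluster)),
                 clusters = levels(data$cluster),
                 source = "linear_step1"),
            class = "cluster_effects")
}

#' @export
print.cluster_effects <- function(x, ...) {
  cat("cluster_effects (", x$source, "): K = ", length(x$beta_hat),
      ", range [", signif(min(x$beta_hat), 3), ", ",
      signif(max(x$beta_hat), 3), "]\n", sep = "")
  invisible(x)
}

#' Build the Step 2 cluster-level regression table
#'
#' One row per cluster: the estimated random intercept as response and
#' the cluster's (verified constant-within-cluster) Z values, intercept
#' column dropped, as predictors. Dummy groups are carried through.
#'
#' @param estimate a \code{cluster_effects} from a Step 1 fit.
#' @param data the \code{\link{hier_data}} the estimate came from; its
#'   Z must be constant within clusters.
#' @param tol within-cluster equality tolerance.
#' @return A \code{hier_data} with K rows, response \code{beta_hat},
#'   covariates the cluster-level Z values, and no cluster/Z structure.
#' @export
build_step2_dataset <- function(estimate, data, tol = 1e-8) {
  stopifnot(inherits(estimate, "cluster_effects"),
            inherits(data, "hier_data"), !is.null(data$Z))
  check_z_constant(data, tol)
  rows <- cluster_rows(data)
  if (!identical(names(rows), estimate$clusters))
    stop("cluster sets of the estimate and the dataset differ")
  Zc <- t(vapply(rows, function(ix) data$Z[ix[1], -1],
                 numeric(ncol(data$Z) - 1)))
  colnames(Zc) <- colnames(data$Z)[-1]
  ztype <- ifelse(apply(Zc, 2, function(v) all(v %in% c(0, 1))),
                  "binary", "continuous")
  hier_data(estimate$beta_hat, Zc, cluster = NULL,
            x_type = ztype, x_group = data$z_group)
}

#' Step 2 (BART): permutation-calibrated cluster-level selection
#'
#' Fits plain BART regressions of the estimated intercepts on the
#' cluster-level covariates: \code{L_rep} chains on the observed table
#' and one chain on each of \code{L} tables with the response permuted
#' across clusters (each cluster is one exchangeable unit). A covariate
#' is selected when its observed importance score (dummy groups summed)
#' exceeds the (1 - alpha) null quantile.
#'
#' @param cluster_table output of \code{\link{build_step2_dataset}}.
#' @param selection a \code{\link{selection_config}}.
#' @param n_iter,n_keep chain length per fit.
#' @param control,hyper model settings.
#' @param seed master seed.
#' @return A \code{selection_decision}; the selected covariates are in
#'   \code{selected_x} (they are cluster-level covariates of the
#'   original model) and mirrored in \code{selected_z}.
#' @export
select_step2_bart <- function(cluster_table,
                              selection = selection_config(),
                              n_iter = 10000, n_keep = 5000,
                              control = bart_control(),
                              hyper = model_hyper(), seed = NULL) {
  stopifnot(inherits(cluster_table, "hier_data"))
  K <- length(cluster_table$y)
  if (K < 10)
    warning("only ", K, " clusters; Step 2 selection will be unstable")
  if (sd(cluster_table$y) == 0)
    warning("degenerate (constant) intercept estimates; nothing selectable")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      selection$L_rep + 2L * selection$L)
  obs_tr <- lapply(seq_len(selection$L_rep), function(i)
    trace_scores(unified_fit(cluster_table, n_iter, n_keep, control,
                             hyper, seed = seeds[i])))
  agg <- function(key, fun) {
    m <- do.call(rbind, lapply(obs_tr, `[[`, key))
    apply(m, 2, fun)
  }
  observed <- list(vip = agg("vip", mean),
                   vip_type = agg("vip_type", mean),
                   mi = agg("mi", median), lps = NULL)

  failed <- 0L
  null_scores <- vector("list", selection$L)
  for (l in seq_len(selection$L)) {
    set.seed(seeds[selection$L_rep + l])
    dp <- cluster_table
    dp$y <- dp$y[sample.int(K)]
    sc <- tryCatch(
      trace_scores(unified_fit(dp, n_iter, n_keep, control, hyper,
                               seed = seeds[selection$L_rep +
                                              selection$L + l])),
      error = function(e) NULL)
    if (is.null(sc)) failed <- failed + 1L else null_scores[[l]] <- sc
  }
  null_scores <- Filter(Negate(is.null), null_scores)
  if (!length(null_scores)) stop("all permutation chains failed")

  crit <- selection$criterion
  obs_x <- aggregate_categorical(observed[[crit]],
                                 cluster_table$x_group)
  null_x <- do.call(rbind, lapply(null_scores, function(sc)
    aggregate_categorical(sc[[crit]], cluster_table$x_group)))
  dec <- list(observed = observed, observed_x = obs_x, null_x = null_x,
              null_lps = NULL, n_keep = n_keep,
              x_group = cluster_table$x_group, z_group = NULL,
              selection = selection,
              aggregation = c(vip = "mean", vip_type = "mean",
                              mi = "median"),
              dropped_chains = failed, seed = seed)
  class(dec) <- "selection_decision"
  dec <- apply_selection(dec, selection$alpha)
  dec$selected_z <- dec$selected_x
  dec
}

#' Step 2 (spike-and-slab linear): cluster-level selection
#'
#' Gibbs sampler for the linear regression of the estimated intercepts
#' on standardized cluster-level covariates with independent
#' spike-and-slab priors \code{phi_j ~ (1 - omega_j) delta_0 +
#' omega_j N(0, tau2_slab)}, \code{omega_j ~ Bernoulli(pi0)}. Each
#' omega_j is drawn with phi_j integrated out, then phi_j from its
#' conjugate normal (or set to zero). A covariate is selected when its
#' posterior inclusion probability exceeds 0.5 (the median probability
#' model); a dummy group is selected when any of its columns is (the
#' any-dummy group rule).
#'
#' @param cluster_table output of \code{\link{build_step2_dataset}}.
#' @param pi0 prior inclusion probability (default 0.5).
#' @param tau2_slab slab variance on standardized predictors (default 10).
#' @param n_iter,n_keep chain length (defaults 4000 / 2000).
#' @param seed integer seed.
#' @return List with \code{selected} (group names), \code{pip}
#'   (per-column posterior inclusion probabilities), \code{group_pip}
#'   (max within group), and settings.
#' @export
select_step2_spike_slab <- function(cluster_table, pi0 = 0.5,
                                    tau2_slab = 10, n_iter = 4000,
                                    n_keep = 2000, seed = NULL) {
  stopifnot(inherits(cluster_table, "hier_data"))
  if (!is.null(seed)) set.seed(seed)
  y <- cluster_table$y
  ysd <- sd(y); if (ysd == 0) ysd <- 1
  ys <- (y - mean(y)) / ysd
  Z <- scale(cluster_table$X)
  Z[, attr(Z, "scale") == 0] <- 0
  K <- length(ys)
  p <- ncol(Z)
  zz <- colSums(Z^2)

  omega <- rep(1L, p)
  phi <- numeric(p)
  sigma2 <- 1
  eta <- as.vector(Z %*% phi)
  pip_acc <- numeric(p)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      rj <- ys - eta + Z[, j] * phi[j]
      A <- zz[j] / sigma2 + 1 / tau2_slab
      m <- sum(Z[, j] * rj) / sigma2 / A
      log_ratio <- 0.5 * A * m^2 - 0.5 * log(A * tau2_slab)
      p1 <- plogis(log(pi0) - log1p(-pi0) + log_ratio)
      omega[j] <- as.integer(runif(1) < p1)
      new_phi <- if (omega[j] == 1L) rnorm(1, m, sqrt(1 / A)) else 0
      eta <- eta + (new_phi - phi[j]) * Z[, j]
      phi[j] <- new_phi
    }
    ssr <- sum((ys - eta)^2)
    sigma2 <- 1 / rgamma(1, 0.01 + K / 2, 0.01 + ssr / 2)
    if (it > n_iter - n_keep) {
      kept <- kept + 1L
      pip_acc <- pip_acc + omega
    }
  }
  pip <- setNames(pip_acc / kept, colnames(cluster_table$X))
  group_pip <- vapply(cluster_table$x_group,
                      function(g) max(pip[g]), numeric(1))
  list(selected = names(which(group_pip > 0.5)), pip = pip,
       group_pip = group_pip, pi0 = pi0, tau2_slab = tau2_slab,
       group_rule = "any-dummy-included", seed = seed)
}

#' The two-step procedure for cluster-constant covariates
#'
#' Step 1 estimates cluster random intercepts (BART with a
#' random-intercept-only structure, or a Bayesian linear mixed model);
#' Step 2 selects cluster-level covariates by regressing the estimated
#' intercepts on Z, either with BART importance scores calibrated by
#' permuting the intercepts across clusters, or with a spike-and-slab
#' linear model and the median-probability rule. Decoupling the two
#' stages avoids the near-collinearity between cluster-constant
#' covariates and the random intercept that destabilizes joint
#' selection.
#'
#' @param data a \code{\link{hier_data}} whose Z is constant within
#'   clusters.
#' @param step1 \code{"bart"} or \code{"linear"}.
#' @param step2 \code{"bart"} or \code{"spike_slab"}.
#' @param selection a \code{\link{selection_config}} (BART Step 2).
#' @param n_iter,n_keep Step 1 chain length.
#' @param step2_n_iter,step2_n_keep Step 2 chain length per fit.
#' @param control,hyper model settings.
#' @param seed master seed.
#' @return List of class \code{two_step_fit}: \code{selected_z},
#'   \code{step1} (the \code{cluster_effects}), \code{step2} (the Step
#'   2 decision object), and the configuration.
#' @export
two_step <- function(data, step1 = c("bart", "linear"),
                     step2 = c("bart", "spike_slab"),
                     selection = selection_config(),
                     n_iter = 10000, n_keep = 5000,
                     step2_n_iter = n_iter, step2_n_keep = n_keep,
                     control = bart_control(), hyper = model_hyper(),
                     seed = NULL) {
  step1 <- match.arg(step1)
  step2 <- match.arg(step2)
  if (!is.null(seed)) set.seed(seed)
  s <- sample.int(.Machine$integer.max, 2)
  est <- if (step1 == "bart") {
    fit_step1_bart(data, n_iter, n_keep, control, hyper, seed = s[1])
  } else {
    fit_step1_linear(data, seed = s[1])
  }
  ct <- build_step2_dataset(est, data)
  s2 <- if (step2 == "bart") {
    select_step2_bart(ct, selection, step2_n_iter, step2_n_keep,
                      control, hyper, seed = s[2])
  } else {
    select_step2_spike_slab(ct, seed = s[2])
  }
  sel <- if (step2 == "bart") s2$selected_z else s2$selected
  structure(list(selected_z = sel, step1 = est, step2 = s2,
                 step1_method = step1, step2_method = step2,
                 seed = seed),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat("two_step_fit (step1 ", x$step1_method, ", step2 ",
      x$step2_method, ")\n  selected Z: ",
      if (length(x$selected_z)) paste(x$selected_z, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}
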