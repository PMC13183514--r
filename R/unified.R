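#' Hyperparameters of the random-effects and residual components
#'
#' Defaults follow the reference specification: slab mean 0 and variance
#' 30 for each random-effect scale lambda_q, Jeffreys Beta(0.5, 0.5)
#' prior on the inclusion probabilities, N(0, 0.5 I) prior on the free
#' entries of the unit lower-triangular correlation factor, and a scaled
#' inverse-chi-squared residual prior with nu = 3 degrees of freedom and
#' an empirical-Bayes scale matched to the residual variance of an
#' initial least-squares fit (computed at fitting time when
#' \code{tau2 = NULL}).
#'
#' @param theta,s2 slab mean and variance of the truncated-normal
#'   component for each lambda_q (recycled over q).
#' @param c,d Beta prior parameters of the inclusion probabilities.
#' @param gamma0 prior mean of the free gamma entries.
#' @param r0_scale prior covariance of gamma is \code{r0_scale * I}.
#' @param nu residual prior degrees of freedom.
#' @param tau2 residual prior scale; \code{NULL} for empirical Bayes.
#' @return A \code{model_hyper} list.
#' @export
model_hyper <- function(theta = 0, s2 = 30, c = 0.5, d = 0.5,
                        gamma0 = 0, r0_scale = 0.5, nu = 3, tau2 = NULL) {
  stopifnot(all(s2 > 0), all(c > 0), all(d > 0), r0_scale > 0, nu > 0)
  structure(list(theta = theta, s2 = s2, c = c, d = d, gamma0 = gamma0,
                 r0_scale = r0_scale, nu = nu, tau2 = tau2),
            class = "model_hyper")
}

#' Modified Cholesky decomposition of a random-effects covariance
#'
#' Factors a symmetric positive semidefinite D as
#' \code{D = Lambda Gamma Gamma' Lambda} with Lambda diagonal
#' nonnegative and Gamma unit lower-triangular. Zero scale components
#' are handled by the identifiability constraint: whenever
#' \code{lambda_u = 0} or \code{lambda_q = 0} the corresponding free
#' entry of Gamma is zero.
#'
#' @param D a symmetric positive semidefinite matrix.
#' @param tol relative pivot tolerance for detecting zero components.
#' @return List with \code{lambda} (diagonal of Lambda) and
#'   \code{Gamma}.
#' @export
decompose_covariance <- function(D, tol = 1e-12) {
  D <- as.matrix(D)
  Q <- nrow(D)
  if (ncol(D) != Q || max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("D must be symmetric")
  scale <- max(diag(D), 0)
  L <- matrix(0, Q, Q)
  lambda <- numeric(Q)
  for (q in seq_len(Q)) {
    piv <- D[q, q] - sum(L[q, seq_len(q - 1)]^2)
    if (piv < -tol * max(1, scale) - 1e-8)
      stop("D is not positive semidefinite")
    if (piv <= tol * max(1, scale)) {
      lambda[q] <- 0
      # a zero-scale component must carry no covariance at all, else
      # the constraint gamma_{uq} = 0 cannot reproduce D
      bad <- any(abs(L[q, seq_len(q - 1)]) > 1e-8 * max(1, sqrt(scale)))
      if (!bad && q < Q) {
        resid_col <- D[seq(q + 1, Q), q] -
          L[seq(q + 1, Q), seq_len(q - 1), drop = FALSE] %*%
          L[q, seq_len(q - 1)]
        bad <- max(abs(resid_col)) > 1e-8 * max(1, scale)
      }
      if (bad)
        stop("component ", q, " has zero scale but nonzero ",
             "covariance; D is not representable under the ",
             "identifiability constraint")
      L[q, seq_len(q - 1)] <- 0
      next
    }
    lambda[q] <- sqrt(piv)
    L[q, q] <- lambda[q]
    if (q < Q) {
      for (u in seq(q + 1, Q)) {
        L[u, q] <- (D[u, q] -
                      sum(L[u, seq_len(q - 1)] * L[q, seq_len(q - 1)])) /
          lambda[q]
      }
    }
  }
  Gamma <- diag(Q)
  for (q in seq_len(Q)) {
    if (lambda[q] > 0) {
      idx <- which(lambda > 0 & seq_len(Q) > q)
      for (u in idx) Gamma[u, q] <- L[u, q] / lambda[u]
    }
  }
  list(lambda = lambda, Gamma = Gamma)
}

# draw from N(mean, sd^2) truncated to (0, Inf); inverse-CDF in the
# central regime, exponential rejection (Robert 1995) deep in the tail
rtnorm_pos <- function(mean, sd) {
  alpha <- -mean / sd
  if (alpha < 5) {
    u <- runif(1, pnorm(alpha), 1)
    mean + sd * qnorm(u)
  } else {
    a <- (alpha + sqrt(alpha^2 + 4)) / 2
    repeat {
      x <- alpha + rexp(1, a)
      if (runif(1) <= exp(-(x - a)^2 / 2)) return(mean + sd * x)
    }
  }
}

#' Collapsed inclusion update for one random-effect scale
#'
#' For the scalar regression of the current residual r on
#' \code{t = Z_q (Gamma b)_q} with lambda_q given the truncated-normal
#' slab TN(theta, s2, (0, Inf)), the marginal likelihood ratio of the
#' slab to the spike is available in closed form: with
#' \code{A = t't / sigma2 + 1/s2} and
#' \code{m = (t'r / sigma2 + theta/s2) / A},
#' \deqn{\log(L_1/L_0) = A m^2/2 - \theta^2/(2 s^2) - \log(A s^2)/2 +
#'   \log\Phi(m\sqrt{A}) - \log\Phi(\theta/s).}
#' The inclusion indicator is Bernoulli with probability
#' \code{pi L1 / (pi L1 + (1 - pi) L0)}, and given inclusion the
#' conjugate full conditional of lambda_q is TN(m, 1/A, (0, Inf)).
#'
#' @param tt sum of squares t't.
#' @param tr cross product t'r.
#' @param sigma2 residual variance.
#' @param theta,s2 slab mean and variance.
#' @param pi prior inclusion probability.
#' @return List with \code{p1} (posterior inclusion probability),
#'   \code{mean} and \code{var} of the untruncated conjugate update
#'   (lambda-hat and s-hat squared), and \code{log_ratio}.
#' @export
inclusion_update <- function(tt, tr, sigma2, theta, s2, pi) {
  A <- tt / sigma2 + 1 / s2
  m <- (tr / sigma2 + theta / s2) / A
  log_ratio <- 0.5 * A * m^2 - theta^2 / (2 * s2) - 0.5 * log(A * s2) +
    pnorm(m * sqrt(A), log.p = TRUE) -
    pnorm(theta / sqrt(s2), log.p = TRUE)
  if (!is.finite(log_ratio)) stop("non-finite marginal likelihood ratio")
  p1 <- plogis(log(pi) - log1p(-pi) + log_ratio)
  list(p1 = p1, mean = m, var = 1 / A, log_ratio = log_ratio)
}

#' Conjugate posterior of the free Gamma entries
#'
#' Given the regressor matrix U (one column per active free entry of
#' Gamma), response r2 (residual net of the diagonal random-effects
#' part), residual variance and the N(g0, r0_scale I) prior, returns
#' the MVN full-conditional mean and upper Cholesky factor of the
#' posterior precision.
#'
#' @param U regressor matrix (n x m).
#' @param r2 response vector.
#' @param sigma2 residual variance.
#' @param r0_scale prior variance of each entry.
#' @param g0 prior mean vector (recycled).
#' @return List with \code{mean} and \code{chol_prec}.
#' @export
gamma_posterior <- function(U, r2, sigma2, r0_scale, g0 = 0) {
  m <- ncol(U)
  g0 <- rep_len(g0, m)
  A <- crossprod(U) / sigma2 + diag(1 / r0_scale, m)
  ch <- chol(A)
  mean <- backsolve(ch, forwardsolve(t(ch),
                                     crossprod(U, r2) / sigma2 +
                                       g0 / r0_scale))
  list(mean = as.vector(mean), chol_prec = ch)
}

# index map for the free entries of Gamma: pairs (q, u) with u < q,
# stacked column-major in u then q (gamma_{qu})
gamma_pairs <- function(Q) {
  if (Q < 2) return(matrix(integer(), 0, 2))
  do.call(rbind, lapply(2:Q, function(q) cbind(q = q, u = seq_len(q - 1))))
}

assemble_gamma <- function(gvec, Q) {
  G <- diag(Q)
  pr <- gamma_pairs(Q)
  if (nrow(pr)) G[pr] <- gvec
  G
}

#' Fit the unified BART mixed-effects model
#'
#' Runs the partially collapsed Gibbs sampler: (1) one Bayesian
#' backfitting sweep of the sum-of-trees ensemble against the outcome
#' minus the random-effects contribution, (2) refresh of the fit vector,
#' (3) conjugate MVN draw of the latent standard-normal cluster effects
#' b_k, (4) conjugate MVN draw of the free entries of Gamma (subject to
#' the identifiability constraint tied to zero lambdas), (5) Beta draw
#' of each inclusion probability, (6)-(8) the atomic collapsed update of
#' each (v_q, lambda_q) pair -- v_q from its lambda-marginalized
#' conditional, then lambda_q from its truncated-normal full conditional
#' (or set to zero) -- and (9) a scaled inverse-chi-squared draw of the
#' residual variance. Steps (6)-(8) are executed as one block per
#' component with no interleaved updates, which the validity of the
#' partially collapsed sampler requires.
#'
#' The outcome is internally standardized to [-0.5, 0.5]; all reported
#' quantities are returned on the original scale. With \code{Z = NULL}
#' (or a \code{hier_data} without Z) the model reduces to plain BART
#' regression.
#'
#' @param data a \code{\link{hier_data}} object.
#' @param n_iter,n_keep total and retained iterations (defaults 10000
#'   and 5000).
#' @param control a \code{\link{bart_control}}; \code{n_trees = 0}
#'   disables the tree component (f = 0), for diagnostics.
#' @param hyper a \code{\link{model_hyper}}.
#' @param seed optional integer seed.
#' @param standardize standardize the outcome internally (default TRUE).
#' @param sigma2_fixed optionally freeze the residual variance
#'   (diagnostic use; skips step 9).
#' @param lambda_fixed optionally freeze the lambda vector (diagnostic
#'   use; skips steps 5-8).
#' @param keep_coef retain the per-draw intercept-column cluster
#'   coefficients (an M x K matrix) in the trace, for diagnostics.
#' @return A \code{mixbart_trace} object: per-retained-draw split
#'   counts, BIRTH acceptance accumulators, inclusion indicators v,
#'   lambda, sigma2 (original scale), Dirichlet splitting probabilities
#'   (sparse mode), posterior running mean/sd of the per-cluster
#'   coefficients Lambda Gamma b (original scale), and bookkeeping
#'   (types, groups, seed, settings).
#' @export
unified_fit <- function(data, n_iter = 10000, n_keep = 5000,
                        control = bart_control(), hyper = model_hyper(),
                        seed = NULL, standardize = TRUE,
                        sigma2_fixed = NULL, lambda_fixed = NULL,
                        keep_coef = FALSE) {
  stopifnot(inherits(data, "hier_data"), n_keep <= n_iter, n_keep >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- data$y
  n <- length(y)
  X <- data$X
  P <- ncol(X)

  if (standardize) {
    y0 <- min(y); yr <- diff(range(y))
    if (yr == 0) yr <- 1
    ys <- (y - y0) / yr - 0.5
  } else {
    y0 <- 0; yr <- 1; ys <- y
  }

  # empirical-Bayes residual scale from an initial least-squares fit
  ls_fit <- stats::lm.fit(cbind(1, X), ys)
  df_res <- max(1, n - ncol(X) - 1)
  sig_ls2 <- sum(ls_fit$residuals^2) / df_res
  tau2 <- if (is.null(hyper$tau2)) sig_ls2 else hyper$tau2 / yr^2
  nu <- hyper$nu

  use_trees <- control$n_trees > 0
  if (use_trees) {
    srange <- if (standardize) 1 else diff(range(ys))
    sigma_mu <- max(srange, .Machine$double.eps) /
      (2 * control$k * sqrt(control$n_trees))
    fptr <- .forest_create(X, as.integer(data$x_type == "binary"),
                           control$n_trees, control$a, control$b,
                           sigma_mu, rep(1 / P, P))
  }

  re <- !is.null(data$Z)
  if (re) {
    Z <- data$Z
    Q <- ncol(Z)
    ci <- as.integer(data$cluster)
    K <- nlevels(data$cluster)
    nk_tab <- tabulate(ci, nlevels(data$cluster))
    Szz_mat <- vapply(split(seq_len(n), ci),
                      function(ix) as.vector(crossprod(Z[ix, , drop = FALSE])),
                      numeric(Q * Q))
    Szz_mat <- matrix(Szz_mat, Q * Q)
    theta <- rep_len(hyper$theta, Q)
    s2 <- rep_len(hyper$s2, Q)
    cq <- rep_len(hyper$c, Q)
    dq <- rep_len(hyper$d, Q)
    pr <- gamma_pairs(Q)
    npair <- nrow(pr)
    g0 <- rep_len(hyper$gamma0, npair)
    r0inv <- 1 / hyper$r0_scale

    # dispersed initialization: half-normal lambda, prior b, pi at its
    # prior mean
    if (!is.null(lambda_fixed)) {
      lambda <- rep_len(lambda_fixed, Q) / yr
      v <- as.integer(lambda > 0)
    } else {
      lambda <- abs(rnorm(Q, 0, 0.2))
      v <- rep(1L, Q)
    }
    gvec <- rep(0, npair)
    Gamma <- assemble_gamma(gvec, Q)
    b <- matrix(rnorm(K * Q), K, Q)
    pi_q <- rep(0.5, Q)
  } else {
    Q <- 0; K <- 0
  }

  sigma2 <- if (is.null(sigma2_fixed)) sig_ls2 else sigma2_fixed / yr^2

  M <- n_keep
  keep_from <- n_iter - n_keep + 1
  counts <- matrix(0L, M, P, dimnames = list(NULL, colnames(X)))
  mi_sum <- matrix(0, M, P, dimnames = list(NULL, colnames(X)))
  mi_cnt <- matrix(0L, M, P, dimnames = list(NULL, colnames(X)))
  sig_tr <- numeric(M)
  if (control$sparse) s_tr <- matrix(0, M, P,
                                     dimnames = list(NULL, colnames(X)))
  if (re) {
    v_tr <- matrix(0L, M, Q, dimnames = list(NULL, colnames(Z)))
    l_tr <- matrix(0, M, Q, dimnames = list(NULL, colnames(Z)))
    coef_sum <- matrix(0, K, Q)
    coef_sq <- matrix(0, K, Q)
    if (keep_coef) coef1_tr <- matrix(0, M, K)
  }
  fit_sum <- numeric(n)

  f <- numeric(n)
  for (it in seq_len(n_iter)) {
    # steps 1-2: backfit trees on y minus the random-effects part
    if (re) {
      Gb <- b %*% t(Gamma)
      coefm <- sweep(Gb, 2, lambda, "*")
      eta <- rowSums(Z * coefm[ci, , drop = FALSE])
    } else eta <- numeric(n)
    if (use_trees) {
      .forest_sweep(fptr, ys - eta, sigma2)
      if (control$sparse) {
        par <- dirichlet_posterior(.forest_counts(fptr), control$alpha_dir)
        s_cur <- rdirichlet1(par)
        .forest_set_s(fptr, s_cur)
      }
      f <- .forest_fit(fptr)
    }
    r <- ys - f

    if (re) {
      # step 3: latent cluster effects (compiled conjugate MVN draw;
      # scalar fast path for the random-intercept-only model)
      LG <- lambda * Gamma               # Lambda %*% Gamma
      Zr <- rowsum(Z * r, ci)            # K x Q, ordered by cluster code
      if (Q == 1) {
        A1 <- lambda[1]^2 * nk_tab / sigma2 + 1
        b[, 1] <- rnorm(K, lambda[1] * Zr[, 1] / sigma2 / A1,
                        sqrt(1 / A1))
      } else {
        b <- .sample_b(Szz_mat, Zr, LG, sigma2)
      }

      # step 4: free entries of Gamma (active pairs only)
      if (npair > 0) {
        active <- lambda[pr[, 1]] > 0 & lambda[pr[, 2]] > 0
        if (any(active)) {
          pa <- pr[active, , drop = FALSE]
          U <- sweep(Z[, pa[, 1], drop = FALSE] *
                       b[ci, pa[, 2], drop = FALSE],
                     2, lambda[pa[, 1]], "*")
          r2 <- r - as.vector((Z * b[ci, , drop = FALSE]) %*% lambda)
          gp <- gamma_posterior(U, r2, sigma2, hyper$r0_scale,
                                g0[active])
          gvec[active] <- gp$mean + backsolve(gp$chol_prec,
                                              rnorm(nrow(pa)))
        }
        gvec[!(lambda[pr[, 1]] > 0 & lambda[pr[, 2]] > 0)] <- 0
        Gamma <- assemble_gamma(gvec, Q)
      }

      if (is.null(lambda_fixed)) {
        # step 5: inclusion probabilities
        pi_q <- rbeta(Q, cq + v, dq + 1 - v)

        # steps 6-8: atomic collapsed (v_q, lambda_q) block, sequential
        # in q with no interleaved updates
        Gb <- b %*% t(Gamma)
        Tm <- Z * Gb[ci, , drop = FALSE]
        eta <- as.vector(Tm %*% lambda)
        for (q in seq_len(Q)) {
          rq <- r - eta + lambda[q] * Tm[, q]
          upd <- inclusion_update(sum(Tm[, q]^2), sum(Tm[, q] * rq),
                                  sigma2, theta[q], s2[q], pi_q[q])
          v[q] <- as.integer(runif(1) < upd$p1)
          new_l <- if (v[q] == 0L) 0 else rtnorm_pos(upd$mean,
                                                     sqrt(upd$var))
          eta <- eta + (new_l - lambda[q]) * Tm[, q]
          lambda[q] <- new_l
        }
        # re-impose the identifiability constraint after the block;
        # entries tied to a reactivated lambda restart at gamma0 (= 0)
        if (npair > 0) {
          dead <- !(lambda[pr[, 1]] > 0 & lambda[pr[, 2]] > 0)
          if (any(dead & gvec != 0)) {
            gvec[dead] <- 0
            Gamma <- assemble_gamma(gvec, Q)
            Gb <- b %*% t(Gamma)
            Tm <- Z * Gb[ci, , drop = FALSE]
            eta <- as.vector(Tm %*% lambda)
          }
        }
      } else {
        Gb <- b %*% t(Gamma)
        Tm <- Z * Gb[ci, , drop = FALSE]
        eta <- as.vector(Tm %*% lambda)
      }
    }

    # step 9: residual variance
    resid <- r - eta
    if (is.null(sigma2_fixed)) {
      ssr <- sum(resid^2)
      sigma2 <- (nu * tau2 + ssr) / rchisq(1, nu + n)
      if (!is.finite(sigma2) || sigma2 <= 0)
        stop("sigma2 diverged at iteration ", it)
    }

    if (it >= keep_from) {
      m <- it - keep_from + 1
      if (use_trees) {
        counts[m, ] <- .forest_counts(fptr)
        mi <- .forest_mi(fptr)
        mi_sum[m, ] <- mi$sum
        mi_cnt[m, ] <- mi$cnt
        if (control$sparse) s_tr[m, ] <- s_cur
      }
      sig_tr[m] <- sigma2 * yr^2
      if (re) {
        v_tr[m, ] <- v
        l_tr[m, ] <- lambda * yr
        coefm <- sweep(b %*% t(Gamma), 2, lambda, "*") * yr
        coef_sum <- coef_sum + coefm
        coef_sq <- coef_sq + coefm^2
        if (keep_coef) coef1_tr[m, ] <- coefm[, 1]
      }
      fit_sum <- fit_sum + (f + 0.5) * yr + y0
    }
  }

  out <- list(
    counts = counts, mi_sum = mi_sum, mi_cnt = mi_cnt,
    v = if (re) v_tr, lambda = if (re) l_tr, sigma2 = sig_tr,
    s = if (control$sparse) s_tr,
    coef_mean = if (re) coef_sum / M,
    coef1 = if (re && keep_coef) coef1_tr,
    coef_sd = if (re) sqrt(pmax(coef_sq / M - (coef_sum / M)^2, 0)),
    fit_mean = fit_sum / M,
    x_type = data$x_type, x_group = data$x_group,
    z_group = data$z_group,
    z_names = if (re) colnames(data$Z),
    cluster_levels = if (re) levels(data$cluster),
    n_iter = n_iter, n_keep = n_keep, control = control, hyper = hyper,
    seed = seed, y_scale = c(min = y0, range = yr))
  class(out) <- "mixbart_trace"
  out
}

#' @export
print.mixbart_trace <- function(x, ...) {
  cat("mixbart_trace: ", x$n_keep, " retained draws (of ", x$n_iter,
      "), P = ", ncol(x$counts), sep = "")
  if (!is.null(x$v)) cat(", Q = ", ncol(x$v), sep = "")
  cat("\n  mean sigma2: ", signif(mean(x$sigma2), 4), sep = "")
  if (!is.null(x$v))
    cat(" | posterior inclusion: ",
        paste(signif(colMeans(x$v), 2), collapse = " "), sep = "")
  cat("\n")
  invisible(x)
}
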