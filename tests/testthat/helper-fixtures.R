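# small in-code fixtures shared across test files

# plain regression dataset (no multilevel structure)
make_plain_data <- function(n = 100, P = 5, f = function(X) 0,
                            sigma = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * P), n, P)
  y <- f(X) + rnorm(n, 0, sigma)
  hier_data(y, X)
}

# small clustered dataset with a random-intercept-plus-slope truth
make_cluster_data <- function(K = 12, nk = 8, Q_noise = 1,
                              lambda_true = c(1, 0.8), sigma = 0.5,
                              seed = 1, P = 3) {
  set.seed(seed)
  n <- K * nk
  ci <- factor(rep(seq_len(K), each = nk))
  X <- matrix(rnorm(n * P), n, P)
  z1 <- rnorm(n)
  Z <- cbind("(Intercept)" = 1, z_1 = z1)
  if (Q_noise > 0) {
    zn <- matrix(rnorm(n * Q_noise), n, Q_noise,
                 dimnames = list(NULL, paste0("z_noise_", seq_len(Q_noise))))
    Z <- cbind(Z, zn)
  }
  b <- matrix(rnorm(K * 2), K, 2)
  re <- lambda_true[1] * b[as.integer(ci), 1] +
    lambda_true[2] * z1 * b[as.integer(ci), 2]
  y <- re + rnorm(n, 0, sigma)
  hier_data(y, X, cluster = ci, Z = Z)
}

# hand-built trace for importance-score oracles
make_trace <- function(counts, mi_sum = NULL, mi_cnt = NULL, v = NULL,
                       x_type = NULL, z_names = NULL, z_group = NULL) {
  counts <- as.matrix(counts)
  P <- ncol(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("x_", seq_len(P))
  if (is.null(mi_sum)) mi_sum <- counts * 0
  if (is.null(mi_cnt)) mi_cnt <- counts * 0L
  structure(list(counts = counts,
                 mi_sum = as.matrix(mi_sum), mi_cnt = as.matrix(mi_cnt),
                 v = v, x_type = x_type %||%
                   rep("continuous", P),
                 z_names = z_names, z_group = z_group,
                 n_keep = nrow(counts)),
            class = "mixbart_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full leaf marginal log-likelihood (leaf value integrated out) -- an
# independent oracle for the tree-move likelihood ratios
leaf_marg_loglik <- function(r, sigma2, sigma_mu2) {
  n <- length(r)
  S <- sum(r)
  -n / 2 * log(2 * pi * sigma2) - sum(r^2) / (2 * sigma2) +
    0.5 * log(sigma2 / (sigma2 + n * sigma_mu2)) +
    sigma_mu2 * S^2 / (2 * sigma2 * (sigma2 + n * sigma_mu2))
}

# truncated-normal density on (0, Inf)
dtnorm_pos <- function(x, mean, sd) {
  ifelse(x > 0, dnorm(x, mean, sd) / pnorm(mean / sd), 0)
}
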