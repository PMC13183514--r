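#' Configure a simulation scenario
#'
#' Describes one cell of the 2 x 2 x 2 factorial simulation design:
#' cluster structure (balanced vs. unbalanced), fixed-effects surface
#' (nonlinear vs. linear), and cluster-level covariate structure
#' (within-cluster varying vs. within-cluster constant Z).
#'
#' Defaults follow the study design: the balanced design has K = 50
#' clusters of 100 individuals; the unbalanced design has K = 35
#' clusters whose sizes are drawn uniformly from \{10, ..., 30\}. Ten
#' individual-level covariates are generated (x_1, x_2 Bernoulli(0.5),
#' the rest standard normal), three informative cluster-level predictors
#' (z_1, z_2 Gaussian and z_3 ordinal on \{0,...,3\}, dummy-encoded for
#' fitting) plus \code{n_noise_z} standard-normal noise predictors, a
#' cross-level correlation rho = 0.2 between x_5 and z_1 and between
#' x_6 and z_2, and unit residual standard deviation.
#'
#' @param design \code{"balanced"} or \code{"unbalanced"}.
#' @param fixed_surface \code{"nonlinear"} (includes a quadratic and an
#'   interaction term) or \code{"linear"}.
#' @param z_structure \code{"variant"} (Z varies within clusters) or
#'   \code{"constant"} (Z constant within clusters).
#' @param K number of clusters; default 50 (balanced) or 35 (unbalanced).
#' @param cluster_size a single size for the balanced design (default
#'   100) or an integer range \code{c(lo, hi)} for the unbalanced design
#'   (default \code{c(10, 30)}).
#' @param P number of individual-level covariates (default 10).
#' @param n_informative_z number of informative cluster-level predictors
#'   (fixed at 3 by the generative design).
#' @param n_noise_z number of noise cluster-level predictors (default 3).
#' @param rho cross-level correlation between (x_5, z_1) and (x_6, z_2);
#'   default 0.2, must lie in [0, 1).
#' @param sigma_eps residual standard deviation (default 1).
#' @param z3_rule ordinal z_3 support rule: \code{"truncated4"} (sum of
#'   four Bernoulli(0.5), values above 3 mapped to 3 so the printed
#'   support \{0,...,3\} is preserved) or \code{"sum3"} (sum of three).
#' @param seed optional integer seed stored with the configuration.
#'
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(design = c("balanced", "unbalanced"),
                            fixed_surface = c("nonlinear", "linear"),
                            z_structure = c("variant", "constant"),
                            K = NULL, cluster_size = NULL, P = 10,
                            n_informative_z = 3, n_noise_z = 3,
                            rho = 0.2, sigma_eps = 1,
                            z3_rule = c("truncated4", "sum3"),
                            seed = NULL) {
  design <- match.arg(design)
  fixed_surface <- match.arg(fixed_surface)
  z_structure <- match.arg(z_structure)
  z3_rule <- match.arg(z3_rule)
  if (is.null(K)) K <- if (design == "balanced") 50L else 35L
  if (is.null(cluster_size))
    cluster_size <- if (design == "balanced") 100L else c(10L, 30L)
  if (K < 2) stop("K must be at least 2")
  p_min <- if (fixed_surface == "nonlinear") 8L else 7L
  if (P < p_min)
    stop("the ", fixed_surface, " surface references covariate indices up to ",
         p_min, "; increase P")
  if (n_informative_z != 3)
    stop("the generative design fixes three informative cluster-level predictors")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (sigma_eps <= 0) stop("sigma_eps must be positive")
  if (design == "unbalanced" &&
      (length(cluster_size) != 2 || cluster_size[1] > cluster_size[2]))
    stop("unbalanced designs need cluster_size = c(lo, hi)")
  cfg <- list(design = design, fixed_surface = fixed_surface,
              z_structure = z_structure, K = as.integer(K),
              cluster_size = as.integer(cluster_size), P = as.integer(P),
              n_informative_z = 3L, n_noise_z = as.integer(n_noise_z),
              rho = rho, sigma_eps = sigma_eps, z3_rule = z3_rule,
              seed = seed)
  q_cand <- 3L + cfg$n_noise_z
  if (z_structure == "constant" && K < q_cand + 1L)
    warning("K is small relative to the ", q_cand,
            " candidate cluster-level covariates; selection will be unstable")
  class(cfg) <- "scenario_config"
  cfg
}

#' Evaluate a fixed-effects surface
#'
#' The nonlinear surface is
#' \deqn{f(x) = 6 x_1 + 3 x_5 - x_7 + x_7^2 + x_6 + x_6 x_8,}
#' so covariates \{1, 5, 6, 7, 8\} carry signal; the linear surface is
#' \deqn{f(x) = 6 x_1 + 3 x_5 - x_7 + x_6,}
#' with signal on \{1, 5, 6, 7\}.
#'
#' @param X a covariate vector or an n x P matrix.
#' @param surface \code{"nonlinear"} or \code{"linear"}.
#' @return A scalar (vector input) or a vector of surface values.
#' @export
fixed_surface <- function(X, surface = c("nonlinear", "linear")) {
  surface <- match.arg(surface)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  need <- if (surface == "nonlinear") 8 else 7
  if (ncol(X) < need)
    stop("the ", surface, " surface references covariate index ", need,
         " but X has only ", ncol(X), " columns")
  out <- if (surface == "nonlinear") {
    6 * X[, 1] + 3 * X[, 5] - X[, 7] + X[, 7]^2 + X[, 6] + X[, 6] * X[, 8]
  } else {
    6 * X[, 1] + 3 * X[, 5] - X[, 7] + X[, 6]
  }
  unname(out)
}

#' Indices of informative individual-level covariates for a surface
#' @param surface \code{"nonlinear"} or \code{"linear"}.
#' @return Integer vector of informative X indices.
#' @export
informative_x <- function(surface = c("nonlinear", "linear")) {
  surface <- match.arg(surface)
  if (surface == "nonlinear") c(1L, 5L, 6L, 7L, 8L) else c(1L, 5L, 6L, 7L)
}

#' Conditional slope covariance of the constant-Z design
#'
#' The fixed 3 x 3 covariance of the informative random slopes around
#' their conditional mean in the cluster-constant-Z setting: 0.01 on
#' the diagonal and -0.005 off it. Its rows sum to zero, so it is
#' positive semidefinite with one zero eigenvalue — the sum of the
#' three slope deviations is exactly zero.
#'
#' @return A 3 x 3 numeric matrix.
#' @export
sigma2_tilde <- function() {
  matrix(c(0.01, -0.005, -0.005,
           -0.005, 0.01, -0.005,
           -0.005, -0.005, 0.01), 3, 3)
}

# draw from MVN(0, S) for a possibly singular PSD S, via eigendecomposition
# with negative eigenvalues clipped at zero (keeps the matrix exactly as
# specified, no jitter)
rmvn_psd <- function(m, S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(vals), nrow = length(vals))
  matrix(rnorm(m * length(vals)), m) %*% t(A)
}

draw_z3 <- function(m, rule) {
  if (rule == "truncated4") pmin(rbinom(m, 4, 0.5), 3) else rbinom(m, 3, 0.5)
}

#' Generate a synthetic hierarchical dataset
#'
#' Simulates one dataset from the configured scenario:
#' \code{y = f(X) + Z beta_k + eps}. The random intercept is drawn
#' independently from N(0, 1). Under variant Z the informative slopes
#' (beta_k1, beta_k2, beta_k3) are MVN(0, Sigma1) with Sigma1 drawn once
#' per dataset from an inverse-Wishart with 6 degrees of freedom and
#' identity scale; under constant Z they are drawn conditionally on the
#' cluster's (z_1, z_2, z_3) with mean (2.5 z_1, 2.5 z_2, 2.0 z_3) and
#' the fixed near-singular covariance \code{sigma2_tilde()}. Noise
#' cluster-level predictors have exactly zero coefficients. The ordinal
#' z_3 enters the generative model through its integer value; the fitted
#' design matrix carries its dummy encoding (levels 1-3, reference 0).
#'
#' The latent components (fixed surface, random-effect contribution,
#' residual) are retained for \code{\link{variance_decomposition}}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param seed optional integer seed; overrides \code{config$seed}.
#' @return A list of class \code{scenario_data} with elements
#'   \code{data} (a \code{\link{hier_data}}), \code{truth}
#'   (\code{informative_x} indices and \code{informative_z} group names),
#'   \code{components} (latent f, re, eps), \code{beta} (the K x 4
#'   matrix of true intercept and slopes), and \code{config}.
#' @export
generate_scenario <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- config$K
  nk <- if (config$design == "balanced") {
    rep(config$cluster_size[1], K)
  } else {
    sample(seq(config$cluster_size[1], config$cluster_size[2]), K,
           replace = TRUE)
  }
  n <- sum(nk)
  ci <- rep(seq_len(K), nk)
  P <- config$P
  nz <- config$n_noise_z
  rho <- config$rho

  constant <- config$z_structure == "constant"
  if (constant) {
    zk1 <- rnorm(K); zk2 <- rnorm(K); zk3 <- draw_z3(K, config$z3_rule)
    z1 <- zk1[ci]; z2 <- zk2[ci]; z3 <- zk3[ci]
  } else {
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- draw_z3(n, config$z3_rule)
  }

  # individual-level covariates; x_5 and x_6 receive cross-level
  # correlation rho with z_1 and z_2 through a linear blend that keeps
  # their marginals standard normal (z_3 and binaries untouched)
  X <- matrix(rnorm(n * P), n, P)
  X[, 1] <- rbinom(n, 1, 0.5)
  X[, 2] <- rbinom(n, 1, 0.5)
  if (P >= 5) X[, 5] <- rho * z1 + sqrt(1 - rho^2) * X[, 5]
  if (P >= 6) X[, 6] <- rho * z2 + sqrt(1 - rho^2) * X[, 6]
  colnames(X) <- paste0("x_", seq_len(P))

  # random coefficients: independent N(0,1) intercept; informative slopes
  beta0 <- rnorm(K)
  if (constant) {
    mu <- cbind(2.5 * zk1, 2.5 * zk2, 2.0 * zk3)
    slopes <- mu + rmvn_psd(K, sigma2_tilde())
    Sigma1 <- NULL
  } else {
    W <- rWishart(1, df = 6, Sigma = diag(3))[, , 1]
    Sigma1 <- solve(W)
    slopes <- rmvn_psd(K, Sigma1)
  }

  f <- fixed_surface(X, config$fixed_surface)
  re <- beta0[ci] + z1 * slopes[ci, 1] + z2 * slopes[ci, 2] +
    z3 * slopes[ci, 3]
  eps <- rnorm(n, 0, config$sigma_eps)
  y <- f + re + eps

  # noise cluster-level predictors are drawn last so that varying
  # their number leaves every other component of the dataset
  # bit-identical under a shared seed
  znoise <- if (constant) {
    matrix(rnorm(K * nz), K, nz)[ci, , drop = FALSE]
  } else {
    matrix(rnorm(n * nz), n, nz)
  }

  # fitted design: intercept, z_1, z_2, dummy-encoded z_3, noise columns
  zd <- sapply(1:3, function(l) as.numeric(z3 == l))
  colnames(zd) <- paste0("z_3.", 1:3)
  Z <- cbind("(Intercept)" = 1, z_1 = z1, z_2 = z2, zd)
  if (nz > 0) {
    colnames(znoise) <- paste0("z_noise_", seq_len(nz))
    Z <- cbind(Z, znoise)
  }
  z_group <- c(list(z_1 = "z_1", z_2 = "z_2", z_3 = colnames(zd)),
               if (nz > 0) as.list(setNames(colnames(znoise),
                                            colnames(znoise))))

  dat <- hier_data(y, X, cluster = factor(ci, levels = seq_len(K)),
                   Z = Z,
                   x_type = c("binary", "binary",
                              rep("continuous", P - 2)),
                   z_group = z_group)
  structure(list(
    data = dat,
    truth = list(informative_x = informative_x(config$fixed_surface),
                 informative_z = c("z_1", "z_2", "z_3")),
    components = list(f = f, re = re, eps = eps),
    beta = cbind(intercept = beta0, slopes),
    Sigma1 = Sigma1,
    config = config), class = "scenario_data")
}

#' @export
print.scenario_data <- function(x, ...) {
  cfg <- x$config
  cat("scenario_data: ", cfg$design, "-", cfg$fixed_surface, "-",
      cfg$z_structure, ", K=", cfg$K, ", n=", length(x$data$y), "\n",
      sep = "")
  invisible(x)
}

#' Realized variance share of the random effects
#'
#' Proportion of the realized outcome variance attributable to the
#' random-effect contribution, \code{var(Z beta) / var(y)}, computed on
#' the generated sample. The study design targets roughly 10--15\%.
#'
#' @param sim a \code{scenario_data} object from
#'   \code{\link{generate_scenario}}.
#' @return A single proportion.
#' @export
variance_decomposition <- function(sim) {
  stopifnot(inherits(sim, "scenario_data"))
  y <- with(sim$components, f + re + eps)
  stats::var(sim$components$re) / stats::var(y)
}
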