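#' Control settings for the sum-of-trees component
#'
#' The canonical regularizing tree prior is used: a node at depth d
#' splits with probability \code{a (1 + d)^(-b)}, leaf values are
#' N(0, sigma_mu^2) with sigma_mu chosen so that H leaf draws span the
#' internally standardized outcome range at k prior standard deviations.
#'
#' @param n_trees ensemble size H (default 20, chosen to keep the
#'   ensemble small enough that predictors compete for splits); 0
#'   disables the tree component entirely (diagnostic use).
#' @param a,b tree-depth prior parameters, defaults 0.95 and 2.
#' @param k leaf-shrinkage multiplier (default 2).
#' @param sparse logical; use the sparsity-inducing Dirichlet prior on
#'   the splitting probabilities instead of the uniform rule.
#' @param alpha_dir Dirichlet concentration (total mass alpha spread as
#'   alpha/P per covariate); default 1.
#' @return A \code{bart_control} list.
#' @export
bart_control <- function(n_trees = 20, a = 0.95, b = 2, k = 2,
                         sparse = FALSE, alpha_dir = 1) {
  stopifnot(n_trees >= 0, a > 0, a < 1, b >= 0, k > 0, alpha_dir > 0)
  structure(list(n_trees = as.integer(n_trees), a = a, b = b, k = k,
                 sparse = sparse, alpha_dir = alpha_dir),
            class = "bart_control")
}

#' Log prior probability of a tree structure
#'
#' Under the regularizing prior, an internal node at depth d contributes
#' \code{log(a (1+d)^(-b))} and a leaf contributes
#' \code{log(1 - a (1+d)^(-b))}; the tree log prior is the sum over all
#' nodes. Splitting-rule probabilities are not included (they cancel
#' against the proposal in the structural Metropolis-Hastings move).
#'
#' @param depths integer vector of node depths (root = 0).
#' @param is_leaf logical vector, same length, marking leaves.
#' @param a,b prior parameters.
#' @return The log prior probability.
#' @export
tree_log_prior <- function(depths, is_leaf, a = 0.95, b = 2) {
  stopifnot(length(depths) == length(is_leaf), a > 0, a < 1, b >= 0)
  p_split <- a * (1 + depths)^(-b)
  sum(ifelse(is_leaf, log(1 - p_split), log(p_split)))
}

#' Posterior parameters of the Dirichlet splitting prior
#'
#' With prior Dirichlet(alpha/P, ..., alpha/P) and current split counts
#' u, the full conditional of the splitting probabilities is
#' Dirichlet(alpha/P + u_1, ..., alpha/P + u_P).
#'
#' @param counts integer vector of current per-covariate split counts.
#' @param alpha_dir Dirichlet concentration.
#' @return The posterior Dirichlet parameter vector.
#' @export
dirichlet_posterior <- function(counts, alpha_dir = 1) {
  stopifnot(all(counts >= 0), alpha_dir > 0)
  alpha_dir / length(counts) + counts
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(par) {
  g <- rgamma(length(par), shape = par, rate = 1)
  g / sum(g)
}

#' Create a standalone sum-of-trees sampler state
#'
#' Low-level access to the ensemble used inside the Gibbs sampler;
#' primarily for diagnostics and testing. The returned handle holds the
#' tree state; \code{\link{backfit_sweep}} advances it by one Bayesian
#' backfitting sweep (one BIRTH/DEATH Metropolis-Hastings structural
#' move plus a conjugate leaf redraw per tree).
#'
#' @param X covariate matrix.
#' @param x_type covariate type flags (\code{"continuous"}/\code{"binary"}).
#' @param control a \code{\link{bart_control}}.
#' @param sigma_mu leaf prior standard deviation; default
#'   \code{0.5 / (k * sqrt(n_trees))}, matching an outcome standardized
#'   to [-0.5, 0.5].
#' @return A \code{bart_forest} handle.
#' @export
bart_forest <- function(X, x_type = NULL, control = bart_control(),
                        sigma_mu = NULL) {
  X <- as.matrix(X)
  if (is.null(x_type))
    x_type <- ifelse(apply(X, 2, function(v) all(v %in% c(0, 1))),
                     "binary", "continuous")
  if (is.null(sigma_mu))
    sigma_mu <- 0.5 / (control$k * sqrt(control$n_trees))
  P <- ncol(X)
  ptr <- .forest_create(X, as.integer(x_type == "binary"),
                        control$n_trees, control$a, control$b,
                        sigma_mu, rep(1 / P, P))
  structure(list(ptr = ptr, P = P, n = nrow(X), control = control,
                 x_type = x_type, sigma_mu = sigma_mu,
                 s = rep(1 / P, P)),
            class = "bart_forest")
}

#' Advance a sum-of-trees state by one backfitting sweep
#'
#' @param forest a \code{\link{bart_forest}} handle.
#' @param partial_response the outcome minus all non-tree model
#'   components (already on the scale the forest was built for).
#' @param sigma2 current residual variance.
#' @return The handle, invisibly; the underlying state is advanced in
#'   place. Per-sweep BIRTH acceptance records are retrievable with
#'   \code{\link{forest_mi_accumulators}}.
#' @export
backfit_sweep <- function(forest, partial_response, sigma2) {
  stopifnot(inherits(forest, "bart_forest"),
            length(partial_response) == forest$n, sigma2 > 0)
  if (any(!is.finite(partial_response)))
    stop("non-finite partial response")
  .forest_sweep(forest$ptr, partial_response, sigma2)
  invisible(forest)
}

#' Current fit vector of a forest
#' @param forest a \code{\link{bart_forest}} handle.
#' @param recompute if \code{TRUE}, re-evaluate every tree from its
#'   structure instead of returning the maintained running fit.
#' @return Numeric vector of length n.
#' @export
forest_fit <- function(forest, recompute = FALSE) {
  if (recompute) .forest_fit_recompute(forest$ptr)
  else .forest_fit(forest$ptr)
}

#' Per-covariate split counts of the current forest state
#' @param forest a \code{\link{bart_forest}} handle.
#' @return Integer vector of length P.
#' @export
forest_split_counts <- function(forest) .forest_counts(forest$ptr)

#' BIRTH acceptance accumulators from the last sweep
#'
#' For every BIRTH proposal during the most recent sweep the proposed
#' split covariate and the Metropolis-Hastings acceptance probability
#' are recorded; DEATH proposals and proposals with no legal cut value
#' contribute nothing. These accumulators feed the MI importance score.
#'
#' @param forest a \code{\link{bart_forest}} handle.
#' @return List with per-covariate \code{sum} of acceptance
#'   probabilities and proposal \code{cnt}.
#' @export
forest_mi_accumulators <- function(forest) .forest_mi(forest$ptr)

#' Redraw the Dirichlet splitting probabilities from their posterior
#'
#' @param forest a \code{\link{bart_forest}} handle built with
#'   \code{sparse = TRUE} control (a warning and no-op otherwise).
#' @return The new probability vector, invisibly stored in the state.
#' @export
update_split_probabilities <- function(forest) {
  if (!forest$control$sparse) {
    warning("forest is in uniform splitting mode; no-op")
    return(invisible(forest))
  }
  par <- dirichlet_posterior(forest_split_counts(forest),
                             forest$control$alpha_dir)
  s <- rdirichlet1(par)
  .forest_set_s(forest$ptr, s)
  forest$s <- s
  invisible(forest)
}

#' Predict from the current forest state
#' @param forest a \code{\link{bart_forest}} handle.
#' @param Xnew matrix of new covariate rows.
#' @return Numeric vector of predictions (on the forest's fitting scale).
#' @export
forest_predict <- function(forest, Xnew) {
  .forest_predict(forest$ptr, as.matrix(Xnew))
}
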