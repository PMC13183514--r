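#' Hierarchical dataset container
#'
#' Bundles an outcome vector, individual-level covariates \code{X},
#' an optional random-effects design \code{Z} (whose first column must be
#' the constant 1 for the random intercept), and the cluster assignment.
#' Covariates are tracked with a type flag (\code{"continuous"} or
#' \code{"binary"}) and a group map so that dummy columns of one
#' categorical covariate can be merged when importance scores are
#' aggregated.
#'
#' @param y numeric outcome vector, one entry per individual.
#' @param X numeric matrix of individual-level covariates (n x P).
#' @param cluster factor (or coercible) of cluster labels, length n.
#'   May be \code{NULL} for plain regression data (no multilevel
#'   structure), e.g. the cluster-level table of the two-step procedure.
#' @param Z optional numeric matrix of random-effect covariates
#'   (n x Q); its first column must be identically 1.
#' @param x_type character vector of length P, entries
#'   \code{"continuous"} or \code{"binary"}. Defaults to a guess: columns
#'   with values in \{0, 1\} are flagged binary.
#' @param x_group named list mapping covariate names to the X column
#'   names that encode them (several for a dummy-expanded categorical).
#'   Defaults to one group per column.
#' @param z_group named list mapping cluster-level covariate names to
#'   non-intercept Z column names. Defaults to one group per column.
#'
#' @return An object of class \code{hier_data}.
#' @export
hier_data <- function(y, X, cluster = NULL, Z = NULL, x_type = NULL,
                      x_group = NULL, z_group = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (anyNA(y) || anyNA(X)) stop("missing values are not supported")
  if (is.null(colnames(X))) colnames(X) <- paste0("x_", seq_len(ncol(X)))
  if (is.null(x_type)) {
    x_type <- ifelse(apply(X, 2, function(v) all(v %in% c(0, 1))),
                     "binary", "continuous")
  }
  x_type <- rep_len(x_type, ncol(X))
  if (!all(x_type %in% c("continuous", "binary")))
    stop("x_type entries must be 'continuous' or 'binary'")
  if (is.null(x_group))
    x_group <- as.list(setNames(colnames(X), colnames(X)))
  if (anyDuplicated(unlist(x_group)))
    stop("x_group entries overlap")

  if (!is.null(cluster)) {
    cluster <- droplevels(as.factor(cluster))
    if (length(cluster) != n) stop("cluster must have length n")
  }

  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("nrow(Z) must equal length(y)")
    if (!all(Z[, 1] == 1))
      stop("the first column of Z must be identically 1 (random intercept)")
    if (is.null(colnames(Z)))
      colnames(Z) <- c("(Intercept)",
                       if (ncol(Z) > 1) paste0("z_", seq_len(ncol(Z) - 1)))
    if (is.null(cluster)) stop("Z requires a cluster assignment")
    if (is.null(z_group)) {
      nm <- colnames(Z)[-1]
      z_group <- as.list(setNames(nm, nm))
    }
    if (anyDuplicated(unlist(z_group))) stop("z_group entries overlap")
    if (!all(unlist(z_group) %in% colnames(Z)[-1]))
      stop("z_group refers to unknown Z columns")
  }

  structure(list(y = y, X = X, Z = Z, cluster = cluster,
                 x_type = x_type, x_group = x_group, z_group = z_group),
            class = "hier_data")
}

#' @export
print.hier_data <- function(x, ...) {
  n <- length(x$y)
  cat("hier_data: ", n, " individuals", sep = "")
  if (!is.null(x$cluster))
    cat(", ", nlevels(x$cluster), " clusters", sep = "")
  cat("\n  X: ", ncol(x$X), " columns (",
      sum(x$x_type == "binary"), " binary, ",
      sum(x$x_type == "continuous"), " continuous)\n", sep = "")
  if (!is.null(x$Z))
    cat("  Z: intercept + ", ncol(x$Z) - 1, " columns in ",
        length(x$z_group), " covariate groups\n", sep = "")
  invisible(x)
}

#' Candidate covariate names at each level
#'
#' @param data a \code{hier_data} object.
#' @return Character vector of group names.
#' @export
candidates_x <- function(data) names(data$x_group)

#' @rdname candidates_x
#' @export
candidates_z <- function(data) names(data$z_group)

# cluster index (integer codes) and per-cluster row lists
cluster_rows <- function(data) {
  split(seq_along(data$y), data$cluster)
}

#' Verify that declared cluster-level covariates are constant in-cluster
#'
#' @param data a \code{hier_data} object with a \code{Z} design.
#' @param tol absolute tolerance for equality.
#' @return Invisibly \code{TRUE}; stops with the name of the first
#'   offending cluster otherwise.
#' @export
check_z_constant <- function(data, tol = 1e-8) {
  stopifnot(inherits(data, "hier_data"), !is.null(data$Z))
  rows <- cluster_rows(data)
  for (k in names(rows)) {
    zk <- data$Z[rows[[k]], -1, drop = FALSE]
    if (nrow(zk) > 1 && max(abs(sweep(zk, 2, zk[1, ]))) > tol)
      stop("Z varies within cluster '", k, "' but was declared constant")
  }
  invisible(TRUE)
}
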