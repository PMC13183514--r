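#' Variable inclusion proportions (VIP)
#'
#' Per retained draw, each covariate's share of all splitting rules in
#' the forest; averaged over draws. Draws in which the forest contains
#' no split at all contribute the uniform share 1/P (the raw ratio is
#' 0/0 there).
#'
#' @param trace a \code{mixbart_trace}.
#' @return Named numeric vector over covariates; sums to 1.
#' @export
compute_vip <- function(trace) {
  cts <- trace$counts
  tot <- rowSums(cts)
  ratio <- cts / ifelse(tot > 0, tot, 1)
  ratio[tot == 0, ] <- 1 / ncol(cts)
  colMeans(ratio)
}

#' Within-type variable inclusion proportions
#'
#' As \code{\link{compute_vip}} but each covariate's split count is
#' normalized by the split total of its own type (continuous or binary)
#' in that draw, which prevents binary covariates from being
#' overshadowed by continuous ones. Draws where a type has no splits
#' contribute 0 for that type's covariates.
#'
#' @param trace a \code{mixbart_trace}.
#' @param x_type covariate type flags; defaults to those in the trace.
#' @return Named numeric vector (nonnegative; each type block averages
#'   to at most 1 per draw).
#' @export
compute_vip_type <- function(trace, x_type = trace$x_type) {
  cts <- trace$counts
  if (is.null(x_type) || length(x_type) != ncol(cts))
    stop("covariate type flags are missing")
  out <- matrix(0, nrow(cts), ncol(cts))
  for (tp in unique(x_type)) {
    cols <- x_type == tp
    tot <- rowSums(cts[, cols, drop = FALSE])
    out[, cols] <- cts[, cols, drop = FALSE] / ifelse(tot > 0, tot, Inf)
  }
  colnames(out) <- colnames(cts)
  colMeans(out)
}

#' Metropolis Importance (MI)
#'
#' Per retained draw, each covariate's mean BIRTH acceptance probability
#' over the BIRTH proposals naming it; the per-draw vector is normalized
#' across covariates and averaged over draws. Covariates never proposed
#' in a draw contribute 0 to that draw; draws with no BIRTH proposal at
#' all contribute the uniform 1/P.
#'
#' @param trace a \code{mixbart_trace}.
#' @return Named numeric vector; sums to 1.
#' @export
compute_mi <- function(trace) {
  ratio <- trace$mi_sum / ifelse(trace$mi_cnt > 0, trace$mi_cnt, 1)
  tot <- rowSums(ratio)
  norm <- ratio / ifelse(tot > 0, tot, 1)
  norm[tot == 0, ] <- 1 / ncol(ratio)
  colMeans(norm)
}

#' Posterior mean splitting probabilities (sparse Dirichlet mode)
#'
#' @param trace a \code{mixbart_trace} fitted with \code{sparse = TRUE}.
#' @return Named numeric vector; sums to 1.
#' @export
compute_dirichlet_prob <- function(trace) {
  if (is.null(trace$s))
    stop("trace was not fitted in sparse Dirichlet mode")
  colMeans(trace$s)
}

# bitmask string ("0"/"1" per group, in group order) of one draw's
# group-level inclusion pattern
draw_masks <- function(v, z_names, z_group) {
  sel_cols <- lapply(z_group, function(cols) match(cols, z_names))
  inc <- vapply(sel_cols, function(ix)
    rowSums(v[, ix, drop = FALSE]) > 0, logical(nrow(v)))
  inc <- matrix(inc, nrow = nrow(v))
  apply(inc, 1, function(r) paste(as.integer(r), collapse = ""))
}

#' Lambda Positivity Scores over random-effects submodels
#'
#' Each retained draw's inclusion pattern over the selectable
#' cluster-level covariates (intercept excluded; dummy columns of one
#' categorical covariate merged — a covariate is active in a draw if any
#' of its columns has nonzero lambda) defines one submodel; the LPS of a
#' submodel is the fraction of draws selecting it.
#'
#' @param trace a \code{mixbart_trace} with a random-effects component.
#' @return Named numeric vector of submodel frequencies; names are
#'   inclusion bitmasks over the covariate groups (attribute
#'   \code{"groups"}), values sum to 1.
#' @export
compute_lps <- function(trace) {
  if (is.null(trace$v)) stop("trace has no random-effects component")
  masks <- draw_masks(trace$v, trace$z_names, trace$z_group)
  tab <- table(masks) / nrow(trace$v)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  attr(out, "groups") <- names(trace$z_group)
  out
}

mask_to_groups <- function(mask, groups) {
  groups[strsplit(mask, "")[[1]] == "1"]
}

#' Merge importance scores of dummy-encoded categoricals
#'
#' Scores of all columns encoding one covariate are summed, so each
#' original covariate carries one score and the total is conserved.
#'
#' @param scores named numeric vector of per-column scores.
#' @param groups named list mapping covariate names to column names.
#' @return Named numeric vector, one entry per covariate group.
#' @export
aggregate_categorical <- function(scores, groups) {
  cols <- unlist(groups)
  if (anyDuplicated(cols)) stop("groups overlap")
  vapply(groups, function(g) sum(scores[g]), numeric(1))
}

#' Elbow cutoff in a ranked probability sequence
#'
#' Returns the number of leading entries to retain: the position just
#' before the largest drop between consecutive entries of the
#' descending sequence. Ties are broken toward the smaller selected
#' set; a constant sequence selects nothing.
#'
#' @param sorted_probs numeric vector sorted in descending order,
#'   length at least 2.
#' @return Integer count of selected entries.
#' @export
elbow_cutoff <- function(sorted_probs) {
  stopifnot(length(sorted_probs) >= 2)
  if (any(diff(sorted_probs) > 1e-12))
    stop("sorted_probs must be sorted in descending order")
  drops <- -diff(sorted_probs)
  if (max(drops) <= 0) return(0L)
  which.max(drops)
}

#' Permute a hierarchical dataset to form a selection null
#'
#' Variant mode (Z varies within clusters; joint independence null
#' Y independent of (X, Z)): within each cluster the rows of the
#' non-intercept Z columns are permuted jointly, then the outcome is
#' permuted within the cluster. Constant mode (Z constant within
#' clusters; null Y independent of X given Z): only the outcome is
#' permuted within clusters. X and cluster membership are never
#' touched. Singleton clusters are identity-permuted; their count is
#' attached as attribute \code{"singletons"}.
#'
#' @param data a \code{\link{hier_data}}.
#' @param z_mode \code{"variant"} or \code{"constant"}.
#' @return A permuted \code{hier_data}.
#' @export
permute_dataset <- function(data, z_mode = c("variant", "constant")) {
  z_mode <- match.arg(z_mode)
  stopifnot(inherits(data, "hier_data"), !is.null(data$cluster))
  out <- data
  singletons <- 0L
  for (rows in cluster_rows(data)) {
    m <- length(rows)
    if (m == 1) { singletons <- singletons + 1L; next }
    if (z_mode == "variant" && !is.null(data$Z)) {
      p1 <- sample.int(m)
      out$Z[rows, -1] <- data$Z[rows[p1], -1]
    }
    p2 <- sample.int(m)
    out$y[rows] <- data$y[rows[p2]]
  }
  attr(out, "singletons") <- singletons
  out
}

#' Selection procedure configuration
#'
#' @param L number of permutation fits for the null distributions
#'   (default 100).
#' @param L_rep number of repeat chains on the observed data (default
#'   10); VIP, within-type VIP and LPS are averaged across chains, MI is
#'   aggregated by the median.
#' @param alpha significance level of the permutation rule (default
#'   0.05).
#' @param criterion importance statistic used for individual-level
#'   selection: \code{"mi"}, \code{"vip"} or \code{"vip_type"}.
#' @param z_mode permutation scheme, \code{"variant"} or
#'   \code{"constant"}; see \code{\link{permute_dataset}}.
#' @return A \code{selection_config} list.
#' @export
selection_config <- function(L = 100, L_rep = 10, alpha = 0.05,
                             criterion = c("mi", "vip", "vip_type"),
                             z_mode = c("variant", "constant")) {
  stopifnot(L >= 1, L_rep >= 1, alpha > 0, alpha <= 0.5)
  structure(list(L = as.integer(L), L_rep = as.integer(L_rep),
                 alpha = alpha, criterion = match.arg(criterion),
                 z_mode = match.arg(z_mode)),
            class = "selection_config")
}

# conservative empirical (1 - alpha) quantile: the ceiling((1-alpha) L)
# order statistic
null_quantile <- function(x, alpha) {
  s <- sort(x)
  s[min(length(s), max(1L, ceiling((1 - alpha) * length(s))))]
}

trace_scores <- function(trace) {
  list(vip = compute_vip(trace),
       vip_type = compute_vip_type(trace),
       mi = compute_mi(trace),
       lps = if (!is.null(trace$v)) compute_lps(trace))
}

# average a list of sparse LPS maps into one named vector over the
# union of observed masks
average_lps <- function(maps) {
  masks <- unique(unlist(lapply(maps, names)))
  out <- setNames(numeric(length(masks)), masks)
  for (m in maps) out[names(m)] <- out[names(m)] + m
  out / length(maps)
}

#' Permutation-calibrated multilevel variable selection
#'
#' Runs \code{L_rep} chains on the observed data (dispersed through
#' their seeds) and one chain on each of \code{L} within-cluster
#' permuted datasets. An individual-level covariate is selected when its
#' observed (aggregated, dummy-merged) importance score exceeds the
#' conservative empirical (1 - alpha) quantile of its permutation null.
#' A random-effects submodel is a candidate when its observed LPS
#' exceeds both its per-submodel null quantile and 1/M; among
#' candidates the one with the largest observed LPS is retained.
#'
#' @param data a \code{\link{hier_data}}.
#' @param selection a \code{\link{selection_config}}.
#' @param n_iter,n_keep chain lengths per fit.
#' @param control,hyper model settings passed to
#'   \code{\link{unified_fit}}.
#' @param seed master seed; all chain and permutation seeds derive from
#'   it, making the decision reproducible.
#' @param select_z run the random-effects (LPS) selection; set
#'   \code{FALSE} for fixed-effects-only analyses.
#' @return A \code{selection_decision}: selected covariate sets,
#'   observed scores, null quantiles, the raw null draws (so the rule
#'   can be re-applied at another alpha with
#'   \code{\link{apply_selection}}), aggregation records and dropped
#'   chain counts.
#' @export
permutation_select <- function(data, selection = selection_config(),
                               n_iter = 10000, n_keep = 5000,
                               control = bart_control(),
                               hyper = model_hyper(), seed = NULL,
                               select_z = !is.null(data$Z)) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      selection$L_rep + 2L * selection$L)
  obs_tr <- lapply(seq_len(selection$L_rep), function(i)
    trace_scores(unified_fit(data, n_iter, n_keep, control, hyper,
                             seed = seeds[i])))

  agg <- function(key, fun) {
    m <- do.call(rbind, lapply(obs_tr, `[[`, key))
    apply(m, 2, fun)
  }
  observed <- list(vip = agg("vip", mean),
                   vip_type = agg("vip_type", mean),
                   mi = agg("mi", median),
                   lps = if (select_z)
                     average_lps(lapply(obs_tr, `[[`, "lps")))

  failed <- 0L
  null_scores <- vector("list", selection$L)
  for (l in seq_len(selection$L)) {
    set.seed(seeds[selection$L_rep + l])
    dp <- permute_dataset(data, selection$z_mode)
    sc <- tryCatch(
      trace_scores(unified_fit(dp, n_iter, n_keep, control, hyper,
                               seed = seeds[selection$L_rep +
                                              selection$L + l])),
      error = function(e) NULL)
    if (is.null(sc)) failed <- failed + 1L else null_scores[[l]] <- sc
  }
  null_scores <- Filter(Negate(is.null), null_scores)
  if (!length(null_scores)) stop("all permutation chains failed")
  if (selection$L < ceiling(1 / selection$alpha))
    warning("L = ", selection$L, " permutations give coarse quantile ",
            "resolution at alpha = ", selection$alpha)

  crit <- selection$criterion
  obs_x <- aggregate_categorical(observed[[crit]], data$x_group)
  null_x <- do.call(rbind, lapply(null_scores, function(sc)
    aggregate_categorical(sc[[crit]], data$x_group)))

  dec <- list(observed = observed, observed_x = obs_x, null_x = null_x,
              null_lps = if (select_z) lapply(null_scores, `[[`, "lps"),
              n_keep = n_keep, x_group = data$x_group,
              z_group = data$z_group, selection = selection,
              aggregation = c(vip = "mean", vip_type = "mean",
                              mi = "median", lps = "mean"),
              dropped_chains = failed, seed = seed)
  class(dec) <- "selection_decision"
  apply_selection(dec, selection$alpha)
}

#' Re-apply the permutation decision rule at a significance level
#'
#' Uses the observed scores and stored null draws of an existing
#' decision; no refitting. Selection is monotone in alpha: enlarging
#' alpha never drops a selected covariate.
#'
#' @param decision a \code{selection_decision}.
#' @param alpha significance level.
#' @return The decision with \code{selected_x}, \code{selected_z},
#'   \code{null_quantile_x} and submodel candidate records refreshed.
#' @export
apply_selection <- function(decision, alpha) {
  qx <- apply(decision$null_x, 2, null_quantile, alpha = alpha)
  decision$null_quantile_x <- qx
  decision$selected_x <- names(which(decision$observed_x > qx))
  decision$alpha <- alpha

  if (!is.null(decision$null_lps)) {
    obs <- decision$observed$lps
    masks <- unique(c(names(obs), unlist(lapply(decision$null_lps,
                                                names))))
    nl <- sapply(masks, function(m)
      sapply(decision$null_lps, function(x)
        if (m %in% names(x)) x[[m]] else 0))
    if (is.null(dim(nl))) nl <- matrix(nl, nrow = 1)
    qz <- apply(nl, 2, null_quantile, alpha = alpha)
    obs_full <- setNames(numeric(length(masks)), masks)
    obs_full[names(obs)] <- obs
    cand <- obs_full > qz & obs_full > 1 / decision$n_keep
    decision$submodels <- data.frame(mask = masks, observed = obs_full,
                                     null_quantile = qz,
                                     candidate = cand,
                                     row.names = NULL)
    groups <- names(decision$z_group)
    if (any(cand)) {
      best <- masks[cand][which.max(obs_full[cand])]
      decision$selected_mask <- best
      decision$selected_z <- mask_to_groups(best, groups)
    } else {
      decision$selected_mask <- strrep("0", length(groups))
      decision$selected_z <- character()
    }
  }
  decision
}

#' @export
print.selection_decision <- function(x, ...) {
  cat("selection_decision (criterion ", x$selection$criterion,
      ", alpha ", x$alpha, ")\n", sep = "")
  cat("  selected X:",
      if (length(x$selected_x)) paste(x$selected_x, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$selected_z))
    cat("  selected Z:",
        if (length(x$selected_z)) paste(x$selected_z, collapse = ", ")
        else "(none)", "\n")
  if (x$dropped_chains > 0)
    cat("  dropped permutation chains:", x$dropped_chains, "\n")
  invisible(x)
}

#' Sparse-Dirichlet selection (single chain, no permutations)
#'
#' Fits one chain with the sparsity-inducing Dirichlet splitting prior.
#' Individual-level covariates are ranked by posterior mean splitting
#' probability (dummy groups merged) and cut at the elbow (largest drop
#' in the ranked sequence); the random-effects submodel with the highest
#' LPS is selected.
#'
#' @param data a \code{\link{hier_data}}.
#' @param n_iter,n_keep chain length.
#' @param control a \code{\link{bart_control}} (its \code{sparse} flag
#'   is forced on).
#' @param hyper a \code{\link{model_hyper}}.
#' @param seed integer seed.
#' @return A list with \code{selected_x}, \code{selected_z},
#'   \code{probs} (ranked group probabilities) and the trace.
#' @export
sparse_select <- function(data, n_iter = 10000, n_keep = 5000,
                          control = bart_control(sparse = TRUE),
                          hyper = model_hyper(), seed = NULL) {
  control$sparse <- TRUE
  tr <- unified_fit(data, n_iter, n_keep, control, hyper, seed = seed)
  pg <- sort(aggregate_categorical(compute_dirichlet_prob(tr),
                                   data$x_group), decreasing = TRUE)
  ncut <- if (length(pg) >= 2) elbow_cutoff(pg) else length(pg)
  sel_x <- names(pg)[seq_len(ncut)]
  sel_z <- NULL
  if (!is.null(tr$v)) {
    lps <- compute_lps(tr)
    best <- names(lps)[which.max(lps)]
    sel_z <- mask_to_groups(best, names(data$z_group))
  }
  list(selected_x = sel_x, selected_z = sel_z, probs = pg, trace = tr)
}
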