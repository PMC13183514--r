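#' Run-scale presets
#'
#' \code{paper_preset()} mirrors the full study settings (250
#' replicates, L = 100 permutations, L_rep = 10 repeat chains, 10000
#' iterations keeping 5000); \code{desk_preset()} is the reduced scale
#' used for desk-size reproductions (25 replicates, L = 30, L_rep = 3,
#' 3000 iterations keeping 1500). Any run records the preset actually
#' used in its output.
#'
#' @param replicates,L,L_rep,n_iter,n_keep,step2_n_iter,step2_n_keep
#'   override individual entries.
#' @return A named list of run-scale settings.
#' @export
paper_preset <- function(replicates = 250, L = 100, L_rep = 10,
                         n_iter = 10000, n_keep = 5000,
                         step2_n_iter = 10000, step2_n_keep = 5000) {
  list(name = "paper", replicates = replicates, L = L, L_rep = L_rep,
       n_iter = n_iter, n_keep = n_keep, step2_n_iter = step2_n_iter,
       step2_n_keep = step2_n_keep)
}

#' @rdname paper_preset
#' @export
desk_preset <- function(replicates = 25, L = 30, L_rep = 3,
                        n_iter = 3000, n_keep = 1500,
                        step2_n_iter = 3000, step2_n_keep = 1500) {
  list(name = "desk", replicates = replicates, L = L, L_rep = L_rep,
       n_iter = n_iter, n_keep = n_keep, step2_n_iter = step2_n_iter,
       step2_n_keep = step2_n_keep)
}

methods_for <- function(z_structure) {
  if (z_structure == "constant")
    c("unified", "two_step", "two_step_bayes_linear", "sparse")
  else c("unified", "sparse")
}

metrics_row <- function(cfg, method, level, met, seconds, seed,
                        ok = TRUE) {
  data.frame(design = cfg$design, fixed_surface = cfg$fixed_surface,
             z_structure = cfg$z_structure, method = method,
             level = level,
             tp = met$tp, fp = met$fp, fn = met$fn,
             precision = met$precision, recall = met$recall,
             f1 = met$f1, type1 = met$type1,
             seconds = seconds, seed = seed, ok = ok,
             stringsAsFactors = FALSE)
}

na_metrics <- list(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                   precision = NA_real_, recall = NA_real_,
                   f1 = NA_real_, type1 = NA_real_)

#' Run one simulation replicate of one method
#'
#' Generates a dataset from the scenario, runs the method end to end,
#' and scores the selected sets against the generating truth at the
#' individual (fixed) and cluster (random) level. The two-step variants
#' apply only where Z is constant within clusters, and are random-level
#' procedures: their fixed-level row is reported as missing. A custom
#' method can be supplied as a function
#' \code{(sim, preset, seed) -> list(selected_x =, selected_z =)} for
#' harness checks.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param method \code{"unified"}, \code{"two_step"},
#'   \code{"two_step_bayes_linear"}, \code{"sparse"}, or a function.
#' @param seed replicate seed (drives data generation and all fits).
#' @param preset a run-scale preset list.
#' @param alpha significance level for permutation-calibrated methods.
#' @param criterion importance criterion for permutation-calibrated
#'   methods (default \code{"mi"}).
#' @return A two-row data frame (levels \code{fixed} and \code{random})
#'   of confusion counts, metrics, wall-clock seconds and bookkeeping.
#' @export
run_replicate <- function(config, method, seed,
                          preset = desk_preset(), alpha = 0.05,
                          criterion = "mi") {
  method_name <- if (is.function(method)) "custom" else method
  if (!is.function(method))
    method <- match.arg(method, c("unified", "two_step",
                                  "two_step_bayes_linear", "sparse"))
  if (method_name %in% c("two_step", "two_step_bayes_linear") &&
      config$z_structure != "constant")
    stop("the two-step procedure applies only to constant-Z scenarios")
  sim <- generate_scenario(config, seed = seed)
  truth_x <- names(sim$data$x_group)[sim$truth$informative_x]
  truth_z <- sim$truth$informative_z
  cand_x <- candidates_x(sim$data)
  cand_z <- candidates_z(sim$data)

  t0 <- proc.time()[["elapsed"]]
  sel_x <- NULL; sel_z <- NULL
  fit_seed <- (seed %% 2000000000L) + 1L   # keep derived seeds in integer range
  if (is.function(method)) {
    out <- method(sim, preset, fit_seed)
    sel_x <- out$selected_x; sel_z <- out$selected_z
  } else if (method == "unified") {
    dec <- permutation_select(
      sim$data,
      selection_config(L = preset$L, L_rep = preset$L_rep,
                       alpha = alpha, criterion = criterion,
                       z_mode = config$z_structure),
      n_iter = preset$n_iter, n_keep = preset$n_keep, seed = fit_seed)
    sel_x <- dec$selected_x; sel_z <- dec$selected_z
  } else if (method == "two_step") {
    ts <- two_step(sim$data, step1 = "bart", step2 = "bart",
                   selection_config(L = preset$L, L_rep = preset$L_rep,
                                    alpha = alpha,
                                    criterion = criterion,
                                    z_mode = "constant"),
                   n_iter = preset$n_iter, n_keep = preset$n_keep,
                   step2_n_iter = preset$step2_n_iter,
                   step2_n_keep = preset$step2_n_keep,
                   seed = fit_seed)
    sel_z <- ts$selected_z
  } else if (method == "two_step_bayes_linear") {
    ts <- two_step(sim$data, step1 = "linear", step2 = "spike_slab",
                   seed = fit_seed)
    sel_z <- ts$selected_z
  } else if (method == "sparse") {
    sp <- sparse_select(sim$data, n_iter = preset$n_iter,
                        n_keep = preset$n_keep, seed = fit_seed)
    sel_x <- sp$selected_x; sel_z <- sp$selected_z
  }
  secs <- proc.time()[["elapsed"]] - t0

  mf <- if (is.null(sel_x)) na_metrics else
    evaluate_selection(sel_x, truth_x, cand_x)
  mr <- if (is.null(sel_z)) na_metrics else
    evaluate_selection(sel_z, truth_z, cand_z)
  rbind(metrics_row(config, method_name, "fixed", mf, secs, seed),
        metrics_row(config, method_name, "random", mr, secs, seed))
}

#' Aggregate replicate records into a summary table
#'
#' Unweighted means and sample standard deviations of recall,
#' precision, F1 and type I error per (scenario, method, level) cell,
#' with replicate and failure counts.
#'
#' @param records a data frame of rows from \code{\link{run_replicate}}
#'   (failed replicates flagged with \code{ok = FALSE} are excluded
#'   from the means and counted).
#' @return A summary data frame, one row per cell.
#' @export
summarize_records <- function(records) {
  key <- interaction(records$design, records$fixed_surface,
                     records$z_structure, records$method,
                     records$level, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    okd <- d[d$ok, , drop = FALSE]
    cell <- d[1, c("design", "fixed_surface", "z_structure", "method",
                   "level")]
    stat <- function(v) c(mean(v, na.rm = TRUE),
                          if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                          else NA_real_)
    m <- vapply(okd[c("recall", "precision", "f1", "type1")], stat,
                numeric(2))
    cbind(cell,
          data.frame(recall = m[1, "recall"], recall_sd = m[2, "recall"],
                     precision = m[1, "precision"],
                     precision_sd = m[2, "precision"],
                     f1 = m[1, "f1"], f1_sd = m[2, "f1"],
                     type1 = m[1, "type1"], type1_sd = m[2, "type1"],
                     replicates = nrow(okd),
                     failures = sum(!d$ok)))
  }))
  rownames(out) <- NULL
  out
}

#' Run a batch of replicates for one scenario cell
#'
#' Replicate seeds are derived deterministically from the master seed,
#' so results are independent of execution order. Failed replicates are
#' recorded (not silently dropped) and excluded from summaries.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param method method name (see \code{\link{run_replicate}}).
#' @param replicates number of replicates.
#' @param seed master seed.
#' @param preset run-scale preset.
#' @param alpha,criterion selection settings.
#' @return Data frame of per-replicate records.
#' @export
run_cell <- function(config, method, replicates = 10, seed = 1,
                     preset = desk_preset(), alpha = 0.05,
                     criterion = "mi") {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    tryCatch(
      run_replicate(config, method, rep_seeds[r], preset, alpha,
                    criterion),
      error = function(e) {
        rbind(metrics_row(config, if (is.function(method)) "custom"
                          else method, "fixed", na_metrics, NA_real_,
                          rep_seeds[r], ok = FALSE),
              metrics_row(config, if (is.function(method)) "custom"
                          else method, "random", na_metrics, NA_real_,
                          rep_seeds[r], ok = FALSE))
      })
  }))
}

#' Sensitivity sweep along one design axis
#'
#' Reruns a base scenario while varying one knob — the number of noise
#' cluster-level predictors, the significance level alpha, the
#' individual-level dimension P, or the residual standard deviation —
#' with replicate seeds shared across values for paired comparison.
#'
#' @param config base \code{\link{scenario_config}}.
#' @param axis \code{"noise_z"}, \code{"alpha"}, \code{"p_dim"} or
#'   \code{"sigma_eps"}.
#' @param values values to sweep.
#' @param method method name.
#' @param replicates replicates per value.
#' @param seed master seed (shared across values).
#' @param preset run-scale preset.
#' @return Data frame of per-replicate records with a \code{value}
#'   column.
#' @export
sensitivity_sweep <- function(config, axis = c("noise_z", "alpha",
                                               "p_dim", "sigma_eps"),
                              values, method = "two_step",
                              replicates = 10, seed = 1,
                              preset = desk_preset()) {
  axis <- match.arg(axis)
  do.call(rbind, lapply(values, function(val) {
    cfg <- config
    alpha <- 0.05
    if (axis == "noise_z") cfg$n_noise_z <- as.integer(val)
    if (axis == "p_dim") cfg$P <- as.integer(val)
    if (axis == "sigma_eps") cfg$sigma_eps <- val
    if (axis == "alpha") alpha <- val
    rec <- run_cell(cfg, method, replicates, seed, preset, alpha)
    rec$value <- val
    rec$axis <- axis
    rec
  }))
}
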