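#' Score a variable-selection decision against ground truth
#'
#' Computes the confusion counts and the four selection metrics used
#' throughout the simulation study: precision TP/(TP+FP), recall
#' TP/(TP+FN), F1 = 2TP/(2TP+FP+FN) (the harmonic mean of the two
#' where both are defined, and 0 for an empty selection against a
#' nonempty truth), and the selection type I error
#' FP / (number of noise candidates). Ratios with empty denominators are
#' reported as \code{NA} with a flag, never silently as 0.
#'
#' @param selected set (integer indices or names) of selected covariates.
#' @param truth set of truly informative covariates.
#' @param candidates full candidate set; \code{selected} and
#'   \code{truth} must be subsets of it.
#' @return A list of class \code{selection_metrics} with counts
#'   \code{tp}, \code{fp}, \code{fn}, \code{noise_total}, metrics
#'   \code{precision}, \code{recall}, \code{f1}, \code{type1}, and
#'   \code{undefined}, the names of any metric with an empty denominator.
#' @export
evaluate_selection <- function(selected, truth, candidates) {
  if (length(setdiff(selected, candidates)) > 0)
    stop("selected set is not a subset of the candidates")
  if (length(setdiff(truth, candidates)) > 0)
    stop("truth set is not a subset of the candidates")
  selected <- unique(selected)
  truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  noise_total <- length(setdiff(candidates, truth))

  undefined <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    undefined <- c(undefined, "f1"); NA_real_
  }
  type1 <- if (noise_total > 0) fp / noise_total else {
    undefined <- c(undefined, "type1"); NA_real_
  }
  structure(list(tp = tp, fp = fp, fn = fn, noise_total = noise_total,
                 precision = precision, recall = recall, f1 = f1,
                 type1 = type1, undefined = undefined),
            class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat(sprintf(
    "selection_metrics: TP=%d FP=%d FN=%d | precision=%.3f recall=%.3f f1=%.3f type1=%.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$type1))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
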