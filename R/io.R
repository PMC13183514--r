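#' Write a hierarchical dataset to delimited text
#'
#' One comma-separated file (UTF-8, "." decimal) with header columns
#' \code{cluster_id, y, x_*, z_*} (the Z intercept column is implied and
#' not written), plus a JSON sidecar (\code{<path>.json}) recording
#' column types, dummy-group maps, whether Z is constant within
#' clusters, optional truth labels, and the generating configuration.
#'
#' @param data a \code{\link{hier_data}}.
#' @param path output CSV path.
#' @param truth optional truth labels to record in the sidecar.
#' @param config optional generating configuration to record.
#' @return Invisibly, the sidecar path.
#' @export
write_hier_data <- function(data, path, truth = NULL, config = NULL) {
  stopifnot(inherits(data, "hier_data"))
  df <- data.frame(
    cluster_id = if (is.null(data$cluster)) seq_along(data$y)
    else as.character(data$cluster),
    y = data$y, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$X, optional = TRUE))
  if (!is.null(data$Z))
    df <- cbind(df, as.data.frame(data$Z[, -1, drop = FALSE],
                                  optional = TRUE))
  write.csv(df, path, row.names = FALSE)
  z_constant <- if (!is.null(data$Z))
    isTRUE(tryCatch(check_z_constant(data), error = function(e) FALSE))
  schema <- list(
    x_columns = colnames(data$X), x_type = data$x_type,
    x_group = data$x_group,
    z_columns = if (!is.null(data$Z)) colnames(data$Z)[-1],
    z_group = data$z_group, z_constant = z_constant,
    has_cluster = !is.null(data$cluster),
    truth = truth, config = config)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(schema, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}

#' Load a hierarchical dataset from delimited text
#'
#' Reads a CSV written by \code{\link{write_hier_data}} (or any file
#' matching its schema sidecar). Declared-constant Z columns are
#' verified and a varying column raises an error naming the offending
#' cluster.
#'
#' @param path CSV path.
#' @param schema sidecar path (default \code{<path>.json}).
#' @return A \code{\link{hier_data}}; any truth labels from the sidecar
#'   are attached as attribute \code{"truth"}.
#' @export
load_hier_data <- function(path, schema = paste0(path, ".json")) {
  sc <- jsonlite::read_json(schema, simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  need <- c("cluster_id", "y", sc$x_columns, sc$z_columns)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  num_cols <- setdiff(need, "cluster_id")
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in columns: ", paste(bad, collapse = ", "))
  X <- as.matrix(df[sc$x_columns])
  Z <- if (length(sc$z_columns)) {
    z <- cbind(1, as.matrix(df[sc$z_columns]))
    colnames(z) <- c("(Intercept)", sc$z_columns)
    z
  }
  as_group <- function(g) if (is.null(g)) NULL else lapply(g, unlist)
  dat <- hier_data(df$y, X,
                   cluster = if (isTRUE(sc$has_cluster)) df$cluster_id,
                   Z = Z, x_type = sc$x_type,
                   x_group = as_group(sc$x_group),
                   z_group = as_group(sc$z_group))
  if (isTRUE(sc$z_constant)) check_z_constant(dat)
  if (!is.null(sc$truth)) attr(dat, "truth") <- sc$truth
  attr(dat, "config") <- sc$config
  dat
}

#' Dummy-encode a categorical column
#'
#' @param x a factor or vector coercible to one.
#' @param name base name for the generated columns.
#' @param full one-hot encode all levels instead of dropping the
#'   reference (first) level.
#' @return Matrix of 0/1 columns named \code{<name>.<level>}.
#' @export
dummy_encode <- function(x, name = "x", full = FALSE) {
  f <- as.factor(x)
  lev <- levels(f)
  keep <- if (full) lev else lev[-1]
  out <- vapply(keep, function(l) as.numeric(f == l),
                numeric(length(f)))
  out <- matrix(out, nrow = length(f),
                dimnames = list(NULL, paste0(name, ".", keep)))
  out
}

#' Build a run manifest
#'
#' Every artifact the toolkit writes is traceable to a manifest:
#' package version, resolved configuration, master seed, timestamps and
#' accumulated warnings — enough to reproduce the run draw for draw.
#'
#' @param config resolved configuration (any JSON-serializable list).
#' @param seed master seed.
#' @param started POSIXct start time.
#' @param warnings character vector of warnings raised during the run.
#' @return A \code{run_manifest} list.
#' @export
run_manifest <- function(config, seed, started = Sys.time(),
                         warnings = character()) {
  structure(list(
    tool = "mixbart",
    version = as.character(utils::packageVersion("mixbart")),
    config = config, seed = seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings), class = "run_manifest")
}

#' Write a decision or manifest as JSON
#' @param x a \code{selection_decision}, \code{run_manifest}, or any
#'   serializable list (environments and traces are dropped).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_json_artifact <- function(x, path) {
  drop <- function(v) {
    if (is.environment(v) || inherits(v, "mixbart_trace")) return(NULL)
    if (is.list(v) && !is.data.frame(v))
      return(Filter(Negate(is.null), lapply(v, drop)))
    v
  }
  jsonlite::write_json(drop(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
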