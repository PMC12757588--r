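#' Run configuration for network inference
#'
#' Collects every tunable of the inference pipeline with the defaults used
#' throughout: 80 pseudocells, a sparsity-tradeoff grid
#' alpha in {0.001, 0.002, ..., 0.4}, a 200-point lambda path, and an edge
#' weight threshold of 0.4.
#'
#' @param n_pseudocells Number of pseudotime bins (default 80). Choose a
#'   value that yields roughly 30-40 cells per pseudocell.
#' @param alpha_max,alpha_step Upper end and step of the alpha grid
#'   (defaults 0.4 and 0.001). `alpha_grid` overrides both when given.
#' @param alpha_grid Explicit strictly increasing grid in \[0, 1\].
#' @param n_lambda Number of lambda values on the regularization path
#'   (default 200).
#' @param lambda_ratio Ratio of the smallest to the largest lambda on the
#'   geometric path (default 1e-4).
#' @param weight_threshold Edge weight magnitude threshold for reporting
#'   interactions (default 0.4, strict inequality).
#' @param mode `"multiome"` (predict accessibility from expression) or
#'   `"rna_only"` (predict expression from expression).
#' @param exclude_self Drop the target's own expression from its predictor
#'   set (default `TRUE`).
#' @param lag Integer pseudocell lag applied to predictors (default 0, the
#'   canonical contemporaneous pairing; nonzero values are for sensitivity
#'   analysis only).
#' @param seed Integer seed for all randomized operations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_pseudocells = 80L,
                       alpha_max = 0.4,
                       alpha_step = 0.001,
                       alpha_grid = NULL,
                       n_lambda = 200L,
                       lambda_ratio = 1e-4,
                       weight_threshold = 0.4,
                       mode = c("multiome", "rna_only"),
                       exclude_self = TRUE,
                       lag = 0L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(alpha_grid)) {
    alpha_grid <- seq(alpha_step, alpha_max, by = alpha_step)
  }
  stopifnot(
    n_pseudocells >= 1, n_lambda >= 2,
    lambda_ratio > 0, lambda_ratio < 1,
    weight_threshold >= 0, weight_threshold <= 1,
    length(alpha_grid) >= 1
  )
  if (any(alpha_grid < 0 | alpha_grid > 1) || is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("`alpha_grid` must be strictly increasing within [0, 1].", call. = FALSE)
  }
  structure(
    list(
      n_pseudocells = as.integer(n_pseudocells),
      alpha_grid = alpha_grid,
      n_lambda = as.integer(n_lambda),
      lambda_ratio = lambda_ratio,
      weight_threshold = weight_threshold,
      mode = mode,
      exclude_self = isTRUE(exclude_self),
      lag = as.integer(lag),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  n_pseudocells:    %d\n", x$n_pseudocells))
  cat(sprintf(
    "  alpha_grid:       %d values in [%g, %g]\n",
    length(x$alpha_grid), min(x$alpha_grid), max(x$alpha_grid)
  ))
  cat(sprintf("  n_lambda:         %d (ratio %g)\n", x$n_lambda, x$lambda_ratio))
  cat(sprintf("  weight_threshold: %g\n", x$weight_threshold))
  cat(sprintf("  mode:             %s\n", x$mode))
  cat(sprintf("  exclude_self:     %s, lag: %d, seed: %d\n", x$exclude_self, x$lag, x$seed))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Fields mirror the arguments of [run_config()]; absent fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop("Unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, y)
}

#' Per-cell ordering along a trajectory
#'
#' Binds cell identifiers to pseudotime values (and optional cluster
#' labels) and sorts them by non-decreasing pseudotime; ties are broken by
#' input order (stable sort).
#'
#' @param cell_id Character vector of unique cell identifiers.
#' @param pseudotime Numeric pseudotime per cell, or `NULL` for orderings
#'   used only by the cluster-random control.
#' @param cluster Optional per-cell cluster labels.
#' @return A tibble of class `cell_ordering`, sorted by pseudotime when
#'   present.
#' @export
cell_ordering <- function(cell_id, pseudotime = NULL, cluster = NULL) {
  cell_id <- trimws(as.character(cell_id))
  if (anyDuplicated(cell_id)) stop("Duplicate cell identifiers.", call. = FALSE)
  out <- tibble::tibble(cell_id = cell_id)
  if (!is.null(pseudotime)) {
    stopifnot(length(pseudotime) == length(cell_id))
    if (any(!is.finite(pseudotime))) stop("Non-finite pseudotime.", call. = FALSE)
    out$pseudotime <- as.numeric(pseudotime)
  }
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == length(cell_id))
    out$cluster <- as.character(cluster)
  }
  if (!is.null(pseudotime)) {
    out <- out[order(out$pseudotime), , drop = FALSE] # stable: ties keep input order
  }
  class(out) <- c("cell_ordering", class(out))
  out
}

#' Read a pseudotime table
#'
#' Expects a TSV with columns `cell_id` and `pseudotime`, plus an optional
#' `cluster` column.
#'
#' @param path TSV path.
#' @return A [cell_ordering()].
#' @export
read_pseudotime <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cell_id", "pseudotime") %in% names(df))) {
    stop("Pseudotime file needs columns `cell_id` and `pseudotime`.", call. = FALSE)
  }
  cell_ordering(df$cell_id, df$pseudotime,
    cluster = if ("cluster" %in% names(df)) df$cluster else NULL
  )
}
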