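#' Infer a signed gene regulatory network from pseudocells
#'
#' The inference core. For every target gene g, a LASSO regularization path
#' is fitted predicting g's pseudocell response from the pseudocell gene
#' expression of the candidate regulators: in `multiome` mode the response
#' is g's pseudocell accessibility (`y_p`), so that regulator transcription
#' is paired with the contemporaneous chromatin response of the target; in
#' `rna_only` mode the response is g's own pseudocell expression. For each
#' value of the sparsity-tradeoff parameter alpha on `config$alpha_grid`, a
#' path point is selected with [select_lambda()] and its coefficients are
#' sign-binarized; the final network weight matrix W is the element-wise
#' mean of these signed matrices over the grid, giving entries in
#' \[-1, 1\] (regulator rows, target columns, zero diagonal).
#'
#' Targets whose response is constant across pseudocells are degenerate:
#' they receive an all-zero column in W and a warning.
#'
#' @param pc A `pseudocell_set` from [make_pseudocells()] or
#'   [make_random_pseudocells()]; `multiome` mode requires its `y_p`.
#' @param config A [run_config()].
#' @param keep_alpha_networks Retain the per-alpha signed matrices (as a
#'   list of sparse matrices); memory scales with
#'   `length(alpha_grid) * G^2`.
#' @return An object of class `signed_network`: fields `W` (G x G),
#'   `gene_ids`, `alpha_grid`, `mode`, and `alpha_networks` when retained.
#' @export
infer_network <- function(pc, config = run_config(), keep_alpha_networks = FALSE) {
  stopifnot(inherits(pc, "pseudocell_set"), inherits(config, "run_config"))
  x_p <- pc$x_p
  n <- ncol(x_p)
  if (n < 3L) stop("Need at least 3 pseudocells.", call. = FALSE)
  genes <- rownames(x_p)
  if (config$mode == "multiome") {
    if (is.null(pc$y_p)) stop("multiome mode requires pseudocell accessibility.", call. = FALSE)
    missing <- setdiff(rownames(pc$y_p), genes)
    if (length(missing)) {
      stop("Gene(s) in accessibility absent from expression: ",
        paste(utils::head(missing, 5), collapse = ", "),
        call. = FALSE
      )
    }
    Y <- pc$y_p[genes, , drop = FALSE]
  } else {
    Y <- x_p
  }

  lag <- config$lag
  if (lag < 0L || lag >= n) stop("`lag` must be in [0, n_pseudocells).", call. = FALSE)
  resp_idx <- (lag + 1L):n
  pred_idx <- 1L:(n - lag)
  Xall <- t(x_p[, pred_idx, drop = FALSE])

  G <- length(genes)
  s <- length(config$alpha_grid)
  W <- matrix(0, G, G, dimnames = list(genes, genes))
  alpha_nets <- if (keep_alpha_networks) {
    lapply(seq_len(s), function(j) {
      Matrix::Matrix(0, G, G, dimnames = list(genes, genes), sparse = TRUE)
    })
  } else {
    NULL
  }
  degenerate_targets <- character(0)

  for (g in genes) {
    preds <- if (config$exclude_self) setdiff(genes, g) else genes
    y <- Y[g, resp_idx]
    path <- fit_lasso_path(y, Xall[, preds, drop = FALSE],
      n_lambda = config$n_lambda, lambda_ratio = config$lambda_ratio
    )
    nnz_ref <- path$nonzero[path$lambda_mse_index]
    if (path$degenerate || nnz_ref == 0L) {
      degenerate_targets <- c(degenerate_targets, g)
      next # zero column; per-alpha networks stay zero too
    }
    S <- sign(path$coefs) # predictors x n_lambda
    rel_mse <- path$mse / path$mse_trivial
    rel_nnz <- path$nonzero / nnz_ref
    obj <- abs(outer(config$alpha_grid, rel_mse) -
      outer(1 - config$alpha_grid, rel_nnz))
    idx <- max.col(-obj, ties.method = "first") # per-alpha selected lambda index
    counts <- tabulate(idx, nbins = length(path$lambdas))
    W[preds, g] <- as.numeric(S %*% counts) / s
    if (keep_alpha_networks) {
      for (j in seq_len(s)) alpha_nets[[j]][preds, g] <- S[, idx[j]]
    }
  }
  if (length(degenerate_targets)) {
    warning(
      "Degenerate target(s) with constant or unpredictable response, ",
      "reported with all-zero regulation: ",
      paste(utils::head(degenerate_targets, 10), collapse = ", "),
      call. = FALSE
    )
  }
  diag(W) <- 0
  structure(
    list(
      W = W, gene_ids = genes, alpha_grid = config$alpha_grid,
      mode = config$mode, alpha_networks = alpha_nets,
      degenerate_targets = degenerate_targets
    ),
    class = "signed_network"
  )
}

#' @exportS3Method base::print
print.signed_network <- function(x, ...) {
  nz <- sum(x$W != 0)
  cat(sprintf(
    "<signed_network> %d genes, %d nonzero edges, %d alpha values, mode = %s\n",
    length(x$gene_ids), nz, length(x$alpha_grid), x$mode
  ))
  invisible(x)
}

#' Edge-level view of a signed network
#'
#' @param x A `signed_network`.
#' @param ... Unused.
#' @return Tibble with one row per nonzero entry of W: `regulator`,
#'   `target`, `weight`, `sign`, sorted by |weight| descending.
#' @export
tidy.signed_network <- function(x, ...) {
  nz <- which(x$W != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    regulator = x$gene_ids[nz[, 1]],
    target = x$gene_ids[nz[, 2]],
    weight = x$W[nz],
    sign = as.integer(sign(x$W[nz]))
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)), .data$regulator, .data$target)
}

#' One-row summary of a signed network
#'
#' @param x A `signed_network`.
#' @param threshold Weight-magnitude threshold used for the edge count
#'   (default 0.4).
#' @param ... Unused.
#' @return Tibble with gene count, nonzero entries, and the count of
#'   edges exceeding the threshold.
#' @export
glance.signed_network <- function(x, threshold = 0.4, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_nonzero = sum(x$W != 0),
    n_edges_above_threshold = sum(abs(x$W) > threshold),
    n_alpha = length(x$alpha_grid),
    mode = x$mode
  )
}

#' Heatmap of a signed network's weight matrix
#'
#' @param object A `signed_network`.
#' @param ... Unused.
#' @return A ggplot object: regulators on rows, targets on columns,
#'   diverging fill over \[-1, 1\].
#' @export
autoplot.signed_network <- function(object, ...) {
  df <- tibble::as_tibble(object$W, rownames = "regulator") |>
    tidyr::pivot_longer(-"regulator", names_to = "target", values_to = "weight")
  df$regulator <- factor(df$regulator, levels = rev(object$gene_ids))
  df$target <- factor(df$target, levels = object$gene_ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$regulator, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = "Target", y = "Regulator", fill = "W") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
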