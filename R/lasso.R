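#' Fit a LASSO regularization path for one target gene
#'
#' Solves, over a decreasing grid of penalty weights lambda, the L1-penalized
#' least-squares problem predicting a target's pseudocell response from the
#' pseudocell expression of candidate regulators. Fitting is delegated to
#' glmnet; the lambda grid is built here: geometric with `n_lambda` points
#' from `lambda_max` (the smallest penalty at which all coefficients are
#' zero, `max_j |<x_j_std, y - mean(y)>| / n` on standardized predictors)
#' down to `lambda_max * lambda_ratio`. Predictors are standardized for
#' fitting; coefficients are reported on the original data scale.
#'
#' @param y Numeric response vector (length n >= 3).
#' @param X Numeric n x p predictor matrix (p >= 1), columns named.
#' @param n_lambda Number of path points (default 200).
#' @param lambda_ratio `lambda_min / lambda_max` (default 1e-4).
#' @return An object of class `lasso_path` with fields `lambdas` (strictly
#'   decreasing), `coefs` (p x n_lambda), `intercepts`, `mse` (in-sample
#'   training MSE per lambda), `nonzero` (nonzero-coefficient count per
#'   lambda), `mse_trivial` (MSE of the intercept-only model),
#'   `lambda_mse_index` (first index attaining the minimal MSE) and
#'   `degenerate` (`TRUE` when the response is constant or no predictor
#'   varies, in which case all coefficients are zero).
#' @export
fit_lasso_path <- function(y, X, n_lambda = 200L, lambda_ratio = 1e-4) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < 3L) stop("Need at least 3 observations.", call. = FALSE)
  if (p < 1L) stop("Need at least 1 predictor.", call. = FALSE)
  if (nrow(X) != n) stop("`X` rows must match `length(y)`.", call. = FALSE)
  if (n_lambda < 2L) stop("`n_lambda` must be at least 2.", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("Non-finite values in `y` or `X`.", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  mse_trivial <- mean((y - mean(y))^2)
  yc <- y - mean(y)
  sds <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  ok <- sds > 0
  lambda_max <- if (any(ok)) {
    Xs <- scale(X[, ok, drop = FALSE], center = TRUE, scale = sds[ok])
    max(abs(crossprod(Xs, yc))) / n
  } else {
    0
  }

  degenerate_path <- function() {
    lambdas <- exp(seq(0, log(lambda_ratio), length.out = n_lambda))
    structure(
      list(
        lambdas = lambdas,
        coefs = matrix(0, p, n_lambda, dimnames = list(colnames(X), NULL)),
        intercepts = rep(mean(y), n_lambda),
        mse = rep(mse_trivial, n_lambda),
        nonzero = rep(0L, n_lambda),
        mse_trivial = mse_trivial,
        lambda_mse_index = 1L,
        degenerate = TRUE
      ),
      class = "lasso_path"
    )
  }
  if (mse_trivial == 0 || lambda_max <= 0) {
    return(degenerate_path())
  }

  # top of the grid sits a hair above the KKT bound so the all-zero model is
  # exact in floating point
  lambdas <- lambda_max * (1 + 1e-6) * exp(seq(0, log(lambda_ratio), length.out = n_lambda))
  # glmnet needs >= 2 predictor columns; pad with an all-zero dummy if needed
  Xfit <- if (p == 1L) cbind(X, `..dummy` = 0) else X
  # At near-zero lambda on exactly-fittable (noise-free) responses the
  # solver can stop short of the tight threshold; the path is then padded
  # below with its last converged solution, so the warning is muffled.
  fit <- withCallingHandlers(
    glmnet::glmnet(Xfit, y,
      family = "gaussian", lambda = lambdas,
      standardize = TRUE, intercept = TRUE, thresh = 1e-18, maxit = 1e7
    ),
    warning = function(w) {
      if (grepl("Convergence for .* lambda value not reached", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- as.matrix(fit$beta)[seq_len(p), , drop = FALSE]
  rownames(coefs) <- colnames(X)
  intercepts <- as.numeric(fit$a0)
  if (ncol(coefs) < n_lambda) { # glmnet may stop early; pad with last solution
    extra <- n_lambda - ncol(coefs)
    coefs <- cbind(coefs, coefs[, rep(ncol(coefs), extra), drop = FALSE])
    intercepts <- c(intercepts, rep(intercepts[length(intercepts)], extra))
  }
  pred <- sweep(X %*% coefs, 2, intercepts, "+")
  mse <- unname(colMeans((y - pred)^2))
  nonzero <- as.integer(colSums(coefs != 0))
  structure(
    list(
      lambdas = lambdas,
      coefs = coefs,
      intercepts = intercepts,
      mse = mse,
      nonzero = nonzero,
      mse_trivial = mse_trivial,
      lambda_mse_index = which.min(mse),
      degenerate = FALSE
    ),
    class = "lasso_path"
  )
}

#' @exportS3Method base::print
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "<lasso_path> %d lambdas in [%.3g, %.3g], %d predictors%s\n",
    length(x$lambdas), min(x$lambdas), max(x$lambdas), nrow(x$coefs),
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Per-lambda summary of a LASSO path
#'
#' @param x A `lasso_path`.
#' @param ... Unused.
#' @return Tibble with one row per lambda: `lambda`, `mse`, `nonzero`.
#' @export
tidy.lasso_path <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambdas,
    mse = x$mse,
    nonzero = x$nonzero
  )
}

#' @export
glance.lasso_path <- function(x, ...) {
  tibble::tibble(
    n_lambda = length(x$lambdas),
    mse_trivial = x$mse_trivial,
    mse_min = min(x$mse),
    nonzero_at_mse_min = x$nonzero[x$lambda_mse_index],
    degenerate = x$degenerate
  )
}

#' Gene-specific sparsity selection along a LASSO path
#'
#' Selects the path point minimizing
#' `| alpha * MSE_lambda / MSE_trivial - (1 - alpha) * nnz_lambda / nnz_at_min_MSE |`,
#' where `nnz` is the nonzero-coefficient count and `nnz_at_min_MSE` refers
#' to the path point with minimal training MSE. The tradeoff parameter
#' `alpha` interpolates between the trivial model (`alpha = 0`: all
#' coefficients zero) and the minimum-training-MSE model (`alpha = 1`).
#' Ties are broken toward the largest lambda (sparsest model). When the
#' minimum-MSE model itself has no nonzero coefficient the path is
#' degenerate and the trivial model is returned for every alpha.
#'
#' @param path A [fit_lasso_path()] result.
#' @param alpha Tradeoff parameter in \[0, 1\].
#' @return A list with `index` (selected lambda index), `lambda`,
#'   `coefficients` (named vector on the original scale) and `degenerate`.
#' @export
select_lambda <- function(path, alpha) {
  stopifnot(inherits(path, "lasso_path"), alpha >= 0, alpha <= 1)
  nnz_ref <- path$nonzero[path$lambda_mse_index]
  if (path$degenerate || nnz_ref == 0L) {
    return(list(
      index = 1L, lambda = path$lambdas[1],
      coefficients = stats::setNames(rep(0, nrow(path$coefs)), rownames(path$coefs)),
      degenerate = TRUE
    ))
  }
  obj <- abs(
    alpha * path$mse / path$mse_trivial -
      (1 - alpha) * path$nonzero / nnz_ref
  )
  idx <- which.min(obj) # first minimum = largest lambda on the decreasing grid
  list(
    index = idx, lambda = path$lambdas[idx],
    coefficients = path$coefs[, idx],
    degenerate = FALSE
  )
}

#' Sign-binarize a coefficient vector
#'
#' Maps each coefficient to +1 (positive), -1 (negative) or 0 (zero),
#' discarding magnitudes.
#'
#' @param coefs Numeric vector of finite coefficients.
#' @return Integer vector in \{-1, 0, +1\}, names preserved.
#' @export
binarize_signed <- function(coefs) {
  if (any(!is.finite(coefs))) stop("Non-finite coefficients.", call. = FALSE)
  stats::setNames(as.integer(sign(coefs)), names(coefs))
}
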