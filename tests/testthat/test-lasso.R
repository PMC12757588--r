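test_that("the lambda grid starts at an all-zero model and ends near the OLS fit", {
  withr::with_seed(4, {
    X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X[, "b"] # noise-free single-predictor response
  })
  path <- fit_lasso_path(y, X, n_lambda = 100)
  expect_identical(path$nonzero[1], 0L)
  expect_equal(path$mse[1], path$mse_trivial, tolerance = 1e-10)
  expect_true(all(diff(path$lambdas) < 0))
  # exact-fit limit: smallest lambda recovers the generative coefficient
  last <- path$coefs[, ncol(path$coefs)]
  expect_equal(unname(last["b"]), 1, tolerance = 1e-3)
  expect_lt(path$mse[length(path$mse)], 1e-6)
})

test_that("training MSE is non-increasing along the path (100 seeded instances)", {
  for (seed in 1:100) {
    inst <- withr::with_seed(seed, {
      n <- sample(10:30, 1)
      p <- sample(2:8, 1)
      X <- matrix(stats::rnorm(n * p), n, p)
      beta <- stats::rnorm(p) * stats::rbinom(p, 1, 0.5)
      list(X = X, y = as.numeric(X %*% beta) + stats::rnorm(n, sd = 0.3))
    })
    path <- fit_lasso_path(inst$y, inst$X, n_lambda = 60)
    expect_true(all(diff(path$mse) <= 1e-8 * pmax(path$mse[-length(path$mse)], 1e-12)))
    expect_lte(path$mse[length(path$mse)], path$mse_trivial + 1e-12)
  }
})

test_that("path coefficients match an independent coordinate-descent solve", {
  for (seed in 1:4) {
    inst <- withr::with_seed(seed, {
      X <- matrix(stats::rnorm(100), 20, 5, dimnames = list(NULL, paste0("g", 1:5)))
      beta <- c(1.5, 0, -2, 0, 0.5)
      list(X = X, y = as.numeric(X %*% beta) + stats::rnorm(20, sd = 0.5))
    })
    path <- fit_lasso_path(inst$y, inst$X, n_lambda = 50)
    for (idx in c(10L, 25L, 45L)) { # spot-check three lambdas along the path
      want <- oracle_lasso(inst$y, inst$X, path$lambdas[idx])
      expect_lt(max(abs(path$coefs[, idx] - want$beta)), 1e-6)
      expect_lt(abs(path$intercepts[idx] - want$intercept), 1e-6)
    }
  }
})

test_that("single-predictor fits work and a constant response degenerates", {
  withr::with_seed(2, {
    x <- matrix(stats::rnorm(15), 15, 1, dimnames = list(NULL, "only"))
    y <- 2 * x[, 1] + stats::rnorm(15, sd = 0.1)
  })
  path <- fit_lasso_path(y, x, n_lambda = 40)
  expect_identical(nrow(path$coefs), 1L)
  expect_equal(unname(path$coefs[1, ncol(path$coefs)]), 2, tolerance = 0.1)

  const <- fit_lasso_path(rep(3, 10), matrix(stats::rnorm(20), 10, 2), n_lambda = 10)
  expect_true(const$degenerate)
  expect_identical(const$mse_trivial, 0)
  expect_true(all(const$coefs == 0))

  expect_error(fit_lasso_path(y, x, n_lambda = 1), "at least 2")
  expect_error(fit_lasso_path(y[1:2], x[1:2, , drop = FALSE]), "at least 3")
  expect_error(fit_lasso_path(c(y[-1], NA), x), "Non-finite")
})

toy_path <- function(mse, nonzero, mse_trivial = 1) {
  # hand-built path object for selection-rule tests
  L <- length(mse)
  structure(
    list(
      lambdas = rev(seq_len(L)) / L,
      coefs = matrix(rep(seq_len(L), each = 3) * rep(c(1, -1, 0), L), 3, L,
        dimnames = list(c("p1", "p2", "p3"), NULL)
      ),
      intercepts = rep(0, L),
      mse = mse,
      nonzero = as.integer(nonzero),
      mse_trivial = mse_trivial,
      lambda_mse_index = which.min(mse),
      degenerate = FALSE
    ),
    class = "lasso_path"
  )
}

test_that("the tradeoff objective reproduces the hand-enumerated example", {
  # mse_trivial = 1; mse = [1.0, 0.6, 0.3, 0.2]; nonzero = [0, 1, 2, 3];
  # alpha = 0.5 gives objective [0.5, 0.1333, 0.1833, 0.4] -> second lambda
  path <- toy_path(c(1.0, 0.6, 0.3, 0.2), c(0, 1, 2, 3))
  sel <- select_lambda(path, 0.5)
  expect_identical(sel$index, 2L)
  obj <- abs(0.5 * path$mse / 1 - 0.5 * path$nonzero / 3)
  expect_equal(obj, c(0.5, 0.4 / 3, 0.55 / 3, 0.4), tolerance = 1e-12)
})

test_that("alpha endpoints select the trivial and the min-MSE models", {
  for (seed in 1:10) {
    inst <- withr::with_seed(seed, {
      X <- matrix(stats::rnorm(80), 16, 5)
      list(X = X, y = as.numeric(X %*% stats::rnorm(5)) + stats::rnorm(16, sd = 0.2))
    })
    path <- fit_lasso_path(inst$y, inst$X, n_lambda = 50)
    s0 <- select_lambda(path, 0)
    expect_identical(sum(s0$coefficients != 0), 0L)
    s1 <- select_lambda(path, 1)
    expect_identical(s1$index, path$lambda_mse_index)
  }
})

test_that("selection ties break toward the largest lambda", {
  path <- toy_path(c(0.5, 0.5, 0.5), c(1, 1, 1))
  # identical objective everywhere -> sparsest (first, largest-lambda) point
  expect_identical(select_lambda(path, 0.7)$index, 1L)
})

test_that("a degenerate path returns the trivial model for every alpha", {
  path <- toy_path(c(1, 1, 1), c(0, 0, 0))
  for (a in c(0, 0.3, 1)) {
    sel <- select_lambda(path, a)
    expect_true(sel$degenerate)
    expect_true(all(sel$coefficients == 0))
  }
})

test_that("sign binarization is the exact sign map", {
  expect_identical(
    binarize_signed(c(a = 0.37, b = -0.02, c = 0, d = 1e-12)),
    c(a = 1L, b = -1L, c = 0L, d = 1L)
  )
  expect_error(binarize_signed(c(1, NA)), "Non-finite")
})
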