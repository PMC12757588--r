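# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and glmnet): naive loops and first-principles
# formulas only.

# Coordinate-descent solve of the penalized least-squares problem
#   min_{b0, b} 1/(2n) * sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j |b_j|
# with predictors standardized to unit (1/n) variance and coefficients
# returned on the original scale — the same problem fit_lasso_path poses
# to glmnet at a single lambda.
oracle_lasso <- function(y, X, lambda, tol = 1e-12, max_iter = 100000L) {
  n <- length(y)
  p <- ncol(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  active <- sds > 0
  Xs <- X
  for (j in seq_len(p)) {
    Xs[, j] <- if (active[j]) (X[, j] - mu[j]) / sds[j] else 0
  }
  beta <- rep(0, p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (iter in seq_len(max_iter)) {
    delta <- 0
    r <- y - b0 - as.numeric(Xs %*% beta)
    for (j in seq_len(p)) {
      if (!active[j]) next
      rho <- sum(Xs[, j] * (r + Xs[, j] * beta[j])) / n
      new <- soft(rho, lambda)
      if (new != beta[j]) {
        r <- r - Xs[, j] * (new - beta[j])
        delta <- max(delta, abs(new - beta[j]))
        beta[j] <- new
      }
    }
    new_b0 <- b0 + mean(r)
    r <- r - (new_b0 - b0)
    delta <- max(delta, abs(new_b0 - b0))
    b0 <- new_b0
    if (delta < tol) break
  }
  out <- ifelse(active, beta / ifelse(sds > 0, sds, 1), 0)
  names(out) <- colnames(X)
  list(beta = out, intercept = b0 - sum(out * mu))
}

# O(peaks x genes) interval-overlap gene scoring with half-open intervals.
oracle_gene_scores <- function(peak_coords, peak_counts, windows) {
  out <- matrix(0, nrow(windows), ncol(peak_counts),
    dimnames = list(windows$gene_id, colnames(peak_counts))
  )
  for (g in seq_len(nrow(windows))) {
    for (p in seq_len(nrow(peak_coords))) {
      same_chrom <- peak_coords$chrom[p] == windows$chrom[g]
      overlaps <- peak_coords$start[p] < windows$window_end[g] &&
        windows$window_start[g] < peak_coords$end[p]
      if (same_chrom && overlaps) {
        out[g, ] <- out[g, ] + peak_counts[p, ]
      }
    }
  }
  out
}

# Brute-force partition of N cells into n bins: assign cell i to the bin
# found by walking bins left to right, filling larger bins first.
oracle_bin_sizes <- function(N, n) {
  sizes <- integer(n)
  i <- 1L
  for (cell in seq_len(N)) {
    cap <- if (i <= N %% n) N %/% n + 1L else N %/% n
    if (sizes[i] == cap) i <- i + 1L
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

# Step-convention area under the early precision-recall curve from a
# logical vector of per-rank hits (descending score, no ties), walking one
# candidate at a time.
oracle_aueprc <- function(hits, r_max) {
  n_pos <- sum(hits)
  tp <- 0
  area <- 0
  prev_recall <- 0
  for (k in seq_along(hits)) {
    if (hits[k]) {
      tp <- tp + 1
      recall <- tp / n_pos
      precision <- tp / k
      lo <- min(prev_recall, r_max)
      hi <- min(recall, r_max)
      area <- area + precision * (hi - lo)
      prev_recall <- recall
      if (prev_recall >= r_max) break
    }
  }
  area / r_max
}

random_edge_list <- function(n_edges, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", 1:30)
    pairs <- expand.grid(regulator = genes, target = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    picked <- pairs[sample.int(nrow(pairs), n_edges), ]
    tibble::tibble(
      regulator = picked$regulator,
      target = picked$target,
      weight = round(stats::runif(n_edges, -1, 1), 6),
      sign = as.integer(sign(round(stats::runif(n_edges, -1, 1), 6)))
    )
  })
}

# A minimal named matrix for container tests.
toy_matrix <- function(nr = 3, nc = 2, seed = 1, nonneg = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(nr * nc), nr, nc,
      dimnames = list(sprintf("gene%02d", seq_len(nr)), sprintf("cell%02d", seq_len(nc)))
    )
    if (nonneg) m <- abs(m)
    m
  })
}

# Ranked-prediction table whose k-th row is a positive iff hits[k]; used by
# the precision-recall tests.
ranked_from_hits <- function(hits, scores = NULL) {
  n <- length(hits)
  if (is.null(scores)) scores <- seq(1, 0.1, length.out = n)
  ranked <- tibble::tibble(
    regulator = sprintf("r%03d", seq_len(n)),
    target = sprintf("t%03d", seq_len(n)),
    score = scores
  )
  positives <- ranked[hits, c("regulator", "target")]
  list(ranked = ranked, positives = positives)
}
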