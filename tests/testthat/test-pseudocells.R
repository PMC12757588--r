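test_that("bin sizes follow the remainder rule and sum to N", {
  expect_identical(pseudocell_bin_sizes(10, 3), c(4L, 3L, 3L))
  # trajectory-scale instance: 3960 cells into 80 bins
  sizes <- pseudocell_bin_sizes(3960, 80)
  expect_identical(sum(sizes == 50L), 40L)
  expect_identical(sum(sizes == 49L), 40L)
  expect_identical(sizes, sort(sizes, decreasing = TRUE)) # larger bins first
  # property sweep vs brute-force filling oracle
  for (N in c(1, 7, 80, 137)) {
    for (n in unique(c(1, 2, 3, N %/% 2, N))) {
      if (n < 1 || n > N) next
      s <- pseudocell_bin_sizes(N, n)
      expect_identical(s, oracle_bin_sizes(N, n))
      expect_identical(sum(s), as.integer(N))
      expect_lte(max(s) - min(s), 1L)
    }
  }
  expect_error(pseudocell_bin_sizes(5, 6), "cannot exceed")
  expect_error(pseudocell_bin_sizes(5, 0), "positive")
})

sim_small <- function(seed = 11, n_cells = 60, n_genes = 6) {
  withr::with_seed(seed, {
    cells <- sprintf("c%03d", seq_len(n_cells))
    pt <- stats::runif(n_cells)
    expr <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells,
      dimnames = list(sprintf("g%d", seq_len(n_genes)), cells)
    )
    access <- abs(matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells,
      dimnames = list(sprintf("g%d", seq_len(n_genes)), cells)
    ))
    list(
      expr = cell_matrix(expr, "expression"),
      access = cell_matrix(access, "accessibility"),
      ordering = cell_ordering(cells, pt)
    )
  })
}

test_that("pseudocell aggregation equals the exact member means", {
  d <- sim_small()
  pc <- make_pseudocells(d$expr, d$access, d$ordering, 7, warn_bin_size = FALSE)
  expect_identical(length(pc$bins), 7L)
  expect_setequal(unlist(pc$bins), cell_ids(d$expr))
  expect_identical(anyDuplicated(unlist(pc$bins)), 0L)
  # naive per-bin loop oracle
  for (i in seq_along(pc$bins)) {
    members <- pc$bins[[i]]
    for (g in gene_ids(d$expr)) {
      expect_equal(pc$x_p[g, i], mean(as.matrix(d$expr)[g, members]))
      expect_equal(pc$y_p[g, i], mean(as.matrix(d$access)[g, members]))
      expect_gte(pc$x_p[g, i], min(as.matrix(d$expr)[g, members]))
      expect_lte(pc$x_p[g, i], max(as.matrix(d$expr)[g, members]))
    }
  }
  expect_identical(pc$mode, "pseudotime_ordered")
})

test_that("bins are contiguous and monotone in pseudotime", {
  d <- sim_small(seed = 3, n_cells = 83)
  pc <- make_pseudocells(d$expr, d$access, d$ordering, 9, warn_bin_size = FALSE)
  pt <- stats::setNames(d$ordering$pseudotime, d$ordering$cell_id)
  for (i in seq_len(length(pc$bins) - 1)) {
    expect_lte(max(pt[pc$bins[[i]]]), min(pt[pc$bins[[i + 1]]]))
  }
})

test_that("a constant gene stays constant across pseudocells", {
  d <- sim_small()
  m <- as.matrix(d$expr)
  m["g1", ] <- 2.5
  expr <- cell_matrix(m, "expression")
  pc <- make_pseudocells(expr, NULL, d$ordering, 10, warn_bin_size = FALSE)
  expect_true(all(pc$x_p["g1", ] == 2.5))
})

test_that("N = n gives the identity partition", {
  d <- sim_small(n_cells = 12)
  pc <- make_pseudocells(d$expr, d$access, d$ordering, 12, warn_bin_size = FALSE)
  expect_true(all(lengths(pc$bins) == 1L))
  sorted <- as.matrix(d$expr)[, d$ordering$cell_id]
  expect_equal(unname(pc$x_p), unname(sorted))
})

test_that("pseudocell construction validates its inputs", {
  d <- sim_small(n_cells = 10)
  expect_error(make_pseudocells(d$expr, d$access, d$ordering, 11, warn_bin_size = FALSE), "cannot exceed")
  expect_error(make_pseudocells(d$expr, d$access, d$ordering, 0, warn_bin_size = FALSE), "positive")
  trimmed <- cell_matrix(as.matrix(d$expr)[, 1:8], "expression")
  expect_error(make_pseudocells(trimmed, d$access, d$ordering, 2, warn_bin_size = FALSE), "absent from the expression")
  expect_warning(make_pseudocells(d$expr, d$access, d$ordering, 5), "30-40 cells")
})

test_that("root cell selection ranks marker sums with stable ties", {
  m <- matrix(c(2, 3, 5, 4, 4, 5, 1, 1),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("c1", "c2", "c3", "c4"))
  )
  expr <- cell_matrix(m, "expression") # sums: 6, 8, 10, 5... recompute below
  sums <- colSums(m)
  expect_identical(select_root_cell(expr, c("m1", "m2"), 1), names(which.max(sums)))
  # tie case: sums [5, 9, 9, 2] -> rank 1 is the earlier of the tied cells
  m2 <- matrix(c(5, 9, 9, 2), 1, 4, dimnames = list("m", paste0("c", 1:4)))
  expr2 <- cell_matrix(m2, "expression")
  expect_identical(select_root_cell(expr2, "m", 1), "c2")
  expect_identical(select_root_cell(expr2, "m", 2), "c3")
  expect_identical(select_root_cell(expr2, "m", 4), "c4")
  expect_error(select_root_cell(expr2, "m", 5), "between 1 and")
  expect_error(select_root_cell(expr2, "nope", 1), "absent")
})

test_that("cluster-random pseudocells never mix clusters and are seed-deterministic", {
  d <- sim_small(seed = 9, n_cells = 24)
  labs <- stats::setNames(rep(c("A", "B"), c(10, 14)), cell_ids(d$expr))
  pc1 <- make_random_pseudocells(d$expr, d$access, labs, bin_size = 4, seed = 5)
  pc2 <- make_random_pseudocells(d$expr, d$access, labs, bin_size = 4, seed = 5)
  pc3 <- make_random_pseudocells(d$expr, d$access, labs, bin_size = 4, seed = 6)
  expect_identical(pc1$bins, pc2$bins)
  expect_false(identical(pc1$bins, pc3$bins))
  expect_identical(pc1$mode, "cluster_random")
  for (bin in pc1$bins) {
    expect_identical(length(unique(labs[bin])), 1L)
  }
  expect_setequal(unlist(pc1$bins), cell_ids(d$expr))
  # size profile: A -> ceil(10/4) = 3 bins, B -> ceil(14/4) = 4 bins
  expect_identical(length(pc1$bins), 7L)
  expect_error(
    make_random_pseudocells(d$expr, d$access, labs, bin_size = 11, seed = 1),
    "smallest cluster"
  )
})
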