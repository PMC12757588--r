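small_pc <- function(seed = 21) {
  cfg <- sim_config(
    n_genes = 8, n_regulators = 3, edge_density = 0.4, n_cells = 200,
    noise_sd = 0.02, dropout_rate = 0, seed = seed
  )
  data <- simulate_multiome(cfg)
  ordering <- cell_ordering(names(data$true_time), data$true_time)
  list(
    pc = make_pseudocells(data$expr, data$access, ordering, 20, warn_bin_size = FALSE),
    truth = data$true_network
  )
}

small_rc <- function(alpha_grid = seq(0.02, 0.4, by = 0.02), ...) {
  run_config(n_pseudocells = 20, alpha_grid = alpha_grid, n_lambda = 60, ...)
}

test_that("inferred weights live in [-1, 1] with a zero diagonal and match the alpha average", {
  d <- small_pc()
  net <- suppressWarnings(infer_network(d$pc, small_rc(), keep_alpha_networks = TRUE))
  expect_true(all(net$W >= -1 & net$W <= 1))
  expect_true(all(diag(net$W) == 0))
  # W reconstructed from the retained per-alpha signed matrices
  recon <- Reduce(`+`, lapply(net$alpha_networks, as.matrix)) / length(net$alpha_networks)
  diag(recon) <- 0
  expect_equal(unname(net$W), unname(recon), tolerance = 1e-12)
  for (A in net$alpha_networks) {
    expect_true(all(as.matrix(A) %in% c(-1, 0, 1)))
  }
})

test_that("smaller alpha yields sparser single-alpha networks", {
  d <- small_pc(seed = 33)
  net_lo <- suppressWarnings(infer_network(d$pc, small_rc(alpha_grid = 0.001)))
  net_hi <- suppressWarnings(infer_network(d$pc, small_rc(alpha_grid = 0.4)))
  expect_lte(sum(net_lo$W != 0), sum(net_hi$W != 0))
})

test_that("rna_only mode predicts expression from expression", {
  d <- small_pc(seed = 5)
  pc_no_access <- d$pc
  pc_no_access$y_p <- NULL
  expect_error(
    infer_network(pc_no_access, small_rc(mode = "multiome")),
    "requires pseudocell accessibility"
  )
  net <- suppressWarnings(infer_network(pc_no_access, small_rc(mode = "rna_only")))
  expect_identical(net$mode, "rna_only")
  expect_true(all(diag(net$W) == 0))
})

test_that("a noise-free single-regulator system puts the largest weight on the true edge", {
  cfg <- sim_config(
    n_genes = 5, n_regulators = 2, edge_density = 0.2, # 2x3 pairs -> 1 edge
    n_cells = 300, noise_sd = 0, dropout_rate = 0, lag = 0, p_inhibitory = 0, seed = 8
  )
  data <- simulate_multiome(cfg)
  expect_identical(nrow(data$true_network), 1L)
  ordering <- cell_ordering(names(data$true_time), data$true_time)
  pc <- make_pseudocells(data$expr, data$access, ordering, 30, warn_bin_size = FALSE)
  net <- suppressWarnings(infer_network(pc, small_rc()))
  tgt <- data$true_network$target[1]
  reg <- data$true_network$regulator[1]
  expect_gt(net$W[reg, tgt], 0)
  others <- setdiff(net$gene_ids, c(reg, tgt))
  expect_true(all(abs(net$W[others, tgt]) < abs(net$W[reg, tgt])))
})

test_that("degenerate targets give an all-zero column and a warning", {
  d <- small_pc(seed = 13)
  pc <- d$pc
  pc$y_p["tgt03", ] <- 1.7 # constant accessibility
  expect_warning(net <- infer_network(pc, small_rc()), "tgt03")
  expect_true(all(net$W[, "tgt03"] == 0))
})

test_that("thresholding is strict on |W| and monotone in tau", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 0.4
  W["a", "c"] <- -0.75
  W["b", "c"] <- 0.1
  net <- structure(
    list(W = W, gene_ids = letters[1:3], alpha_grid = 0.1, mode = "multiome"),
    class = "signed_network"
  )
  edges <- threshold_network(net, 0.4)
  expect_identical(nrow(edges), 1L) # 0.4 excluded by the strict inequality
  expect_identical(edges$sign, -1L)
  expect_identical(edges$regulator, "a")
  all_edges <- threshold_network(net, 0)
  expect_identical(nrow(all_edges), 3L)
  # nesting across thresholds
  for (tau_pair in list(c(0, 0.2), c(0.1, 0.5), c(0.3, 0.74))) {
    lo <- threshold_network(net, tau_pair[1])
    hi <- threshold_network(net, tau_pair[2])
    expect_true(all(
      paste(hi$regulator, hi$target) %in% paste(lo$regulator, lo$target)
    ))
  }
})

test_that("hub ranking counts outgoing edges and partitions them by sign", {
  edges <- tibble::tibble(
    regulator = c("A", "A", "B"),
    target = c("B", "C", "C"),
    weight = c(0.9, -0.8, 0.7),
    sign = c(1L, -1L, 1L)
  )
  hubs <- rank_hubs(edges)
  expect_identical(hubs$gene, c("A", "B"))
  expect_identical(hubs$out_degree, c(2L, 1L))
  expect_identical(hubs$n_activating, c(1L, 1L))
  expect_identical(hubs$n_inhibitory, c(1L, 0L))
  expect_identical(sum(hubs$out_degree), nrow(edges))
  expect_identical(nrow(rank_hubs(edges[0, ])), 0L)
  # degree conservation on random edge lists
  for (seed in 1:3) {
    e <- random_edge_list(25, seed)
    expect_identical(sum(rank_hubs(e)$out_degree), nrow(e))
  }
})

test_that("consensus keeps sign-consistent shared edges and reports conflicts", {
  n1 <- tibble::tibble(
    regulator = c("A", "C"), target = c("B", "D"),
    weight = c(0.9, -0.5), sign = c(1L, -1L)
  )
  n2 <- tibble::tibble(
    regulator = c("A", "C", "E"), target = c("B", "D", "F"),
    weight = c(0.5, 0.6, 0.9), sign = c(1L, 1L, 1L)
  )
  cons <- consensus(list(n1, n2))
  expect_identical(nrow(cons$edges), 1L) # A->B (+); C->D conflicts
  expect_identical(cons$edges$regulator, "A")
  expect_identical(nrow(cons$sign_conflicts), 1L)
  expect_identical(cons$sign_conflicts$regulator, "C")
  # idempotence, commutativity, associativity
  expect_identical(tidy(consensus(list(n1, n1)))[, c("regulator", "target")],
    n1[, c("regulator", "target")])
  ab <- tidy(consensus(list(n1, n2)))
  ba <- tidy(consensus(list(n2, n1)))
  expect_identical(ab, ba)
  n3 <- n2[1, ]
  expect_identical(
    tidy(consensus(list(n1, n2, n3))),
    tidy(consensus(list(tibble::tibble(
      regulator = ab$regulator, target = ab$target,
      weight = 1, sign = ab$sign
    ), n3)))
  )
  expect_error(consensus(list(n1)), "at least 2")
  # direction-only relaxation keeps the sign-conflicted pair
  relaxed <- consensus(list(n1, n2), require_sign_agreement = FALSE)
  expect_identical(nrow(relaxed$edges), 2L)
})
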