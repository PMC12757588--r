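#' Bin sizes for partitioning N cells into n pseudocells
#'
#' All N cells are used: the first `N %% n` bins hold `floor(N/n) + 1`
#' cells and the remaining bins hold `floor(N/n)` cells, so sizes differ by
#' at most one and the larger bins come first.
#'
#' @param n_cells Total number of cells N.
#' @param n_bins Number of bins n, with `1 <= n <= N`.
#' @return Integer vector of length `n_bins` summing to `n_cells`.
#' @export
pseudocell_bin_sizes <- function(n_cells, n_bins) {
  n_cells <- as.integer(n_cells)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be positive.", call. = FALSE)
  if (n_bins > n_cells) stop("`n_bins` cannot exceed the number of cells.", call. = FALSE)
  base <- n_cells %/% n_bins
  extra <- n_cells %% n_bins
  c(rep(base + 1L, extra), rep(base, n_bins - extra))
}

#' Select the trajectory root cell by marker expression
#'
#' Returns the cell whose summed expression over the marker genes has the
#' `rank`-th largest value; ties are broken by input cell order. Typical
#' usage picks the cell with the highest combined expression of canonical
#' stem-cell markers (e.g. Mecom + Mpl for mouse HSCs) as the root for
#' pseudotime inference.
#'
#' @param expr A [cell_matrix()] with `modality = "expression"`.
#' @param marker_genes Character vector of marker gene identifiers present
#'   in `expr`.
#' @param rank Which rank of the marker sum to return (1 = highest).
#' @return A single cell identifier.
#' @export
select_root_cell <- function(expr, marker_genes, rank = 1L) {
  stopifnot(inherits(expr, "cell_matrix"))
  missing <- setdiff(marker_genes, gene_ids(expr))
  if (length(missing)) {
    stop("Marker gene(s) absent from matrix: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n <- ncol(expr$values)
  if (rank < 1L || rank > n) {
    stop("`rank` must be between 1 and the number of cells.", call. = FALSE)
  }
  sums <- Matrix::colSums(expr$values[marker_genes, , drop = FALSE])
  ord <- order(-sums) # stable: ties keep input cell order
  cell_ids(expr)[ord[rank]]
}

new_pseudocell_set <- function(bins, x_p, y_p, mode) {
  structure(
    list(bins = bins, x_p = x_p, y_p = y_p, mode = mode),
    class = "pseudocell_set"
  )
}

#' @exportS3Method base::print
print.pseudocell_set <- function(x, ...) {
  sizes <- lengths(x$bins)
  cat(sprintf(
    "<pseudocell_set> %d bins (%d cells, sizes %d-%d), mode = %s\n",
    length(x$bins), sum(sizes), min(sizes), max(sizes), x$mode
  ))
  invisible(x)
}

aggregate_bins <- function(mat, bins) {
  out <- vapply(
    bins,
    function(members) Matrix::rowMeans(mat[, members, drop = FALSE]),
    numeric(nrow(mat))
  )
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(mat), NULL))
  colnames(out) <- paste0("pc", seq_along(bins))
  out
}

check_cells_present <- function(mat, cells, what) {
  missing <- setdiff(cells, colnames(mat$values))
  if (length(missing)) {
    stop(sprintf(
      "%d cell(s) in the ordering are absent from the %s matrix (e.g. %s).",
      length(missing), what, missing[1]
    ), call. = FALSE)
  }
}

#' Construct pseudotime-ordered pseudocells
#'
#' Cells are sorted by pseudotime and partitioned into `n` contiguous bins
#' following [pseudocell_bin_sizes()]. Pseudocell expression `x_p` and
#' accessibility `y_p` are the arithmetic means of the member cells'
#' values per gene.
#'
#' @param expr Expression [cell_matrix()].
#' @param access Accessibility [cell_matrix()], or `NULL` for RNA-only
#'   workflows.
#' @param ordering A [cell_ordering()] with pseudotime; its cells must all
#'   be present in the matrices.
#' @param n Number of pseudocells. Values yielding fewer than ~30 or more
#'   than ~40 cells per bin trigger a guidance warning, since bins of
#'   roughly 30-40 cells tend to balance noise removal against
#'   over-averaging.
#' @param warn_bin_size Emit the bin-size guidance warning (default `TRUE`).
#' @return A `pseudocell_set` with fields `bins` (list of member cell-id
#'   vectors), `x_p`, `y_p` (genes x n matrices; `y_p` is `NULL` when
#'   `access` is), and `mode = "pseudotime_ordered"`.
#' @export
make_pseudocells <- function(expr, access, ordering, n, warn_bin_size = TRUE) {
  stopifnot(inherits(expr, "cell_matrix"), inherits(ordering, "cell_ordering"))
  if (!"pseudotime" %in% names(ordering)) {
    stop("`ordering` must carry pseudotime.", call. = FALSE)
  }
  cells <- ordering$cell_id
  check_cells_present(expr, cells, "expression")
  if (!is.null(access)) {
    stopifnot(inherits(access, "cell_matrix"))
    check_cells_present(access, cells, "accessibility")
  }
  sizes <- pseudocell_bin_sizes(length(cells), n)
  if (warn_bin_size && (min(sizes) < 30 || max(sizes) > 40)) {
    warning(sprintf(
      "Bins hold %d-%d cells; around 30-40 cells per pseudocell is recommended.",
      min(sizes), max(sizes)
    ), call. = FALSE)
  }
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  bins <- Map(function(s, e) cells[s:e], idx_start, idx_end)
  x_p <- aggregate_bins(expr$values, bins)
  y_p <- if (is.null(access)) NULL else aggregate_bins(access$values, bins)
  new_pseudocell_set(bins, x_p, y_p, "pseudotime_ordered")
}

#' Construct cluster-random pseudocells (negative control)
#'
#' Within each cluster, cells are shuffled (seeded) and partitioned into
#' `ceiling(cluster_size / bin_size)` bins using the same
#' larger-bins-first remainder rule as the pseudotime mode; aggregation is
#' identical. This is the control in which pseudocells respect cell-type
#' identity but not pseudotime order.
#'
#' @inheritParams make_pseudocells
#' @param cluster_labels Named character vector or a `cluster` column on a
#'   [cell_ordering()]: one label per cell.
#' @param bin_size Target number of cells per bin.
#' @param seed Integer seed; identical seeds give identical bins.
#' @return A `pseudocell_set` with `mode = "cluster_random"`.
#' @export
make_random_pseudocells <- function(expr, access, cluster_labels, bin_size, seed) {
  stopifnot(inherits(expr, "cell_matrix"))
  if (inherits(cluster_labels, "cell_ordering")) {
    if (!"cluster" %in% names(cluster_labels)) {
      stop("Ordering carries no cluster labels.", call. = FALSE)
    }
    labs <- stats::setNames(cluster_labels$cluster, cluster_labels$cell_id)
  } else {
    labs <- cluster_labels
  }
  if (is.null(names(labs))) stop("`cluster_labels` must be named by cell_id.", call. = FALSE)
  cells <- names(labs)
  check_cells_present(expr, cells, "expression")
  if (!is.null(access)) check_cells_present(access, cells, "accessibility")
  clusters <- split(cells, labs[cells])
  clusters <- clusters[lengths(clusters) > 0]
  if (bin_size > min(lengths(clusters))) {
    stop("`bin_size` exceeds the smallest cluster size.", call. = FALSE)
  }
  bins <- withr::with_seed(seed, {
    unlist(
      lapply(clusters, function(members) {
        shuffled <- sample(members)
        sizes <- pseudocell_bin_sizes(
          length(members),
          ceiling(length(members) / bin_size)
        )
        idx_end <- cumsum(sizes)
        idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
        Map(function(s, e) shuffled[s:e], idx_start, idx_end)
      }),
      recursive = FALSE
    )
  })
  names(bins) <- NULL
  x_p <- aggregate_bins(expr$values, bins)
  y_p <- if (is.null(access)) NULL else aggregate_bins(access$values, bins)
  new_pseudocell_set(bins, x_p, y_p, "cluster_random")
}

#' Bin membership of a pseudocell set as a tibble
#'
#' @param x A `pseudocell_set`.
#' @param ... Unused.
#' @return Tibble with columns `cell_id` and `bin_index`.
#' @export
tidy.pseudocell_set <- function(x, ...) {
  tibble::tibble(
    cell_id = unlist(x$bins),
    bin_index = rep(seq_along(x$bins), lengths(x$bins))
  )
}

#' One-row summary of a pseudocell set
#'
#' @param x A `pseudocell_set`.
#' @param ... Unused.
#' @return Tibble with bin counts and size range.
#' @export
glance.pseudocell_set <- function(x, ...) {
  sizes <- lengths(x$bins)
  tibble::tibble(
    n_bins = length(x$bins),
    n_cells = sum(sizes),
    min_bin_size = min(sizes),
    max_bin_size = max(sizes),
    mode = x$mode
  )
}
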