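#' Threshold a signed network into an edge list
#'
#' Keeps entries with `|W| > tau` (strict inequality, so a weight exactly
#' equal to the threshold is excluded). Magnitude is used so that strong
#' inhibitory interactions are retained alongside activating ones.
#'
#' @param net A `signed_network` from [infer_network()], or an edge tibble
#'   with columns `regulator`, `target`, `weight`.
#' @param tau Threshold in \[0, 1\] (default 0.4).
#' @return Edge tibble (`regulator`, `target`, `weight`, `sign`) ordered by
#'   |weight| descending, then regulator, then target.
#' @export
threshold_network <- function(net, tau = 0.4) {
  stopifnot(tau >= 0, tau <= 1)
  edges <- if (inherits(net, "signed_network")) tidy(net) else as_edge_list(net)
  edges <- dplyr::filter(edges, abs(.data$weight) > tau)
  dplyr::arrange(edges, dplyr::desc(abs(.data$weight)), .data$regulator, .data$target)
}

as_edge_list <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("regulator", "target")
  if (!all(need %in% names(df))) {
    stop("Edge list needs columns `regulator` and `target`.", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  if (!"weight" %in% names(out)) out$weight <- 1
  if (!"sign" %in% names(out)) out$sign <- as.integer(sign(out$weight))
  out$sign <- as.integer(out$sign)
  if (any(out$regulator == out$target)) {
    stop("Self-edges (regulator == target) are not allowed.", call. = FALSE)
  }
  if (anyDuplicated(out[, c("regulator", "target")])) {
    stop("Duplicate (regulator, target) pairs.", call. = FALSE)
  }
  out[, c("regulator", "target", "weight", "sign")]
}

#' Rank regulators by out-degree
#'
#' Hub genes are those with the most outgoing edges in a thresholded
#' network; the activating / inhibitory split partitions the out-degree
#' when edge signs are present.
#'
#' @param edges Edge tibble (e.g. from [threshold_network()]).
#' @return Tibble (`gene`, `out_degree`, `n_activating`, `n_inhibitory`)
#'   sorted by out-degree descending, ties alphabetical.
#' @export
rank_hubs <- function(edges) {
  edges <- as_edge_list(edges)
  if (nrow(edges) == 0) {
    return(tibble::tibble(
      gene = character(), out_degree = integer(),
      n_activating = integer(), n_inhibitory = integer()
    ))
  }
  edges |>
    dplyr::group_by(gene = .data$regulator) |>
    dplyr::summarise(
      out_degree = dplyr::n(),
      n_activating = sum(.data$sign > 0),
      n_inhibitory = sum(.data$sign < 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$out_degree), .data$gene)
}

#' Consensus (intersection) of thresholded networks
#'
#' An edge belongs to the consensus when the (regulator, target) pair is
#' present in every input network with the same sign. Pairs present in all
#' inputs but with conflicting signs are excluded and reported separately.
#'
#' @param nets List of >= 2 edge tibbles.
#' @param require_sign_agreement If `FALSE`, intersect on direction only
#'   and report the first network's sign.
#' @return A list of class `consensus_network`: `edges` (tibble
#'   `regulator`, `target`, `sign`), `sign_conflicts` (same columns minus
#'   sign), `source_count`.
#' @export
consensus <- function(nets, require_sign_agreement = TRUE) {
  if (length(nets) < 2) stop("Need at least 2 networks.", call. = FALSE)
  nets <- lapply(nets, as_edge_list)
  pair_tables <- lapply(nets, function(e) e[, c("regulator", "target", "sign")])
  shared <- Reduce(
    function(a, b) dplyr::inner_join(a, b, by = c("regulator", "target")),
    lapply(pair_tables, function(e) e[, c("regulator", "target")])
  ) |> dplyr::distinct()
  signs <- lapply(pair_tables, function(e) {
    dplyr::left_join(shared, e, by = c("regulator", "target"))$sign
  })
  sign_mat <- do.call(cbind, signs)
  agree <- apply(sign_mat, 1, function(r) length(unique(r)) == 1L)
  if (!require_sign_agreement) {
    edges <- dplyr::mutate(shared, sign = sign_mat[, 1])
    conflicts <- shared[0, ]
  } else {
    edges <- dplyr::mutate(shared[agree, , drop = FALSE], sign = sign_mat[agree, 1])
    conflicts <- shared[!agree, , drop = FALSE]
  }
  structure(
    list(
      edges = dplyr::arrange(edges, .data$regulator, .data$target),
      sign_conflicts = dplyr::arrange(conflicts, .data$regulator, .data$target),
      source_count = length(nets)
    ),
    class = "consensus_network"
  )
}

#' @exportS3Method base::print
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "<consensus_network> %d conserved edges across %d networks (%d sign conflicts)\n",
    nrow(x$edges), x$source_count, nrow(x$sign_conflicts)
  ))
  invisible(x)
}

#' @export
tidy.consensus_network <- function(x, ...) x$edges

#' Write an edge list as TSV
#'
#' Columns `regulator`, `target`, `weight`, `sign`; inverse of
#' [read_edge_list()].
#'
#' @param edges Edge tibble or `signed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "signed_network")) edges <- tidy(edges)
  edges <- as_edge_list(edges)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read an edge list from TSV
#'
#' Accepts the 4-column format written by [write_edge_list()] or a minimal
#' 2-column (`regulator`, `target`) reference list, in which case weights
#' default to 1.
#'
#' @param path TSV path.
#' @return Edge tibble (`regulator`, `target`, `weight`, `sign`).
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_edge_list(df)
}
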