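#' Reference network of true-positive interactions
#'
#' Wraps a directed regulator -> target pair list (e.g. ChIP-derived
#' interactions) for benchmarking. The regulator and target universes —
#' the gene sets over which predictions are evaluable — default to the
#' genes appearing on each side of the reference.
#'
#' @param pairs Data frame with columns `regulator` and `target`.
#' @return A list of class `reference_network`: `positives` (tibble),
#'   `regulator_universe`, `target_universe`.
#' @export
reference_network <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("regulator", "target") %in% names(pairs))) {
    stop("Reference needs columns `regulator` and `target`.", call. = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)[, c("regulator", "target")]
  pairs <- dplyr::distinct(pairs)
  if (nrow(pairs) == 0) stop("Reference network is empty.", call. = FALSE)
  if (any(pairs$regulator == pairs$target)) {
    stop("Reference contains self-pairs.", call. = FALSE)
  }
  structure(
    list(
      positives = pairs,
      regulator_universe = unique(pairs$regulator),
      target_universe = unique(pairs$target)
    ),
    class = "reference_network"
  )
}

#' Restrict network predictions to the evaluable universe
#'
#' Following the usual GRN-benchmarking convention, candidate pairs are
#' restricted to regulators and targets that appear in the reference (so
#' precision is not penalized for pairs that could never be positive), and
#' self-pairs are removed. The ranking score is `|W|`: direction is kept
#' but the sign is ignored, since ChIP-style references are unsigned.
#'
#' @param net A `signed_network`, or an edge tibble with `weight`.
#' @param ref A [reference_network()].
#' @return Tibble (`regulator`, `target`, `score`) sorted by score
#'   descending; equal scores form tie groups handled atomically by
#'   [early_prc()].
#' @export
build_evaluable_predictions <- function(net, ref) {
  stopifnot(inherits(ref, "reference_network"))
  if (inherits(net, "signed_network")) {
    genes <- net$gene_ids
    regs <- intersect(genes, ref$regulator_universe)
    tgts <- intersect(genes, ref$target_universe)
    cand <- tidyr::expand_grid(regulator = regs, target = tgts)
    cand <- dplyr::filter(cand, .data$regulator != .data$target)
    if (nrow(cand)) {
      cand$score <- abs(net$W[cbind(cand$regulator, cand$target)])
    } else {
      cand$score <- numeric(0)
    }
  } else {
    edges <- as_edge_list(net)
    cand <- dplyr::filter(
      edges,
      .data$regulator %in% ref$regulator_universe,
      .data$target %in% ref$target_universe,
      .data$regulator != .data$target
    )
    cand <- dplyr::transmute(cand,
      regulator = .data$regulator, target = .data$target,
      score = abs(.data$weight)
    )
  }
  if (nrow(cand) == 0) {
    stop(sprintf(
      "No evaluable pairs: network genes overlap %d reference regulators and %d targets.",
      length(intersect(
        if (inherits(net, "signed_network")) net$gene_ids else unique(c(net$regulator, net$target)),
        ref$regulator_universe
      )),
      length(intersect(
        if (inherits(net, "signed_network")) net$gene_ids else unique(c(net$regulator, net$target)),
        ref$target_universe
      ))
    ), call. = FALSE)
  }
  dplyr::arrange(cand, dplyr::desc(.data$score), .data$regulator, .data$target)
}

#' Early precision-recall curve and its normalized area (AUEPRC)
#'
#' Walks the score-ranked candidate list threshold by threshold (all
#' candidates with equal score enter as one atomic tie group), recording
#' precision and recall after each group. Recall is computed against the
#' positives that are evaluable (present among the candidates). The area
#' is accumulated with the step convention — precision at each point times
#' the recall increment it contributes, with the final increment truncated
#' at `r_max` — and then divided by `r_max`, so a method whose early
#' predictions are all correct scores 1 regardless of `r_max`.
#'
#' @param ranked Tibble from [build_evaluable_predictions()].
#' @param positives A [reference_network()] or a data frame of positive
#'   pairs.
#' @param r_max Upper recall bound in (0, 1\] (e.g. 0.1 or 0.015 for early
#'   evaluation; 1 for the full curve).
#' @return A list of class `eprc_result`: `curve` (tibble `recall`,
#'   `precision`, `score`), `r_max`, `aueprc`, `n_positives` (evaluable
#'   positives), `n_candidates`.
#' @export
early_prc <- function(ranked, positives, r_max = 0.1) {
  stopifnot(r_max > 0, r_max <= 1)
  if (inherits(positives, "reference_network")) positives <- positives$positives
  pos_keys <- paste(positives$regulator, positives$target, sep = "\r")
  cand_keys <- paste(ranked$regulator, ranked$target, sep = "\r")
  is_pos <- cand_keys %in% pos_keys
  n_pos <- sum(is_pos)
  if (n_pos == 0) {
    stop("No reference positive appears among the evaluable candidates.", call. = FALSE)
  }
  o <- order(-ranked$score)
  scores <- ranked$score[o]
  is_pos <- is_pos[o]
  grp_last <- cumsum(rle(scores)$lengths) # last index of each tie group
  tp <- cumsum(is_pos)[grp_last]
  k <- grp_last
  recall <- tp / n_pos
  precision <- tp / k
  area <- 0
  prev_r <- 0
  for (i in seq_along(recall)) {
    if (prev_r >= r_max) break
    dr <- min(recall[i], r_max) - prev_r
    if (dr > 0) area <- area + precision[i] * dr
    prev_r <- min(recall[i], r_max)
  }
  structure(
    list(
      curve = tibble::tibble(
        recall = recall, precision = precision,
        score = scores[grp_last]
      ),
      r_max = r_max,
      aueprc = area / r_max,
      n_positives = n_pos,
      n_candidates = nrow(ranked)
    ),
    class = "eprc_result"
  )
}

#' @exportS3Method base::print
print.eprc_result <- function(x, ...) {
  cat(sprintf(
    "<eprc_result> AUEPRC = %.4f over recall [0, %g] (%d positives / %d candidates)\n",
    x$aueprc, x$r_max, x$n_positives, x$n_candidates
  ))
  invisible(x)
}

#' @export
tidy.eprc_result <- function(x, ...) x$curve

#' @export
glance.eprc_result <- function(x, ...) {
  tibble::tibble(
    aueprc = x$aueprc, r_max = x$r_max,
    n_positives = x$n_positives, n_candidates = x$n_candidates
  )
}

#' Early precision-recall curve plot
#'
#' @param object An `eprc_result`.
#' @param ... Unused.
#' @return A ggplot step plot of precision against recall over
#'   \[0, r_max\].
#' @export
autoplot.eprc_result <- function(object, ...) {
  df <- dplyr::filter(object$curve, .data$recall <= object$r_max)
  df <- dplyr::bind_rows(tibble::tibble(recall = 0, precision = 1, score = Inf), df)
  ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, object$r_max), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("AUEPRC = %.3f (recall range [0, %g])", object$aueprc, object$r_max)
    ) +
    ggplot2::theme_minimal()
}

#' Benchmark several networks against one reference
#'
#' Each network is restricted to the same evaluable universe and scored by
#' AUEPRC; networks that fail evaluation (e.g. no identifier overlap) are
#' reported with `NA` and a warning rather than aborting the others.
#'
#' @param nets Named list of `signed_network` objects or edge tibbles.
#' @param ref A [reference_network()].
#' @param r_max Recall upper bound passed to [early_prc()].
#' @return Tibble (`name`, `aueprc`, `n_positives`, `n_candidates`).
#' @export
run_benchmark <- function(nets, ref, r_max = 0.1) {
  stopifnot(length(nets) >= 1)
  if (is.null(names(nets)) || any(names(nets) == "")) {
    names(nets) <- paste0("net", seq_along(nets))
  }
  purrr::imap_dfr(nets, function(net, nm) {
    res <- tryCatch(
      {
        ranked <- build_evaluable_predictions(net, ref)
        e <- early_prc(ranked, ref, r_max)
        tibble::tibble(
          name = nm, aueprc = e$aueprc,
          n_positives = e$n_positives, n_candidates = e$n_candidates
        )
      },
      error = function(cond) {
        warning(sprintf("Network '%s' failed evaluation: %s", nm, conditionMessage(cond)),
          call. = FALSE
        )
        tibble::tibble(
          name = nm, aueprc = NA_real_,
          n_positives = NA_integer_, n_candidates = NA_integer_
        )
      }
    )
    res
  })
}
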