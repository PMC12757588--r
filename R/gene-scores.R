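#' Build per-gene accessibility windows
#'
#' The accessibility window of a gene is its gene body extended by a fixed
#' number of bases upstream of the transcription start site (TSS) on the
#' gene's strand: 5 kb by default. For a `+` strand gene the window is
#' `[max(0, start - upstream), end)`; for a `-` strand gene it is
#' `[start, end + upstream)`. Coordinates are 0-based half-open.
#'
#' @param annotations Tibble as returned by [read_annotations()].
#' @param upstream Bases upstream of the TSS to include (default 5000).
#' @return A tibble with columns `gene_id`, `chrom`, `window_start`,
#'   `window_end`, `strand`.
#' @export
build_gene_windows <- function(annotations, upstream = 5000L) {
  stopifnot(upstream >= 0)
  validate_annotations(annotations)
  dplyr::transmute(
    annotations,
    gene_id = .data$gene_id,
    chrom = .data$chrom,
    window_start = as.integer(ifelse(.data$strand == "+",
      pmax(0L, .data$start - as.integer(upstream)), .data$start
    )),
    window_end = as.integer(ifelse(.data$strand == "+",
      .data$end, .data$end + as.integer(upstream)
    )),
    strand = .data$strand
  )
}

#' Parse "chrom:start-end" peak identifiers
#'
#' @param ids Character vector of peak identifiers encoded as
#'   `chrom:start-end` with 0-based half-open coordinates.
#' @return Tibble with columns `peak_id`, `chrom`, `start`, `end`.
#' @export
parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop(
      "Unparseable peak identifier(s): ",
      paste(utils::head(ids[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    peak_id = ids,
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)),
    end = as.integer(vapply(m, `[[`, "", 4L))
  )
}

#' Compute per-gene accessibility scores from a peak matrix
#'
#' The score of gene g in cell c is the sum of counts, over all peaks whose
#' interval overlaps the gene's accessibility window, of the peak-by-cell
#' matrix. Overlap is strict half-open intersection: a peak and a window
#' overlap iff `peak.start < window.end && window.start < peak.end`. A peak
#' overlapping several gene windows contributes fully to each; genes with no
#' overlapping peak get all-zero scores. This is an unweighted simplification
#' of distance-weighted gene-activity scores such as ArchR's; a precomputed
#' accessibility matrix can be supplied to the inference step instead.
#'
#' @param peaks A [cell_matrix()] with `modality = "peaks"`. Peak coordinates
#'   are taken from `peak_coords` when given, otherwise parsed from the
#'   rownames as `chrom:start-end`.
#' @param windows Tibble from [build_gene_windows()].
#' @param peak_coords Optional tibble with columns `chrom`, `start`, `end`
#'   parallel to the peak matrix rows (0-based half-open), e.g. from a BED
#'   file read with [read_annotations()]-style conventions.
#' @param normalize If `TRUE`, scale each cell's scores to a total of
#'   10,000 (counts-per-10k); default `FALSE` (raw sums).
#' @return A [cell_matrix()] with `modality = "accessibility"`, genes in
#'   window order.
#' @export
compute_gene_scores <- function(peaks, windows, peak_coords = NULL,
                                normalize = FALSE) {
  stopifnot(inherits(peaks, "cell_matrix"))
  if (peaks$modality != "peaks") {
    stop("`peaks` must have modality 'peaks'.", call. = FALSE)
  }
  if (nrow(windows) == 0) stop("`windows` is empty.", call. = FALSE)
  if (is.null(peak_coords)) {
    peak_coords <- parse_peak_ids(rownames(peaks$values))
  }
  if (nrow(peak_coords) != nrow(peaks$values)) {
    stop("`peak_coords` rows must match peak matrix rows.", call. = FALSE)
  }
  # half-open [s, e) == 1-based closed [s + 1, e]
  peak_gr <- GenomicRanges::GRanges(
    peak_coords$chrom,
    IRanges::IRanges(start = peak_coords$start + 1L, end = peak_coords$end)
  )
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$window_start + 1L, end = windows$window_end)
  )
  # findOverlaps warns when the two sets share no chromosome; for scoring
  # that simply means zero overlap, not an error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win_gr, peak_gr))
  ind <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits),
    j = S4Vectors::subjectHits(hits),
    x = 1,
    dims = c(nrow(windows), nrow(peak_coords))
  )
  scores <- as.matrix(ind %*% peaks$values)
  dimnames(scores) <- list(windows$gene_id, colnames(peaks$values))
  if (normalize) {
    tot <- colSums(scores)
    tot[tot == 0] <- 1
    scores <- sweep(scores, 2, tot / 1e4, "/")
  }
  cell_matrix(scores, "accessibility")
}
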