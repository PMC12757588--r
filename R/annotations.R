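#' Read gene annotations from BED or GTF
#'
#' Coordinates are normalized to the 0-based half-open convention used
#' throughout the package: BED intervals pass through unchanged, GTF
#' (1-based closed) starts are decremented by one. For GTF only features
#' with `type == "gene"` are kept; genes that appear solely through other
#' feature types (e.g. exon-only records) are dropped with a warning.
#'
#' @param path Path to a BED6 or GTF file.
#' @param format `"bed"` or `"gtf"`; guessed from the extension when omitted.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @export
read_annotations <- function(path, format = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed", gtf = "gtf", gff = "gtf",
      stop("Cannot guess annotation format from extension: ", ext, call. = FALSE)
    )
  }
  format <- match.arg(format, c("bed", "gtf"))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ann <- tibble::tibble(
      gene_id = trimws(as.character(gr$name)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, # back to BED 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    meta <- S4Vectors::mcols(gr)
    types <- as.character(meta$type)
    all_ids <- trimws(as.character(meta$gene_id))
    keep <- types == "gene"
    missing_ids <- setdiff(all_ids[!keep], all_ids[keep])
    if (length(missing_ids)) {
      warning(
        "Dropping gene identifiers with no 'gene' feature: ",
        paste(missing_ids, collapse = ", "),
        call. = FALSE
      )
    }
    gr <- gr[keep]
    ann <- tibble::tibble(
      gene_id = trimws(as.character(S4Vectors::mcols(gr)$gene_id)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  if (any(!ann$strand %in% c("+", "-"))) {
    stop("Unknown strand value; only '+' and '-' are supported.", call. = FALSE)
  }
  if (any(ann$start >= ann$end)) {
    stop("Annotation with start >= end after normalization.", call. = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) {
    stop("Duplicate gene_id in annotations.", call. = FALSE)
  }
  ann
}
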