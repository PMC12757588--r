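#' Genes-by-cells matrix container
#'
#' A `cell_matrix` wraps a numeric matrix whose rows are genes and whose
#' columns are cells, together with a modality tag. Expression matrices hold
#' (normalized) transcript abundance; accessibility matrices hold per-gene
#' chromatin accessibility scores; peak matrices hold peak-by-cell counts
#' (rows are peaks rather than genes, identified as `chrom:start-end`).
#'
#' @param values Numeric matrix (base or `Matrix` sparse) with unique,
#'   non-empty rownames (gene or peak identifiers) and colnames (cell
#'   identifiers). All values must be finite; accessibility and peak values
#'   must be non-negative.
#' @param modality One of `"expression"`, `"accessibility"`, `"peaks"`.
#' @return An object of class `cell_matrix`: a list with elements `values`
#'   and `modality`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
#' cm <- cell_matrix(m, "expression")
#' dim(cm)
#' @export
cell_matrix <- function(values, modality = c("expression", "accessibility", "peaks")) {
  modality <- match.arg(modality)
  if (!(is.matrix(values) || inherits(values, "Matrix"))) {
    stop("`values` must be a base matrix or a Matrix sparse matrix.", call. = FALSE)
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("`values` must have rownames (genes) and colnames (cells).", call. = FALSE)
  }
  gene_ids <- trimws(gene_ids)
  cell_ids <- trimws(cell_ids)
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  if (anyDuplicated(gene_ids)) {
    stop("Duplicate gene/peak identifiers in rownames.", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("Duplicate cell identifiers in colnames.", call. = FALSE)
  }
  vals <- if (inherits(values, "Matrix")) values@x else values
  if (length(vals) && any(!is.finite(vals))) {
    stop("All matrix values must be finite.", call. = FALSE)
  }
  if (modality %in% c("accessibility", "peaks") && length(vals) && any(vals < 0)) {
    stop("Accessibility/peak values must be non-negative.", call. = FALSE)
  }
  structure(list(values = values, modality = modality), class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' @export
dimnames.cell_matrix <- function(x) dimnames(x$values)

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat(sprintf(
    "<cell_matrix> %d genes x %d cells, modality = %s\n",
    nrow(x$values), ncol(x$values), x$modality
  ))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.cell_matrix <- function(x, ...) as.matrix(x$values)

#' Gene and cell identifiers of a cell_matrix
#' @param x A `cell_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

#' Read a genes-by-cells matrix from disk
#'
#' Supports dense CSV/TSV (first column = gene identifiers, header row =
#' cell identifiers) and sparse MatrixMarket (`.mtx`) with companion
#' plain-text row-name and column-name files (one identifier per line).
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Guessed from the file
#'   extension when omitted.
#' @param modality Modality tag for the resulting [cell_matrix()].
#' @param row_names,col_names For `format = "mtx"`: paths to the row-name
#'   and column-name files.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(path, format = NULL,
                             modality = c("expression", "accessibility", "peaks"),
                             row_names = NULL, col_names = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
      stop("Cannot guess format from extension: ", ext, call. = FALSE)
    )
  }
  format <- match.arg(format, c("mtx", "csv", "tsv"))
  if (format == "mtx") {
    if (is.null(row_names) || is.null(col_names)) {
      stop("MTX input requires `row_names` and `col_names` files.", call. = FALSE)
    }
    m <- Matrix::readMM(path)
    rn <- trimws(readLines(row_names))
    cn <- trimws(readLines(col_names))
    if (nrow(m) != length(rn)) {
      stop(sprintf(
        "Row-name file has %d entries but matrix has %d rows.",
        length(rn), nrow(m)
      ), call. = FALSE)
    }
    if (ncol(m) != length(cn)) {
      stop(sprintf(
        "Column-name file has %d entries but matrix has %d columns.",
        length(cn), ncol(m)
      ), call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    return(cell_matrix(methods::as(m, "CsparseMatrix"), modality))
  }
  delim <- if (format == "csv") "," else "\t"
  df <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
  if (ncol(df) < 2) stop("Dense matrix file needs a gene column plus >= 1 cell column.", call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("Non-numeric values in matrix body.", call. = FALSE)
  rownames(m) <- genes
  cell_matrix(m, modality)
}

#' Write a genes-by-cells matrix as TSV
#'
#' Inverse of [read_cell_matrix()] for the dense TSV layout.
#'
#' @param x A [cell_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_matrix <- function(x, path) {
  stopifnot(inherits(x, "cell_matrix"))
  df <- tibble::as_tibble(as.matrix(x$values), rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
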