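# Lightweight containers shared by every stage of the pipeline.
#
# An ExpressionMatrix is a genes x cells (or genes x spots) sparse count
# matrix plus optional per-column annotations. A SpotGrid couples an
# ExpressionMatrix with integer array coordinates on a hex or square lattice.

#' Construct an expression matrix container
#'
#' Wraps a genes x cells (or genes x spots) count matrix together with
#' optional per-column cell-type labels and sample identifiers. Counts are
#' stored sparse; log-normalized expression is computed on demand by
#' [lognorm()].
#'
#' @param counts Numeric matrix or sparse Matrix, genes in rows, cells in
#'   columns. Must carry row and column names; entries must be non-negative.
#' @param cell_type Optional character vector of per-cell labels (length
#'   `ncol(counts)`).
#' @param sample_id Optional character vector of per-cell sample identifiers.
#' @return An object of class `ExpressionMatrix` with elements `counts`,
#'   `cell_type`, `sample_id`.
#' @export
expression_matrix <- function(counts, cell_type = NULL, sample_id = NULL) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene names in counts")
  if (min(counts@x, 0) < 0)
    stop("counts must be non-negative")
  if (!is.null(cell_type)) {
    stopifnot(length(cell_type) == ncol(counts))
    cell_type <- as.character(cell_type)
  }
  if (!is.null(sample_id)) {
    stopifnot(length(sample_id) == ncol(counts))
    sample_id <- as.character(sample_id)
  }
  structure(list(counts = counts, cell_type = cell_type,
                 sample_id = sample_id),
            class = "ExpressionMatrix")
}

as_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  m <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$counts)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$cell_type)) {
    tb <- table(x$cell_type)
    cat("cell types:", paste(sprintf("%s(%d)", names(tb), tb),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

# Accept either an ExpressionMatrix or a bare (sparse) matrix.
get_counts <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x$counts)
  if (inherits(x, "SpotGrid")) return(x$em$counts)
  as_dgc(x)
}

#' Library-size log-normalization
#'
#' Scales each column to `scale_factor` total counts and applies
#' `log1p`. The standard normalization layer used throughout the pipeline.
#'
#' @param x ExpressionMatrix, SpotGrid, or genes x cells matrix.
#' @param scale_factor Target column sum before `log1p` (default 1e4).
#' @param allow_zero If TRUE, all-zero columns are returned as zeros
#'   instead of raising an error (useful for sparse spatial spots).
#' @return Sparse genes x cells matrix of log-normalized expression.
#' @export
lognorm <- function(x, scale_factor = 1e4, allow_zero = FALSE) {
  counts <- get_counts(x)
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    if (!allow_zero) {
      bad <- colnames(counts)[which(cs == 0)]
      stop("cells with zero total counts: ", paste(utils::head(bad, 5),
                                                   collapse = ", "))
    }
    cs[cs == 0] <- 1
  }
  out <- counts %*% Matrix::Diagonal(x = scale_factor / cs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  as_dgc(out)
}

#' Counts-per-million normalization (no log)
#'
#' @param x ExpressionMatrix, SpotGrid or matrix.
#' @return Sparse matrix with columns scaled to one million counts.
#' @export
cpm <- function(x) {
  counts <- get_counts(x)
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = 1e6 / cs)
  dimnames(out) <- dimnames(counts)
  as_dgc(out)
}

#' Construct a spatial spot grid
#'
#' Couples an [expression_matrix()] of spots with integer array coordinates
#' on a hexagonal (Visium-like, 6-neighbor) or square (4-neighbor) lattice.
#'
#' @param em ExpressionMatrix with spots in columns.
#' @param coords data.frame with columns `barcode`, `row`, `col` (integer
#'   array coordinates); one row per spot, barcodes matching `colnames(em)`.
#' @param lattice `"hex"` or `"square"`.
#' @return Object of class `SpotGrid` with elements `em`, `coords`,
#'   `lattice`.
#' @export
spot_grid <- function(em, coords, lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  stopifnot(inherits(em, "ExpressionMatrix"),
            all(c("barcode", "row", "col") %in% names(coords)))
  coords <- coords[, c("barcode", "row", "col")]
  coords$barcode <- as.character(coords$barcode)
  if (!identical(sort(coords$barcode), sort(colnames(em$counts))))
    stop("coords barcodes do not match matrix columns")
  coords <- coords[match(colnames(em$counts), coords$barcode), ]
  rownames(coords) <- NULL
  if (anyDuplicated(coords[, c("row", "col")]))
    stop("duplicate spot coordinates")
  structure(list(em = em, coords = coords, lattice = lattice),
            class = "SpotGrid")
}

#' @export
print.SpotGrid <- function(x, ...) {
  cat(sprintf("SpotGrid (%s lattice): %d spots x %d genes\n",
              x$lattice, nrow(x$coords), nrow(x$em$counts)))
  invisible(x)
}

#' @export
dim.SpotGrid <- function(x) dim(x$em$counts)
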