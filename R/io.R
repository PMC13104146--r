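# Readers and writers for the plain-text interchange formats used by the
# pipeline: MTX + genes/barcodes TSV triplets, spot-coordinate TSV, GMT
# gene sets, gene-position tables and ligand-receptor pair tables.

#' Write an expression matrix as MTX + TSV triplet
#'
#' Produces `matrix.mtx`, `genes.tsv` and `barcodes.tsv` under `dir`
#' (10x-style layout). If the matrix carries cell-type or sample labels a
#' `metadata.tsv` is written as well.
#'
#' @param em ExpressionMatrix.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(em, dir) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(em$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(em$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(barcode = colnames(em$counts)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(em$cell_type) || !is.null(em$sample_id)) {
    md <- data.frame(barcode = colnames(em$counts))
    if (!is.null(em$cell_type)) md$cell_type <- em$cell_type
    if (!is.null(em$sample_id)) md$sample_id <- em$sample_id
    utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an MTX + TSV triplet written by [write_matrix_dir()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `metadata.tsv`.
#' @return ExpressionMatrix.
#' @export
read_matrix_dir <- function(dir) {
  m <- as_dgc(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes, barcodes)
  ct <- sid <- NULL
  mdf <- file.path(dir, "metadata.tsv")
  if (file.exists(mdf)) {
    md <- utils::read.table(mdf, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    md <- md[match(barcodes, md$barcode), ]
    if ("cell_type" %in% names(md)) ct <- md$cell_type
    if ("sample_id" %in% names(md)) sid <- md$sample_id
  }
  expression_matrix(m, cell_type = ct, sample_id = sid)
}

#' Write spot coordinates TSV
#'
#' Columns: `barcode`, `array_row`, `array_col` (Visium-style naming).
#'
#' @param grid SpotGrid.
#' @param path Output file.
#' @export
write_spot_coords <- function(grid, path) {
  stopifnot(inherits(grid, "SpotGrid"))
  df <- data.frame(barcode = grid$coords$barcode,
                   array_row = grid$coords$row,
                   array_col = grid$coords$col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spot grid from a matrix directory and coordinate TSV
#'
#' @param dir Matrix directory as for [read_matrix_dir()].
#' @param coords_path TSV with `barcode`, `array_row`, `array_col`.
#' @param lattice `"hex"` or `"square"`.
#' @return SpotGrid.
#' @export
read_spot_grid <- function(dir, coords_path, lattice = c("hex", "square")) {
  em <- read_matrix_dir(dir)
  co <- utils::read.table(coords_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  spot_grid(em, data.frame(barcode = co$barcode, row = co$array_row,
                           col = co$array_col), match.arg(lattice))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "cscniche") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene genomic-position table
#'
#' @param path TSV with columns `gene`, `chrom`, `start`.
#' @return data.frame with those columns (genes unique, start >= 0).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start") %in% names(df)))
  validate_gene_annotation(df[, c("gene", "chrom", "start")])
}

validate_gene_annotation <- function(ann) {
  if (anyDuplicated(ann$gene)) stop("duplicate genes in annotation")
  if (any(ann$start < 0)) stop("negative gene start positions")
  ann
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns `pathway`, `ligand`, `receptor`; multi-subunit
#' complexes are comma-joined within a field (e.g. `ITGA6,ITGB1`).
#'
#' @param path TSV file.
#' @return data.frame of class `LRDatabase` with list columns
#'   `ligand_subunits`, `receptor_subunits` and a `pair` key.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "ligand", "receptor") %in% names(df)))
  lr_database(df$pathway, df$ligand, df$receptor)
}

#' Construct a ligand-receptor database
#'
#' @param pathway Character vector of pathway names.
#' @param ligand,receptor Character vectors; complex subunits comma-joined.
#' @return data.frame of class `LRDatabase`.
#' @export
lr_database <- function(pathway, ligand, receptor) {
  stopifnot(length(pathway) == length(ligand),
            length(ligand) == length(receptor),
            all(nzchar(ligand)), all(nzchar(receptor)))
  df <- data.frame(pathway = pathway, ligand = ligand, receptor = receptor,
                   stringsAsFactors = FALSE)
  df$pair <- paste0(df$ligand, "->", df$receptor)
  if (anyDuplicated(paste(df$pathway, df$pair)))
    stop("duplicate (pathway, pair) keys")
  df$ligand_subunits <- strsplit(df$ligand, ",", fixed = TRUE)
  df$receptor_subunits <- strsplit(df$receptor, ",", fixed = TRUE)
  class(df) <- c("LRDatabase", "data.frame")
  df
}

#' Default ligand-receptor database shipped with the package
#'
#' MK-pathway (MDK to NCL, SDC1, SDC2, PTPRZ1 and the ITGA6+ITGB1 complex)
#' and SPP1-pathway (SPP1 to CD44 and the ITGAV+ITGB1 complex) pairs.
#'
#' @return `LRDatabase` data.frame.
#' @export
default_lr_database <- function() {
  path <- system.file("extdata", "lr_pairs.tsv", package = "cscniche")
  read_lr_database(path)
}

#' Default CAF-subtype marker gene sets shipped with the package
#'
#' Marker sets for six cancer-associated fibroblast subtypes (myCAF, iCAF,
#' apCAF, vCAF, mesCAF, adipoCAF). Synthetic stand-in lists built from
#' widely used subtype markers; see the package vignette.
#'
#' @return Named list of character vectors.
#' @export
default_caf_signatures <- function() {
  read_gmt(system.file("extdata", "caf_signatures_synthetic.gmt",
                       package = "cscniche"))
}

#' Write a survival table to CSV
#'
#' @param table data.frame with `subject_id`, `time`, `event`, `biomarker`
#'   and optionally `response`.
#' @param path Output CSV.
#' @export
write_survival_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival table from CSV
#'
#' @param path CSV with columns `subject_id`, `time`, `event`, `biomarker`
#'   and optionally `response`.
#' @return data.frame; times must be positive, events 0/1.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "event", "biomarker") %in% names(df)))
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event flags must be 0/1")
  df
}
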