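#' Write a synthetic cohort to plain-text files
#'
#' Events go to `events.tsv` (one row per cell), cytokines to
#' `cytokines.csv`, outcomes to `outcomes.csv`.
#'
#' @param cohort A `cohort_data` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$cytokines, file.path(dir, "cytokines.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an event table from TSV/CSV
#'
#' @param path File with one row per cell and marker columns.
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a cells x genes expression matrix
#'
#' Accepts either a MatrixMarket triple (`matrix.mtx` stored genes x
#' cells with `genes.tsv` / `barcodes.tsv` alongside, the common
#' single-cell layout) or a dense CSV with cells in rows.
#'
#' @param path Path to the `.mtx` file or the dense CSV.
#' @param genes,barcodes Optional paths to the gene / barcode lists; by
#'   default looked up next to the `.mtx` file.
#' @return Numeric matrix, cells in rows, genes in columns.
#' @export
read_expression <- function(path, genes = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    d <- dirname(path)
    if (is.null(genes)) genes <- file.path(d, "genes.tsv")
    if (is.null(barcodes)) barcodes <- file.path(d, "barcodes.tsv")
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(barcodes)
    t(m)
  } else {
    as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  }
}

#' Write an expression matrix as MatrixMarket plus gene/barcode lists
#'
#' @param x `expression_data` or cells x genes matrix.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_expression <- function(x, dir) {
  if (inherits(x, "expression_data")) x <- x$counts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(x), file.path(dir, "genes.tsv"))
  writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a gene set from a one-gene-per-line text file
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of gene names.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Serialise an elastic-net model to a structured text file
#'
#' @param model An `elastic_net_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_enet_model <- function(model, path) {
  lines <- c(
    sprintf("alpha\t%.17g", model$alpha),
    sprintf("lambda\t%.17g", model$lambda),
    sprintf("mixing\t%.17g", model$mixing),
    sprintf("seed\t%d", model$seed),
    sprintf("beta\t%s\t%.17g", names(model$beta), model$beta)
  )
  writeLines(lines, path)
  invisible(path)
}
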