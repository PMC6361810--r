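#' Read an expression count matrix
#'
#' Reads a dense delimited matrix (CSV/TSV with a header row and a row-id
#' column by default) or a Matrix-Market triplet file with companion gene
#' and barcode lists (10x-style), returning an [expression_matrix()] in the
#' internal orientation rows = cells, columns = genes regardless of the
#' on-disk orientation.
#'
#' @param path file to read. For `format = "mtx"` this is the `.mtx` file.
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @param orientation how the file is laid out: `"cells_by_genes"` (rows
#'   are cells) or `"genes_by_cells"` (rows are genes, e.g. 10x exports).
#' @param header for dense formats, whether the file has a header row and
#'   row-id column; with `header = FALSE` identifiers are auto-generated.
#' @param genes_file,barcodes_file companions for `mtx`; default to
#'   `genes.tsv` and `barcodes.tsv` next to the matrix file. Each is a
#'   one-or-more-column TSV whose first column holds the identifiers.
#' @param layer layer tag for the returned matrix (default `"counts"`).
#'
#' @return An `ExpressionMatrix`.
#' @export
read_counts <- function(path,
                        format = c("csv", "tsv", "mtx"),
                        orientation = c("cells_by_genes", "genes_by_cells"),
                        header = TRUE,
                        genes_file = NULL,
                        barcodes_file = NULL,
                        layer = "counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_mc("file not found: ", path)

  if (format == "mtx") {
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    barcodes_file <- barcodes_file %||%
      file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genes_file)) {
      stop_mc("mtx companion gene list not found: ", genes_file)
    }
    if (!file.exists(barcodes_file)) {
      stop_mc("mtx companion barcode list not found: ", barcodes_file)
    }
    M <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop_mc("failed to parse Matrix-Market file ", path, ": ",
              conditionMessage(e))
    })
    vals <- as.matrix(M)
    row_ids <- utils::read.delim(genes_file, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]]
    col_ids <- utils::read.delim(barcodes_file, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]]
    # companion convention: genes index the mtx rows under genes_by_cells,
    # the mtx columns under cells_by_genes
    if (orientation == "genes_by_cells") {
      dim_ids <- list(row_ids, col_ids)
    } else {
      dim_ids <- list(col_ids, row_ids)
    }
    if (length(dim_ids[[1]]) != nrow(vals) ||
        length(dim_ids[[2]]) != ncol(vals)) {
      stop_mc("companion id lists do not match matrix dimensions (",
              nrow(vals), " x ", ncol(vals), ")")
    }
    dimnames(vals) <- dim_ids
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = header,
                        row.names = if (header) 1L else NULL,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) {
        stop_mc("failed to parse ", format, " file ", path, ": ",
                conditionMessage(e))
      })
    vals <- as.matrix(df)
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))) &
                     !is.na(vals))[1]
      stop_mc("non-numeric entry in ", path,
              if (!is.na(bad)) paste0(" (value '", vals[bad], "')"))
    }
  }

  if (orientation == "genes_by_cells") vals <- t(vals)
  expression_matrix(vals, layer = layer)
}

#' Read cell labels
#'
#' Two-column delimited file (cell_id, group), or a single column of group
#' names aligned positionally to the matrix row order. No header.
#'
#' @param path file to read.
#' @param sep field separator (default tab).
#' @return A [cell_labels()] object.
#' @export
read_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_mc("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) {
      stop_mc("failed to parse label file ", path, ": ",
              conditionMessage(e))
    })
  if (nrow(df) == 0) stop_mc("empty label file: ", path)
  if (ncol(df) >= 2) {
    cell_labels(df[[2]], cell_id = df[[1]])
  } else {
    cell_labels(df[[1]])
  }
}

#' Write an expression matrix
#'
#' Dense CSV/TSV is written with the cell ids as a row-id column and gene
#' ids as header, at full double precision, so a read/write round trip is
#' exact to ~1e-15 relative. MTX is written as a Matrix-Market coordinate
#' file (exact for integer counts) with `genes.tsv` / `barcodes.tsv`
#' companions next to it.
#'
#' @param E an `ExpressionMatrix`.
#' @param path output file.
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @param orientation on-disk layout to write (default `cells_by_genes`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(E, path,
                         format = c("csv", "tsv", "mtx"),
                         orientation = c("cells_by_genes",
                                         "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  stopifnot(is_expression_matrix(E))
  if (nrow(E$values) == 0 || ncol(E$values) == 0) {
    stop_mc("refusing to write an empty (0-cell or 0-gene) matrix")
  }
  vals <- E$values
  if (orientation == "genes_by_cells") vals <- t(vals)

  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                "generalMatrix"), file = path)
    # companions: genes index the non-cell axis
    if (orientation == "genes_by_cells") {
      gene_col <- rownames(vals); cell_col <- colnames(vals)
    } else {
      gene_col <- colnames(vals); cell_col <- rownames(vals)
    }
    writeLines(gene_col, file.path(dirname(path), "genes.tsv"))
    writeLines(cell_col, file.path(dirname(path), "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    con <- tryCatch(file(path, "w"), error = function(e) {
      stop_mc("cannot open ", path, " for writing: ", conditionMessage(e))
    })
    on.exit(close(con))
    writeLines(paste(c("", colnames(vals)), collapse = sep), con)
    body <- apply(vals, 1, function(r) {
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = sep)
    })
    writeLines(paste(rownames(vals), body, sep = sep), con)
  }
  invisible(path)
}
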