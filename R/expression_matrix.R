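#' Expression matrix container
#'
#' Light container for a single-cell expression matrix with the orientation
#' fixed to rows = cells, columns = genes. The `layer` tag records where the
#' values sit in the preprocessing pipeline: raw `counts`, library-size
#' `normalized`, or `log` (log2 of normalized values plus a pseudo-count).
#' All layers are non-negative; log2(x + 1) >= 0 whenever x >= 0.
#'
#' @param values numeric matrix, m cells x n genes, all entries >= 0 and
#'   finite.
#' @param cell_ids character vector of m unique cell identifiers; defaults
#'   to `rownames(values)` or `cell1..cellm`.
#' @param gene_ids character vector of n unique gene identifiers; defaults
#'   to `colnames(values)` or `gene1..genen`.
#' @param layer one of `"counts"`, `"normalized"`, `"log"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, carrying the ids as dimnames), `layer`, and,
#'   after [library_size_normalize()], the recorded `norm_totals` and
#'   `norm_median` needed to undo normalization.
#' @export
#' @examples
#' E <- expression_matrix(matrix(0:5, 2, 3), layer = "counts")
#' dim(E)
expression_matrix <- function(values,
                              cell_ids = NULL,
                              gene_ids = NULL,
                              layer = c("counts", "normalized", "log")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_mc("expression values must be numeric")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop_mc("expression values must be finite and non-missing")
  }
  if (any(values < 0)) {
    stop_mc("expression values must be non-negative; found ",
            sum(values < 0), " negative entries")
  }
  m <- nrow(values)
  n <- ncol(values)
  make_ids <- function(prefix, k) {
    if (k > 0) paste0(prefix, seq_len(k)) else character(0)
  }
  cell_ids <- as.character(cell_ids %||% rownames(values) %||%
                             make_ids("cell", m))
  gene_ids <- as.character(gene_ids %||% colnames(values) %||%
                             make_ids("gene", n))
  if (length(cell_ids) != m) {
    stop_mc("length(cell_ids) (", length(cell_ids),
            ") does not match number of rows (", m, ")")
  }
  if (length(gene_ids) != n) {
    stop_mc("length(gene_ids) (", length(gene_ids),
            ") does not match number of columns (", n, ")")
  }
  if (anyDuplicated(cell_ids)) stop_mc("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop_mc("duplicate gene identifiers")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Cell identifiers of an expression matrix
#' @param E an `ExpressionMatrix`
#' @return character vector
#' @export
cell_ids <- function(E) rownames(E$values)

#' Gene identifiers of an expression matrix
#' @param E an `ExpressionMatrix`
#' @return character vector
#' @export
gene_ids <- function(E) colnames(E$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d cells x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  cat(sprintf("  zeros: %.1f%%  range: [%.4g, %.4g]\n",
              100 * mean(x$values == 0), min(x$values), max(x$values)))
  invisible(x)
}

# Replace values (and optionally layer) keeping ids and extra fields.
em_with_values <- function(E, values, layer = E$layer) {
  out <- E
  dimnames(values) <- dimnames(E$values)
  out$values <- values
  out$layer <- layer
  out
}

#' Cell-label container
#'
#' Group annotations for the cells of an expression matrix, used by the
#' separability, clustering and differential-expression evaluations.
#'
#' @param labels character vector of group names. If `cell_id` is `NULL`
#'   the labels are positional (aligned to the matrix row order).
#' @param cell_id optional character vector of cell identifiers, same
#'   length as `labels`.
#' @return An object of class `CellLabels` with fields `cell_id` (or
#'   `NULL`), `labels`, and `groups` (distinct names in first-appearance
#'   order).
#' @export
cell_labels <- function(labels, cell_id = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop_mc("no labels given")
  if (!is.null(cell_id)) {
    cell_id <- as.character(cell_id)
    if (length(cell_id) != length(labels)) {
      stop_mc("cell_id and labels must have the same length")
    }
    if (anyDuplicated(cell_id)) {
      stop_mc("duplicate cell_id in labels: ",
              paste(unique(cell_id[duplicated(cell_id)]), collapse = ", "))
    }
  }
  structure(list(cell_id = cell_id, labels = labels,
                 groups = unique(labels)),
            class = "CellLabels")
}

#' @export
print.CellLabels <- function(x, ...) {
  cat(sprintf("<CellLabels> %d cells, %d groups: %s\n",
              length(x$labels), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

# Align labels to the rows of E; returns a character vector of length m.
# Accepts CellLabels (id-bound or positional) or a bare vector.
align_labels <- function(E, labels) {
  if (inherits(labels, "CellLabels")) {
    if (!is.null(labels$cell_id)) {
      unknown <- setdiff(labels$cell_id, cell_ids(E))
      if (length(unknown) > 0) {
        stop_mc("labels refer to unknown cell ids: ",
                paste(utils::head(unknown, 5), collapse = ", "))
      }
      missing <- setdiff(cell_ids(E), labels$cell_id)
      if (length(missing) > 0) {
        stop_mc("cells without a label: ",
                paste(utils::head(missing, 5), collapse = ", "))
      }
      return(labels$labels[match(cell_ids(E), labels$cell_id)])
    }
    labels <- labels$labels
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(E$values)) {
    stop_mc("labels length (", length(labels),
            ") does not match number of cells (", nrow(E$values), ")")
  }
  labels
}
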