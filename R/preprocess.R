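#' Filter lowly expressed genes
#'
#' A gene is considered expressed, and kept, when at least `min_cells`
#' cells carry at least `min_reads` reads of it. Cells and gene order are
#' untouched. Filtering is idempotent.
#'
#' @param E `ExpressionMatrix` on the counts layer.
#' @param min_reads minimum reads for a cell to count as detecting the
#'   gene (default 3).
#' @param min_cells minimum number of detecting cells (default 3).
#' @return Filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(E, min_reads = 3, min_cells = 3) {
  stopifnot(is_expression_matrix(E))
  if (E$layer != "counts") {
    stop_mc("filter_genes expects the counts layer, got '", E$layer, "'")
  }
  keep <- colSums(E$values >= min_reads) >= min_cells
  if (!any(keep)) {
    stop_mc("no genes pass the filter (>=", min_reads, " reads in >=",
            min_cells, " cells); lower min_reads/min_cells or skip ",
            "filtering")
  }
  out <- E
  out$values <- E$values[, keep, drop = FALSE]
  out
}

#' Library-size normalization
#'
#' Divides each cell's counts by the cell's total and multiplies by the
#' median of the totals across cells, so every cell's normalized total
#' equals that median. The per-cell totals and the median are recorded on
#' the result so that [denormalize()] can invert the map exactly.
#'
#' @param E `ExpressionMatrix` on the counts layer.
#' @return `ExpressionMatrix` on the normalized layer with fields
#'   `norm_totals` and `norm_median`.
#' @export
library_size_normalize <- function(E) {
  stopifnot(is_expression_matrix(E))
  if (E$layer != "counts") {
    stop_mc("library_size_normalize expects the counts layer, got '",
            E$layer, "'")
  }
  totals <- rowSums(E$values)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    stop_mc("cells with zero total counts: ",
            paste(utils::head(cell_ids(E)[zero], 5), collapse = ", "))
  }
  med <- stats::median(totals)
  out <- em_with_values(E, E$values / totals * med, layer = "normalized")
  out$norm_totals <- stats::setNames(totals, cell_ids(E))
  out$norm_median <- med
  out
}

#' Log2 transform with pseudo-count
#'
#' `out = log2(in + pseudocount)`; with the default pseudo-count of 1 the
#' transform maps 0 to 0 and is exactly inverted by
#' [inverse_log_transform()].
#'
#' @param E `ExpressionMatrix` on the counts or normalized layer.
#' @param pseudocount positive offset added before taking logs (default 1).
#' @return `ExpressionMatrix` on the log layer.
#' @export
log_transform <- function(E, pseudocount = 1) {
  stopifnot(is_expression_matrix(E))
  if (pseudocount <= 0) stop_mc("pseudocount must be > 0")
  if (E$layer == "log") {
    stop_mc("matrix is already on the log layer")
  }
  out <- em_with_values(E, log2(E$values + pseudocount), layer = "log")
  out$pseudocount <- pseudocount
  out
}

#' Invert the log2 transform
#'
#' `out = 2^in - pseudocount`, clipped at zero. Exact inverse of
#' [log_transform()] up to floating point.
#'
#' @param E `ExpressionMatrix` on the log layer.
#' @param pseudocount the pseudo-count used in the forward transform;
#'   defaults to the one recorded on `E`, else 1.
#' @return `ExpressionMatrix` on the normalized layer.
#' @export
inverse_log_transform <- function(E, pseudocount = NULL) {
  stopifnot(is_expression_matrix(E))
  if (E$layer != "log") {
    stop_mc("inverse_log_transform expects the log layer, got '",
            E$layer, "'")
  }
  pseudocount <- pseudocount %||% E$pseudocount %||% 1
  out <- em_with_values(E, pmax(2^E$values - pseudocount, 0),
                        layer = "normalized")
  out$pseudocount <- NULL
  out
}

#' Undo library-size normalization
#'
#' `out[c, g] = E[c, g] * total(c) / median`, using the per-cell totals
#' and median recorded at forward time (or supplied explicitly). Values
#' are left fractional: rounding would destroy small imputed values near
#' the 0.5 zero-threshold used by the dropout analysis.
#'
#' @param E `ExpressionMatrix` on the normalized layer.
#' @param original_totals per-cell totals recorded during normalization;
#'   defaults to `E$norm_totals`.
#' @param original_median median of the original totals; defaults to
#'   `E$norm_median`.
#' @return `ExpressionMatrix` on the counts layer (fractional).
#' @export
denormalize <- function(E, original_totals = NULL, original_median = NULL) {
  stopifnot(is_expression_matrix(E))
  if (E$layer != "normalized") {
    stop_mc("denormalize expects the normalized layer, got '",
            E$layer, "'")
  }
  totals <- original_totals %||% E$norm_totals
  med <- original_median %||% E$norm_median
  if (is.null(totals) || is.null(med)) {
    stop_mc("no stored normalization totals; pass original_totals and ",
            "original_median")
  }
  if (length(totals) != nrow(E$values)) {
    stop_mc("original_totals length does not match number of cells")
  }
  if (med == 0) stop_mc("original_median must be non-zero")
  out <- em_with_values(E, E$values * as.numeric(totals) / med,
                        layer = "counts")
  out$norm_totals <- NULL
  out$norm_median <- NULL
  out
}
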