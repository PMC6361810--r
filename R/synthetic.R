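#' Generate a non-negative low-rank matrix
#'
#' `X = |G1| %*% |G2|` with `G1` (m x r) and `G2` (r x n) standard-normal
#' draws, elementwise absolute value taken before the product: the result
#' is non-negative with rank (generically exactly) `r`.
#'
#' @param m,n dimensions.
#' @param r planted rank, `<= min(m, n)`.
#' @param seed RNG seed.
#' @return `ExpressionMatrix` (normalized layer; values are continuous).
#' @export
generate_lowrank <- function(m, n, r, seed = 1) {
  if (r < 1 || r > min(m, n)) {
    stop_mc("r must be in [1, min(m, n)]")
  }
  vals <- local_seed(seed, {
    abs(matrix(stats::rnorm(m * r), m, r)) %*%
      abs(matrix(stats::rnorm(r * n), r, n))
  })
  expression_matrix(vals, layer = "normalized")
}

#' Generate clustered scRNA-seq-like data with dropout
#'
#' Builds `k_clusters` cluster-specific low-rank blocks: the cells of
#' cluster c get expression `|U_c| %*% |V_c|` with independent factor
#' draws per cluster, so clusters differ in their mean profiles while the
#' stacked matrix has rank exactly `r` (the per-cluster ranks partition
#' `r`). The matrix is scaled so the mean per-cell total equals `depth`.
#' Structural zeros (a gene silent in an entire cluster) are planted by
#' zeroing factor columns, which keeps the truth exactly low-rank. The
#' observed layer rounds the truth to integer counts and then applies
#' dropout independently per entry with probability
#' `exp(-dropout_strength * x^2)` where `x = log2(1 + value)` — the
#' double-exponential decay convention: lowly expressed genes are hit
#' hardest, high expression is essentially never dropped.
#'
#' @param m_cells,n_genes dimensions (defaults 500 x 300, a desk-scale
#'   dataset).
#' @param k_clusters number of cell groups (default 3).
#' @param r planted rank of the complete matrix, `>= k_clusters`
#'   (default 6).
#' @param dropout_strength decay rate of dropout probability in squared
#'   log-expression; 0 disables dropout. Default 0.2, a moderate regime
#'   (roughly a third of positive counts dropped at the default depth).
#' @param structural_zero_frac probability that a (gene, cluster) pair is
#'   silenced (default 0.05).
#' @param depth target mean total count per cell (default 3000).
#' @param seed RNG seed.
#' @return List of class `SyntheticTruth`:
#'   `truth` (complete continuous `ExpressionMatrix`, exactly rank `r`),
#'   `observed` (integer counts with dropouts zeroed, counts layer),
#'   `dropout_mask` (1 where a positive count was dropped),
#'   `structural_zero_mask` (1 where the truth is a planted zero),
#'   `labels` (`CellLabels` of cluster memberships),
#'   `planted_rank`.
#' @export
generate_scrnaseq <- function(m_cells = 500, n_genes = 300,
                              k_clusters = 3, r = 6,
                              dropout_strength = 0.2,
                              structural_zero_frac = 0.05,
                              depth = 3000, seed = 1) {
  if (k_clusters > m_cells) stop_mc("k_clusters exceeds m_cells")
  if (r < k_clusters) stop_mc("r must be >= k_clusters (each cluster ",
                              "block needs rank >= 1)")
  if (r > min(m_cells, n_genes)) stop_mc("r exceeds min(m_cells, n_genes)")
  if (dropout_strength < 0) stop_mc("dropout_strength must be >= 0")
  if (structural_zero_frac < 0 || structural_zero_frac >= 1) {
    stop_mc("structural_zero_frac must be in [0, 1)")
  }
  local_seed(seed, {
    cluster_of <- sort(rep_len(seq_len(k_clusters), m_cells))
    rks <- rep(r %/% k_clusters, k_clusters) +
      (seq_len(k_clusters) <= r %% k_clusters)
    X <- matrix(0, m_cells, n_genes)
    struct <- matrix(0, m_cells, n_genes)
    for (c in seq_len(k_clusters)) {
      cells <- which(cluster_of == c)
      rc <- rks[c]
      U <- abs(matrix(stats::rnorm(length(cells) * rc), ncol = rc))
      V <- abs(matrix(stats::rnorm(rc * n_genes), nrow = rc))
      silent <- which(stats::runif(n_genes) < structural_zero_frac)
      V[, silent] <- 0
      X[cells, ] <- U %*% V
      struct[cells, silent] <- 1
    }
    X <- X * depth / mean(rowSums(X))
    # library-size floor, emulating cell QC: no cell sits below 5% of the
    # target depth (row rescaling preserves the planted rank)
    totals <- rowSums(X)
    low <- which(totals < 0.05 * depth)
    if (length(low) > 0) {
      X[low, ] <- X[low, , drop = FALSE] * (0.05 * depth / totals[low])
    }
    counts_complete <- round(X)
    logx <- log2(1 + X)
    p_drop <- exp(-dropout_strength * logx^2)
    hit <- matrix(stats::runif(m_cells * n_genes), m_cells, n_genes) <
      p_drop
    dropout <- (hit & counts_complete > 0 & struct == 0 &
                  dropout_strength > 0) * 1
    observed <- counts_complete
    observed[dropout == 1] <- 0
    # emulate QC'd data with no bad cells: a cell emptied entirely by
    # dropout gets its largest original count back
    empty <- which(rowSums(observed) == 0)
    for (i in empty) {
      j <- which.max(counts_complete[i, ])
      observed[i, j] <- counts_complete[i, j]
      dropout[i, j] <- 0
    }
    labels <- cell_labels(paste0("cluster", cluster_of))
    structure(list(truth = expression_matrix(X, layer = "normalized"),
                   observed = expression_matrix(observed,
                                                layer = "counts"),
                   dropout_mask = dropout,
                   structural_zero_mask = struct,
                   labels = labels,
                   planted_rank = as.integer(sum(rks))),
              class = "SyntheticTruth")
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "<SyntheticTruth> %d cells x %d genes, %d clusters, rank %d\n",
    nrow(x$truth$values), ncol(x$truth$values),
    length(x$labels$groups), x$planted_rank))
  cat(sprintf("  dropouts: %d (%.1f%% of positive counts)  structural zeros: %d\n",
              sum(x$dropout_mask),
              100 * sum(x$dropout_mask) /
                max(1, sum(round(x$truth$values) > 0)),
              sum(x$structural_zero_mask)))
  invisible(x)
}
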