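#' Randomly mask entries of a matrix
#'
#' Sub-samples a complete matrix to mimic dropout: exactly
#' `round(sampling_ratio * m * n)` entries are kept as observed, the rest
#' are zeroed and marked held-out. Reproducible by seed.
#'
#' @param X `ExpressionMatrix` or numeric matrix (the complete truth).
#' @param sampling_ratio fraction of entries kept, in (0, 1).
#' @param seed RNG seed.
#' @return List with `Y` (masked copy of `X`), `mask` (1 = observed) and
#'   `heldout` (1 = removed; the complement).
#' @export
mask_at_random <- function(X, sampling_ratio, seed = 1) {
  if (!is.numeric(sampling_ratio) || sampling_ratio <= 0 ||
      sampling_ratio >= 1) {
    stop_mc("sampling_ratio must be in (0, 1)")
  }
  vals <- as_values(X)
  m <- nrow(vals); n <- ncol(vals)
  n_keep <- round(sampling_ratio * m * n)
  keep <- local_seed(seed, sample.int(m * n, n_keep))
  mask <- matrix(0, m, n)
  mask[keep] <- 1
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) {
    warn_mc("some rows or columns have no observed entries after masking")
  }
  Yv <- vals * mask
  Y <- if (is_expression_matrix(X)) em_with_values(X, Yv) else Yv
  list(Y = Y, mask = mask, heldout = 1 - mask)
}

#' Recovery error on held-out entries
#'
#' Over the held-out positions only: `rmse = sqrt(mean((t - e)^2))`,
#' `mae = mean(|t - e|)`, and `nmse = sum((t - e)^2) / sum(t^2)`
#' (Frobenius-normalized, the matrix-completion convention).
#'
#' @param X_true,X_est complete truth and estimate, same shape.
#' @param heldout binary mask, 1 at held-out positions.
#' @return List of class `RecoveryMetrics`: `nmse`, `rmse`, `mae`,
#'   `n_heldout`.
#' @export
recovery_metrics <- function(X_true, X_est, heldout) {
  t <- as_values(X_true); e <- as_values(X_est)
  stopifnot(all(dim(t) == dim(e)), all(dim(heldout) == dim(t)))
  idx <- which(heldout != 0)
  if (length(idx) == 0) stop_mc("held-out set is empty")
  tv <- t[idx]; ev <- e[idx]
  if (sum(tv^2) == 0) {
    stop_mc("all held-out truths are zero; NMSE is undefined")
  }
  structure(list(nmse = sum((tv - ev)^2) / sum(tv^2),
                 rmse = sqrt(mean((tv - ev)^2)),
                 mae = mean(abs(tv - ev)),
                 n_heldout = length(idx)),
            class = "RecoveryMetrics")
}

#' Cell-type separability score
#'
#' For two cell groups: the intra-group scatter of a group is the median
#' Spearman correlation over all pairs of cells within it; the
#' inter-group scatter is the median Spearman correlation over all
#' cross-group pairs. The separability score is the average of the two
#' intra-group scatters minus the inter-group scatter. A higher score
#' means cells of the same type resemble each other more than cells of
#' different types.
#'
#' @param E `ExpressionMatrix`, log layer recommended for rank stability.
#' @param labels `CellLabels` or character vector aligned to cells.
#' @param groupA,groupB names of the two groups to compare.
#' @return List of class `CTSResult`: `intra_scatter` (named per-group
#'   medians), `intra_mean`, `inter_scatter`, `cts`.
#' @export
cts_score <- function(E, labels, groupA, groupB) {
  stopifnot(is_expression_matrix(E))
  lab <- align_labels(E, labels)
  ia <- which(lab == groupA)
  ib <- which(lab == groupB)
  if (length(ia) < 2 || length(ib) < 2) {
    stop_mc("both groups need at least 2 cells (", groupA, ": ",
            length(ia), ", ", groupB, ": ", length(ib), ")")
  }
  cells <- c(ia, ib)
  expr <- t(E$values[cells, , drop = FALSE])
  const <- apply(expr, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warn_mc(sum(const), " constant cell vector(s); their pairs are ",
            "excluded (Spearman undefined)")
  }
  cmat <- suppressWarnings(stats::cor(expr, method = "spearman"))
  na <- length(ia); nb <- length(ib)
  A <- seq_len(na); B <- na + seq_len(nb)
  pair_vals <- function(rows, cols, same) {
    v <- cmat[rows, cols, drop = FALSE]
    if (same) v <- v[upper.tri(v)]
    stats::median(v[!is.na(v)])
  }
  intra <- c(pair_vals(A, A, TRUE), pair_vals(B, B, TRUE))
  names(intra) <- c(groupA, groupB)
  inter <- pair_vals(A, B, FALSE)
  structure(list(intra_scatter = intra,
                 intra_mean = mean(intra),
                 inter_scatter = inter,
                 cts = mean(intra) - inter),
            class = "CTSResult")
}

#' @export
print.CTSResult <- function(x, ...) {
  cat(sprintf("<CTSResult> intra = (%s), inter = %.4f, cts = %.4f\n",
              paste(sprintf("%s: %.4f", names(x$intra_scatter),
                            x$intra_scatter), collapse = ", "),
              x$inter_scatter, x$cts))
  invisible(x)
}

#' Clustering agreement under repeated k-means
#'
#' Projects cells onto the top principal components (genes mean-centered,
#' unscaled, exact SVD-based PCA), runs k-means `n_runs` times with
#' random initial centroids (the run-to-run variability source), and
#' returns the adjusted Rand index of each run against the annotated
#' labels.
#'
#' @param E `ExpressionMatrix`, log layer recommended.
#' @param labels `CellLabels` or character vector.
#' @param k number of clusters; defaults to the number of annotated
#'   groups.
#' @param n_runs number of k-means restarts (default 100).
#' @param n_pcs number of principal components (default 2).
#' @param seed master seed; per-run seeds are derived from it.
#' @return Numeric vector of `n_runs` ARI values.
#' @export
clustering_ari <- function(E, labels, k = NULL, n_runs = 100, n_pcs = 2,
                           seed = 1) {
  stopifnot(is_expression_matrix(E))
  lab <- align_labels(E, labels)
  k <- k %||% length(unique(lab))
  if (k < 2) stop_mc("k must be >= 2")
  if (k > nrow(E$values)) stop_mc("k exceeds the number of cells")
  pcs <- stats::prcomp(E$values, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  vapply(seq_len(n_runs), function(run) {
    cl <- local_seed(seed + run - 1L,
                     stats::kmeans(pcs, centers = k, nstart = 1,
                                   iter.max = 50)$cluster)
    mclust::adjustedRandIndex(cl, lab)
  }, numeric(1))
}

#' Zero fraction by bulk-expression bin
#'
#' Bins genes by a matched bulk reference: bin 1 holds genes whose bulk
#' value is exactly 0; the remaining bins are equal-width over
#' `(0, max_expression]`; genes above `max_expression` are excluded. For
#' each bin the fraction of single-cell matrix entries (that bin's genes
#' across all cells) below `zero_threshold` is reported — values in
#' [0, 0.5) count as (imputed) zeros, giving all methods minor
#' flexibility. In a well-imputed matrix the zero fraction should stay
#' near 1 in bin 1 (true zeros kept) and fall in higher bins (dropouts
#' recovered).
#'
#' @param single `ExpressionMatrix` on the counts scale (raw or imputed).
#' @param bulk_reference numeric vector of per-gene bulk expression,
#'   aligned to `gene_ids(single)` (names are matched when present).
#' @param n_bins number of bins (default 10, bin 1 = zero-expression).
#' @param zero_threshold values below this count as zero (default 0.5).
#' @param max_expression upper end of the binned range (default 500).
#' @return Data frame with `bin`, `lower`, `upper`, `n_genes`,
#'   `zero_fraction` (`NA` for empty bins).
#' @export
zero_fraction_by_bins <- function(single, bulk_reference, n_bins = 10,
                                  zero_threshold = 0.5,
                                  max_expression = 500) {
  stopifnot(is_expression_matrix(single))
  bulk <- bulk_reference
  if (!is.null(names(bulk))) {
    missing <- setdiff(gene_ids(single), names(bulk))
    if (length(missing) > 0) {
      stop_mc("bulk reference missing genes: ",
              paste(utils::head(missing, 5), collapse = ", "))
    }
    bulk <- bulk[gene_ids(single)]
  }
  if (length(bulk) != ncol(single$values)) {
    stop_mc("bulk reference length does not match number of genes")
  }
  breaks <- seq(0, max_expression, length.out = n_bins)
  # bin 1: exact zeros; bins 2..n_bins: (breaks[j-1], breaks[j]]
  bin <- rep(NA_integer_, length(bulk))
  bin[bulk == 0] <- 1L
  inside <- bulk > 0 & bulk <= max_expression
  bin[inside] <- 1L + findInterval(bulk[inside], breaks, left.open = TRUE,
                                   rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = c(0, breaks[-n_bins]),
                    upper = c(0, breaks[-1]),
                    n_genes = 0L, zero_fraction = NA_real_)
  for (j in seq_len(n_bins)) {
    g <- which(bin == j)
    out$n_genes[j] <- length(g)
    if (length(g) > 0) {
      vals <- single$values[, g, drop = FALSE]
      out$zero_fraction[j] <- mean(vals < zero_threshold)
    }
  }
  out
}

#' Coefficient of variation versus mean, per gene
#'
#' For each gene computes the mean and the coefficient of variation
#' (sd/mean) across cells. Under pure Poisson sampling noise
#' `CV = mean^(-1/2)`, i.e. `log10 CV = -0.5 * log10 mean` — the
#' reference line returned alongside the points. Genes with zero mean or
#' zero CV are excluded (logged via message).
#'
#' @param E `ExpressionMatrix`, normalized layer recommended.
#' @return List with `points` (data frame: gene, mean, cv, log10_mean,
#'   log10_cv), `fit` (intercept/slope of the least-squares line through
#'   the points) and `reference` (intercept 0, slope -0.5).
#' @export
cv_mean_relation <- function(E) {
  stopifnot(is_expression_matrix(E))
  mu <- colMeans(E$values)
  sdv <- apply(E$values, 2, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  keep <- !is.na(cv) & cv > 0 & mu > 0
  if (any(!keep)) {
    message(sum(!keep), " gene(s) excluded (zero mean or zero CV)")
  }
  pts <- data.frame(gene = gene_ids(E)[keep],
                    mean = mu[keep], cv = cv[keep],
                    log10_mean = log10(mu[keep]),
                    log10_cv = log10(cv[keep]),
                    row.names = NULL)
  fit <- stats::coef(stats::lm(log10_cv ~ log10_mean, data = pts))
  list(points = pts,
       fit = c(intercept = unname(fit[1]), slope = unname(fit[2])),
       reference = c(intercept = 0, slope = -0.5))
}

#' Average silhouette on a 2-D embedding
#'
#' Standard silhouette with Euclidean distance on a caller-supplied
#' low-dimensional embedding (e.g. from t-SNE or PCA); returns the mean
#' over cells. Cells in singleton groups get silhouette 0 (warned).
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param labels `CellLabels` or character vector of group names.
#' @return Mean silhouette width (scalar).
#' @export
silhouette_on_embedding <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  if (inherits(labels, "CellLabels")) labels <- labels$labels
  labels <- as.character(labels)
  if (length(labels) != nrow(embedding)) {
    stop_mc("labels length does not match number of embedded points")
  }
  if (length(unique(labels)) < 2) stop_mc("need at least 2 groups")
  if (any(table(labels) == 1)) {
    warn_mc("singleton group(s); their cells' silhouette is 0")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum p-value per gene between two cell groups, with the
#' exact distribution at small sample sizes and the tie-corrected normal
#' approximation otherwise (the standard `wilcox.test` behavior). Genes
#' are ranked by p-value.
#'
#' @param E `ExpressionMatrix`, log layer recommended.
#' @param labels `CellLabels` or character vector.
#' @param groupA,groupB group names to contrast.
#' @return Data frame with `gene`, `p_value`, `rank` (1 = most
#'   significant; ties broken by gene order).
#' @export
wilcoxon_de <- function(E, labels, groupA, groupB) {
  stopifnot(is_expression_matrix(E))
  lab <- align_labels(E, labels)
  ia <- which(lab == groupA)
  ib <- which(lab == groupB)
  if (length(ia) < 2 || length(ib) < 2) {
    stop_mc("both groups need at least 2 cells")
  }
  all_tied <- apply(E$values[c(ia, ib), , drop = FALSE], 2,
                    function(g) length(unique(g)) == 1)
  if (any(all_tied)) {
    warn_mc(sum(all_tied), " gene(s) identical across both groups; ",
            "p = 1 for those")
  }
  p <- apply(E$values, 2, function(g) {
    if (length(unique(g[c(ia, ib)])) == 1) return(1)
    suppressWarnings(
      stats::wilcox.test(g[ia], g[ib], alternative = "two.sided")$p.value)
  })
  data.frame(gene = gene_ids(E), p_value = unname(p),
             rank = rank(p, ties.method = "first"), row.names = NULL)
}

#' ROC AUC of a differential-expression ranking
#'
#' Given per-gene p-values and a caller-supplied ground-truth DE /
#' non-DE labeling, returns the area under the ROC curve of the ranking
#' (1 = all true DE genes rank ahead of all non-DE genes).
#'
#' @param p_values numeric vector of per-gene p-values.
#' @param is_de logical vector, `TRUE` for ground-truth DE genes.
#' @return AUC (scalar in [0, 1]).
#' @export
de_auc <- function(p_values, is_de) {
  stopifnot(length(p_values) == length(is_de))
  if (length(unique(is_de)) < 2) {
    stop_mc("ground truth must contain both DE and non-DE genes")
  }
  r <- pROC::roc(response = factor(is_de, levels = c(FALSE, TRUE)),
                 predictor = -p_values, direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Singular-value spectrum and energy
#'
#' Descending singular values and the cumulative squared-energy fraction
#' they capture — the low-rank diagnostic: expression matrices hold most
#' of their information in the first few singular values.
#'
#' @param E `ExpressionMatrix` or numeric matrix.
#' @return List with `d` (singular values) and `energy` (cumulative
#'   fraction of squared energy, non-decreasing to 1).
#' @export
singular_spectrum <- function(E) {
  d <- svd(as_values(E))$d
  list(d = d, energy = cumsum(d^2) / sum(d^2))
}

#' Rank capturing a given energy fraction
#'
#' Smallest number of leading singular values whose cumulative squared
#' energy reaches `frac` of the total; the default rank rule of the
#' matrix-factorization solver.
#'
#' @param E `ExpressionMatrix` or numeric matrix.
#' @param frac energy fraction (default 0.99).
#' @return Integer rank.
#' @export
energy_rank <- function(E, frac = 0.99) {
  sp <- singular_spectrum(E)
  as.integer(which(sp$energy >= frac)[1])
}
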