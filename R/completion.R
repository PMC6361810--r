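#' Solver configuration for matrix completion
#'
#' @param lam dimensionless regularization weight for the nuclear-norm
#'   solver. The effective Lagrange multiplier is `lam` times the largest
#'   singular value of the observed matrix, computed once at the start, so
#'   the same `lam` behaves identically across data scales. Recovery is
#'   robust for any reasonably small value (< 0.01); default 0.005.
#' @param step_a scalar step parameter `a >= 1` of the
#'   majorization-minimization update `B = X + (1/a) * At(Y - A(X))`.
#'   Because the sampling operator is an elementwise binary mask its
#'   spectral norm is at most 1, so `a = 1` already satisfies the
#'   majorization condition.
#' @param rank_r factor rank for the matrix-factorization solver. `NULL`
#'   (default) picks the smallest rank capturing 99% of the cumulative
#'   squared singular-value energy of the observed matrix.
#' @param tol relative objective-change stopping threshold (default 1e-4).
#' @param max_iter iteration cap (default 500).
#' @param nonneg clip negative values to zero after each outer update
#'   (default `TRUE`; expression cannot be negative).
#' @return A `CompletionConfig` list.
#' @export
completion_config <- function(lam = 0.005, step_a = 1, rank_r = NULL,
                              tol = 1e-4, max_iter = 500, nonneg = TRUE) {
  if (!is.numeric(lam) || lam <= 0) stop_mc("lam must be > 0")
  if (!is.numeric(step_a) || step_a < 1) stop_mc("step_a must be >= 1")
  if (!is.null(rank_r) &&
      (!is.numeric(rank_r) || rank_r < 1 || rank_r != round(rank_r))) {
    stop_mc("rank_r must be a positive integer or NULL")
  }
  if (!is.numeric(tol) || tol <= 0) stop_mc("tol must be > 0")
  if (!is.numeric(max_iter) || max_iter < 1) {
    stop_mc("max_iter must be a positive integer")
  }
  structure(list(lam = lam, step_a = step_a,
                 rank_r = if (is.null(rank_r)) NULL else as.integer(rank_r),
                 tol = tol, max_iter = as.integer(max_iter),
                 nonneg = isTRUE(nonneg)),
            class = "CompletionConfig")
}

#' Build the sampling mask from the data
#'
#' The sub-sampling operator is a binary mask with 1 where an entry of the
#' complete matrix has been observed and 0 where it has not. For dropout
#' imputation the only available convention is that non-zero entries were
#' observed and zeros were not (a zero may be a dropout); masking
#' experiments supply the mask externally instead.
#'
#' @param Y `ExpressionMatrix` or numeric matrix.
#' @return Binary 0/1 matrix of the same shape.
#' @export
build_mask <- function(Y) {
  vals <- as_values(Y)
  mask <- (vals > 0) * 1
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) {
    warn_mc("mask has rows or columns with no observed entries; ",
            "those fibers are determined only by the low-rank structure")
  }
  mask
}

#' Soft-thresholding operator
#'
#' Elementwise `sign(s) * max(0, |s| - tau)`: shrinks magnitudes toward
#' zero by `tau`, zeroing anything smaller than `tau` in magnitude.
#'
#' @param s numeric vector.
#' @param tau threshold, `>= 0`.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(s, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    stop_mc("tau must be a single value >= 0")
  }
  sign(s) * pmax(0, abs(s) - tau)
}

# SVD with a fixed sign convention: the largest-magnitude element of each
# left singular vector is made positive, so runs are bitwise reproducible
# across equivalent decompositions.
svd_signed <- function(B) {
  s <- svd(B)
  if (length(s$d) > 0) {
    flip <- apply(s$u, 2, function(u) u[which.max(abs(u))] < 0)
    if (any(flip)) {
      s$u[, flip] <- -s$u[, flip, drop = FALSE]
      s$v[, flip] <- -s$v[, flip, drop = FALSE]
    }
  }
  s
}

#' Singular-value soft-thresholding (proximal operator of the nuclear norm)
#'
#' Returns `U diag(soft_threshold(s, tau)) Vt` where `B = U diag(s) Vt` is
#' an SVD of `B`. This is the exact minimizer of
#' `||B - X||_F^2 + 2 * tau * ||X||_*`: the Frobenius term decouples
#' across singular values, leaving one scalar problem
#' `(s_B - s_X)^2 + 2 tau |s_X|` per value, solved by soft-thresholding.
#'
#' @param B numeric matrix.
#' @param tau threshold, `>= 0`.
#' @return Matrix of the same shape as `B`.
#' @export
svt_prox <- function(B, tau) {
  if (!all(is.finite(B))) stop_mc("svt_prox: non-finite values in B")
  s <- tryCatch(svd_signed(B), error = function(e) {
    stop_mc("SVD failed in svt_prox: ", conditionMessage(e))
  })
  d <- soft_threshold(s$d, tau)
  s$u %*% (d * t(s$v))
}

#' Nuclear-norm objective
#'
#' `||Y - A(X)||_F^2 + lam * ||X||_*` where `A` is the elementwise
#' sampling mask and the nuclear norm is the sum of singular values.
#'
#' @param X,Y numeric matrices (or `ExpressionMatrix`) of the same shape.
#' @param mask binary sampling mask.
#' @param lam absolute nuclear-norm weight.
#' @return Scalar objective value.
#' @export
objective_nnm <- function(X, Y, mask, lam) {
  X <- as_values(X); Y <- as_values(Y)
  stopifnot(all(dim(X) == dim(Y)), all(dim(mask) == dim(Y)))
  sum((mask * (Y - X))^2) + lam * sum(svd(X)$d)
}

# Shared MM step: B = X + (1/a) At(Y - A(X)). For an elementwise binary
# mask the adjoint scatters the masked residual back in place.
mm_step <- function(X, Y, mask, a) {
  X + (1 / a) * mask * (Y - mask * X)
}

#' Impute by nuclear-norm minimization
#'
#' Minimizes `||Y - A(X)||_F^2 + lam_eff * ||X||_*` by
#' majorization-minimization: each iteration forms
#' `B = X + (1/a) At(Y - A(X))` and applies singular-value
#' soft-thresholding with threshold `lam_eff / 2`, followed by projection
#' onto the non-negative orthant. `lam_eff = cfg$lam * sigma1(Y)` is fixed
#' at the start (`sigma1` = largest singular value of the observed
#' matrix), making `cfg$lam` scale-free. Starts from `X = 0`; stops when
#' the relative objective change drops below `cfg$tol` or at
#' `cfg$max_iter`. Deterministic for fixed inputs.
#'
#' @param Y observed `ExpressionMatrix` (or matrix) with unobserved
#'   entries zeroed.
#' @param mask binary sampling mask, same shape; see [build_mask()].
#' @param cfg a [completion_config()].
#' @return An `ImputationResult`: list with `X` (recovered matrix, same
#'   container type as `Y`), `objective_trace`, `iterations`, `converged`,
#'   `method`, and `lam_eff`.
#' @export
nnm_impute <- function(Y, mask, cfg = completion_config()) {
  Yv <- as_values(Y)
  stopifnot(all(dim(mask) == dim(Yv)))
  lam_eff <- cfg$lam * svd(Yv)$d[1]
  X <- matrix(0, nrow(Yv), ncol(Yv))
  trace <- objective_nnm(X, Yv, mask, lam_eff)
  converged <- FALSE
  k <- 0L
  while (k < cfg$max_iter) {
    k <- k + 1L
    B <- mm_step(X, Yv, mask, cfg$step_a)
    X <- svt_prox(B, lam_eff / 2)
    if (cfg$nonneg) X <- pmax(X, 0)
    if (!all(is.finite(X))) {
      stop_mc("non-finite values in NNM iterate at iteration ", k)
    }
    obj <- objective_nnm(X, Yv, mask, lam_eff)
    trace <- c(trace, obj)
    if (abs(trace[k] - obj) < cfg$tol * max(trace[k], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  finish_result(Y, X, trace, k, converged, "nnm", lam_eff)
}

#' Impute by rank-constrained matrix factorization
#'
#' Models the complete matrix as `X = U V` with `U` m x r and `V` r x n,
#' and minimizes the masked data-fit `||Y - A(UV)||_F^2` by
#' majorization-minimization: each outer iteration forms the same `B`
#' surrogate as [nnm_impute()] and runs one alternating-least-squares
#' sweep (update `U` against `B`, then `V`), then projects `UV` onto the
#' non-negative orthant. `V` is initialized from the top `r` right
#' singular vectors of the observed matrix; `X` starts at 0. Deterministic
#' given the SVD-based initialization. Rank-deficient least-squares
#' systems fall back to the Moore-Penrose pseudoinverse (with a message).
#'
#' @inheritParams nnm_impute
#' @return An `ImputationResult` (method `"mf"`, field `rank_r` records
#'   the rank used).
#' @export
mf_impute <- function(Y, mask, cfg = completion_config()) {
  Yv <- as_values(Y)
  stopifnot(all(dim(mask) == dim(Yv)))
  r <- cfg$rank_r %||% energy_rank(Yv)
  if (r > min(dim(Yv))) {
    stop_mc("rank_r (", r, ") exceeds min(m, n) = ", min(dim(Yv)))
  }
  sv <- svd_signed(Yv)
  V <- t(sv$v[, seq_len(r), drop = FALSE])
  X <- matrix(0, nrow(Yv), ncol(Yv))
  obj_fit <- function(X) sum((mask * (Yv - X))^2)
  trace <- obj_fit(X)
  converged <- FALSE
  k <- 0L
  while (k < cfg$max_iter) {
    k <- k + 1L
    B <- mm_step(X, Yv, mask, cfg$step_a)
    U <- t(solve_ls(tcrossprod(V), V %*% t(B)))
    V <- solve_ls(crossprod(U), t(U) %*% B)
    X <- U %*% V
    if (cfg$nonneg) X <- pmax(X, 0)
    if (!all(is.finite(X))) {
      stop_mc("non-finite values in MF iterate at iteration ", k)
    }
    obj <- obj_fit(X)
    trace <- c(trace, obj)
    if (abs(trace[k] - obj) < cfg$tol * max(trace[k], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  out <- finish_result(Y, X, trace, k, converged, "mf", NA_real_)
  out$rank_r <- r
  out
}

# Solve G %*% Z = RHS for Z; pseudoinverse fallback when G is singular.
solve_ls <- function(G, RHS) {
  tryCatch(solve(G, RHS), error = function(e) {
    message("rank-deficient least-squares system; using pseudoinverse")
    MASS::ginv(G) %*% RHS
  })
}

finish_result <- function(Y, X, trace, iterations, converged, method,
                          lam_eff) {
  Xout <- if (is_expression_matrix(Y)) em_with_values(Y, X) else X
  structure(list(X = Xout,
                 objective_trace = as.numeric(trace),
                 iterations = as.integer(iterations),
                 converged = converged,
                 method = method,
                 lam_eff = lam_eff),
            class = "ImputationResult")
}

#' @export
print.ImputationResult <- function(x, ...) {
  cat(sprintf(
    "<ImputationResult> method = %s, %d iterations (%s), objective %.6g -> %.6g\n",
    x$method, x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Full imputation pipeline
#'
#' Runs the preprocessing chain (optional gene filter, library-size
#' normalization, log2 transform), builds the sampling mask from the
#' zeros of the log matrix, completes it with the chosen solver, and maps
#' the recovered matrix back through the exact inverse transforms. The
#' three returned matrices are mutually consistent under those maps.
#'
#' @param E_raw `ExpressionMatrix` on the counts layer.
#' @param method `"nnm"` (default, the workhorse) or `"mf"`.
#' @param cfg a [completion_config()].
#' @param filter apply [filter_genes()] first (default `TRUE`); skip it
#'   when downstream analyses need the full gene set, e.g. the
#'   zero-fraction dropout analysis.
#' @param min_reads,min_cells gene-filter thresholds.
#' @param pseudocount pseudo-count of the log transform.
#' @return A list with `log`, `normalized`, `counts` (imputed
#'   `ExpressionMatrix` on each scale) and `result` (the
#'   `ImputationResult`).
#' @export
impute_dropouts <- function(E_raw, method = c("nnm", "mf"),
                            cfg = completion_config(),
                            filter = TRUE, min_reads = 3, min_cells = 3,
                            pseudocount = 1) {
  method <- match.arg(method)
  stopifnot(is_expression_matrix(E_raw))
  if (E_raw$layer != "counts") {
    stop_mc("impute_dropouts expects raw counts, got layer '",
            E_raw$layer, "'")
  }
  E <- if (filter) filter_genes(E_raw, min_reads, min_cells) else E_raw
  En <- library_size_normalize(E)
  El <- log_transform(En, pseudocount)
  mask <- suppressWarnings(build_mask(El))
  res <- switch(method,
                nnm = nnm_impute(El, mask, cfg),
                mf = mf_impute(El, mask, cfg))
  log_imp <- res$X
  log_imp$norm_totals <- En$norm_totals
  log_imp$norm_median <- En$norm_median
  norm_imp <- inverse_log_transform(log_imp, pseudocount)
  norm_imp$norm_totals <- En$norm_totals
  norm_imp$norm_median <- En$norm_median
  counts_imp <- denormalize(norm_imp)
  list(log = log_imp, normalized = norm_imp, counts = counts_imp,
       result = res)
}
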