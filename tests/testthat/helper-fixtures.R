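# Shared fixtures, built in code.

# Hand-built 4-cell x 6-gene count fixture used by the preprocessing
# tests. Column comments give the detection pattern at the >=3-reads
# threshold.
toy_counts <- function() {
  vals <- cbind(
    g_keep_exact = c(3, 3, 3, 0),   # 3 cells >= 3 -> kept
    g_drop_one   = c(2, 5, 0, 0),   # 1 cell  >= 3 -> dropped
    g_all_zero   = c(0, 0, 0, 0),   # dropped
    g_keep_rich  = c(10, 4, 3, 3),  # 4 cells >= 3 -> kept
    g_drop_low   = c(1, 1, 1, 1),   # 0 cells >= 3 -> dropped
    g_keep_flat  = c(5, 5, 5, 5)    # kept
  )
  rownames(vals) <- paste0("c", 1:4)
  expression_matrix(vals, layer = "counts")
}

random_counts <- function(m = 8, n = 10, seed = 42, lambda = 5) {
  set.seed(seed)
  vals <- matrix(rpois(m * n, lambda), m, n)
  vals[1, 1] <- max(vals[1, 1], 1)  # avoid all-zero rows at tiny sizes
  expression_matrix(vals, layer = "counts")
}

# Adjusted Rand index by explicit pair enumeration: for every pair of
# items, tally whether the two partitions agree on putting them together
# or apart, then apply the chance correction.
ari_enumeration <- function(p1, p2) {
  n <- length(p1)
  pairs <- utils::combn(n, 2)
  same1 <- p1[pairs[1, ]] == p1[pairs[2, ]]
  same2 <- p2[pairs[1, ]] == p2[pairs[2, ]]
  a <- sum(same1 & same2)         # together in both
  total <- ncol(pairs)
  exp_idx <- sum(same1) * sum(same2) / total
  max_idx <- (sum(same1) + sum(same2)) / 2
  (a - exp_idx) / (max_idx - exp_idx)
}

# Spearman rho of two vectors from first principles (average ranks,
# Pearson on ranks) -- used as the pair-loop oracle for the CTS score.
spearman_manual <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
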