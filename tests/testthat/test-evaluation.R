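test_that("random masking keeps the requested number of entries", {
  X <- matrix(abs(rnorm(100)) + 1, 10, 10)
  msk <- mask_at_random(X, 0.5, seed = 2)
  expect_equal(sum(msk$mask), 50)
  expect_equal(msk$mask + msk$heldout, matrix(1, 10, 10))
  expect_true(all(msk$Y[msk$heldout == 1] == 0))

  msk2 <- mask_at_random(X, 0.5, seed = 2)
  expect_identical(msk$mask, msk2$mask)  # same seed, same mask
  expect_false(identical(msk$mask, mask_at_random(X, 0.5, seed = 3)$mask))

  expect_error(mask_at_random(X, 1.2), "sampling_ratio")
  # tiny matrix at extreme ratio: rounding keeps everything, and the
  # degenerate-mask warning path fires on sparse cases
  expect_equal(sum(mask_at_random(matrix(1, 2, 2), 0.99)$mask), 4)
  expect_warning(mask_at_random(matrix(1, 3, 3), 0.12, seed = 1),
                 "no observed")
})

test_that("recovery metrics match hand arithmetic and a loop oracle", {
  X_true <- matrix(c(1, 2, 3, 4), 2, 2)
  held <- rbind(c(1, 0), c(1, 0))  # held-out truths are 1 and 2
  met <- recovery_metrics(X_true, matrix(0, 2, 2), held)
  expect_equal(met$rmse, sqrt(2.5))
  expect_equal(met$mae, 1.5)
  expect_equal(met$nmse, 1.0)
  expect_equal(met$n_heldout, 2L)

  ident <- recovery_metrics(X_true, X_true, held)
  expect_equal(c(ident$nmse, ident$rmse, ident$mae), c(0, 0, 0))
  expect_gte(met$rmse, met$mae)  # power-mean inequality

  set.seed(13)
  t <- matrix(rnorm(48), 6, 8)^2
  e <- matrix(rnorm(48), 6, 8)^2
  h <- matrix(rbinom(48, 1, 0.4), 6, 8)
  h[1, 1] <- 1
  se <- ae <- tt <- 0; n <- 0
  for (i in 1:6) for (j in 1:8) {
    if (h[i, j] == 1) {
      se <- se + (t[i, j] - e[i, j])^2
      ae <- ae + abs(t[i, j] - e[i, j])
      tt <- tt + t[i, j]^2
      n <- n + 1
    }
  }
  m <- recovery_metrics(t, e, h)
  expect_lt(abs(m$rmse - sqrt(se / n)), 1e-12)
  expect_lt(abs(m$mae - ae / n), 1e-12)
  expect_lt(abs(m$nmse - se / tt), 1e-12)

  expect_error(recovery_metrics(matrix(0, 2, 2), matrix(1, 2, 2), held),
               "undefined")
  expect_error(recovery_metrics(t, e, matrix(0, 6, 8)), "empty")
})

test_that("separability score: forced constructions and pair-loop oracle", {
  # group A: copies of an increasing vector; group B: copies of its
  # strictly decreasing rearrangement. Within-group Spearman = 1,
  # cross-group = -1, so cts = 1 - (-1) = 2.
  v <- c(1, 3, 5, 7, 9, 11)
  E <- expression_matrix(rbind(v, v * 2, v * 3,
                               rev(v), rev(v) * 2, rev(v) * 3),
                         cell_ids = paste0("c", 1:6), layer = "log")
  lab <- c("A", "A", "A", "B", "B", "B")
  res <- cts_score(E, lab, "A", "B")
  expect_equal(unname(res$intra_scatter), c(1, 1))
  expect_equal(res$inter_scatter, -1)
  expect_equal(res$cts, 2)
  # symmetry under swapping the groups
  sw <- cts_score(E, lab, "B", "A")
  expect_equal(sw$cts, res$cts)

  # two identical "groups" separate nothing
  E2 <- expression_matrix(rbind(v, v * 2, v, v * 2),
                          cell_ids = paste0("c", 1:4), layer = "log")
  expect_equal(cts_score(E2, c("A", "A", "B", "B"), "A", "B")$cts, 0)

  # pair-loop oracle on random two-cluster data
  sim <- generate_scrnaseq(m_cells = 12, n_genes = 20, k_clusters = 2,
                           r = 4, dropout_strength = 0,
                           structural_zero_frac = 0, depth = 300,
                           seed = 6)
  L <- log_transform(library_size_normalize(sim$observed))
  got <- cts_score(L, sim$labels, "cluster1", "cluster2")
  lab <- sim$labels$labels
  groups <- list(which(lab == "cluster1"), which(lab == "cluster2"))
  intra <- vapply(groups, function(g) {
    vals <- c()
    for (i in g) for (j in g) {
      if (i < j) vals <- c(vals, spearman_manual(L$values[i, ],
                                                 L$values[j, ]))
    }
    median(vals)
  }, numeric(1))
  inter <- c()
  for (i in groups[[1]]) for (j in groups[[2]]) {
    inter <- c(inter, spearman_manual(L$values[i, ], L$values[j, ]))
  }
  expect_lt(abs(got$cts - (mean(intra) - median(inter))), 1e-12)

  expect_error(cts_score(E, c("A", "B", "B", "B", "B", "B"), "A", "B"),
               "at least 2 cells")
})

test_that("clustering ARI: perfect blobs, chance level, formula oracle", {
  # well-separated blobs: every k-means run recovers the annotation
  set.seed(17)
  blob <- rbind(matrix(rnorm(40 * 10, mean = 0, sd = 0.05), 40),
                matrix(rnorm(40 * 10, mean = 5, sd = 0.05), 40))
  E <- expression_matrix(blob - min(blob), layer = "log")
  lab <- rep(c("a", "b"), each = 40)
  aris <- clustering_ari(E, lab, n_runs = 10, seed = 5)
  expect_equal(aris, rep(1, 10))

  # random labels agree only at chance: ARI near 0
  rnd <- sample(c("a", "b"), 80, replace = TRUE)
  expect_lt(abs(mean(clustering_ari(E, rnd, n_runs = 10, seed = 5))),
            0.15)

  # enumerated-pairs oracle on two partitions of 6 items
  p1 <- c(1, 1, 1, 2, 2, 2)
  p2 <- c(1, 1, 2, 2, 2, 2)
  expect_equal(mclust::adjustedRandIndex(p1, p2),
               ari_enumeration(p1, p2))
  expect_equal(ari_enumeration(p1, p1), 1)

  expect_error(clustering_ari(E, lab, k = 100), "exceeds")
})

test_that("zero-fraction binning follows the bulk reference", {
  # 6 genes, bulk values: one zero-expression gene, others spread over
  # (0, 500], one beyond the range (excluded)
  bulk <- c(g1 = 0, g2 = 30, g3 = 80, g4 = 260, g5 = 490, g6 = 800)
  vals <- cbind(g1 = c(0, 0, 0),    # all zero
                g2 = c(0, 1, 2),    # one zero of three
                g3 = c(3, 4, 0.2),  # 0.2 counts as an imputed zero
                g4 = c(5, 6, 7),    # none
                g5 = c(0, 0, 1),    # two of three
                g6 = c(0, 0, 0))    # excluded: bulk > 500
  E <- expression_matrix(vals, layer = "counts")
  zf <- zero_fraction_by_bins(E, bulk, n_bins = 10)
  # bins are width 500/9 = 55.56 over (0, 500]
  expect_equal(zf$zero_fraction[1], 1)         # g1
  expect_equal(zf$zero_fraction[2], 1 / 3)     # g2 in (0, 55.6]
  expect_equal(zf$zero_fraction[3], 1 / 3)     # g3 in (55.6, 111.1]
  expect_equal(zf$zero_fraction[6], 0)         # g4
  expect_true(is.na(zf$zero_fraction[9]))     # empty bin stays NA
  expect_equal(zf$zero_fraction[10], 2 / 3)    # g5 in (444.4, 500]
  expect_true(is.na(zf$zero_fraction[4]))      # empty bin stays NA
  expect_equal(sum(zf$n_genes), 5)             # g6 excluded

  # a matrix with nothing below the threshold has all-zero fractions
  E2 <- expression_matrix(vals + 1, layer = "counts")
  zf2 <- zero_fraction_by_bins(E2, bulk)
  expect_true(all(zf2$zero_fraction[!is.na(zf2$zero_fraction)] == 0))
})

test_that("CV-mean relation recovers Poisson scaling", {
  set.seed(23)
  mus <- rep(c(1, 5, 10, 50, 100), each = 8)
  vals <- sapply(mus, function(mu) rpois(800, mu))
  E <- expression_matrix(vals, layer = "normalized")
  rel <- cv_mean_relation(E)
  expect_equal(unname(rel$reference["slope"]), -0.5)
  expect_lt(abs(rel$fit["slope"] + 0.5), 0.1)

  # constant gene excluded
  vals2 <- cbind(vals[, 1:3], 7)
  colnames(vals2) <- c("g1", "g2", "g3", "const")
  E2 <- expression_matrix(vals2, layer = "normalized")
  expect_message(rel2 <- cv_mean_relation(E2), "excluded")
  expect_equal(nrow(rel2$points), 3)

  # CV is scale-invariant: scaling all cells shifts means only
  rel3 <- cv_mean_relation(expression_matrix(vals * 10,
                                             layer = "normalized"))
  expect_equal(rel3$points$cv, rel$points$cv, tolerance = 1e-12)
})

test_that("silhouette agrees with a hand enumeration and its limits", {
  # two tight, distant groups approach silhouette 1
  emb <- rbind(matrix(c(0, 0.01, 0, 0.01, 0, 0, 0.01, 0.01), 4, 2),
               matrix(c(100, 100.01, 100, 100.01, 0, 0, 0.01, 0.01),
                      4, 2))
  lab <- rep(c("a", "b"), each = 4)
  expect_gt(silhouette_on_embedding(emb, lab), 0.999)

  # 5-point hand example, enumerated from pairwise distances
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(4, 0), c(4, 1))
  lab5 <- c("A", "A", "A", "B", "B")
  D <- as.matrix(dist(pts))
  sil_hand <- vapply(1:5, function(i) {
    own <- which(lab5 == lab5[i] & seq_len(5) != i)
    oth <- which(lab5 != lab5[i])
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(silhouette_on_embedding(pts, lab5), mean(sil_hand),
               tolerance = 1e-12)

  expect_warning(
    silhouette_on_embedding(pts, c("A", "A", "A", "A", "B")),
    "singleton")
  expect_error(silhouette_on_embedding(pts, rep("A", 5)), "2 groups")
})

test_that("rank-sum DE: permutation oracle, ties, and the AUC helper", {
  # complete separation, 5 vs 5, no ties: exact two-sided p equals the
  # value from enumerating all C(10,5) group assignments
  gA <- c(1, 2, 3, 4, 5); gB <- c(10, 11, 12, 13, 14)
  E <- expression_matrix(matrix(c(gA, gB), ncol = 1),
                         cell_ids = paste0("c", 1:10), layer = "log")
  de <- wilcoxon_de(E, rep(c("A", "B"), each = 5), "A", "B")
  pooled <- c(gA, gB)
  combs <- combn(10, 5)
  w_all <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - 5 * 6 / 2  # Mann-Whitney U of group A
  })
  w_obs <- sum(rank(pooled)[1:5]) - 15
  p_exact <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  expect_equal(de$p_value[1], p_exact)

  # identical distributions: large p; all-tied gene warns and gets p 1
  set.seed(29)
  same <- matrix(rnorm(20 * 30), 20, 30)
  E2 <- expression_matrix(same - min(same), layer = "log")
  de2 <- wilcoxon_de(E2, rep(c("A", "B"), each = 10), "A", "B")
  expect_gt(median(de2$p_value), 0.2)

  E3 <- expression_matrix(cbind(c(gA, gB), rep(1, 10)), layer = "log")
  expect_warning(de3 <- wilcoxon_de(E3, rep(c("A", "B"), each = 5),
                                    "A", "B"), "identical")
  expect_equal(de3$p_value[2], 1)

  # AUC helper: perfect ordering gives 1
  p <- c(0.001, 0.002, 0.01, 0.4, 0.6, 0.9)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(de_auc(p, truth), 1)
  expect_equal(de_auc(rev(p), truth), 0)
  expect_error(de_auc(p, rep(TRUE, 6)), "both")
})

test_that("singular spectrum flags low rank and drives the rank default", {
  X <- matrix(rnorm(10 * 2), 10, 2) %*% matrix(rnorm(2 * 8), 2, 8)
  sp <- singular_spectrum(X)
  expect_equal(sum(sp$d > 1e-10 * sp$d[1]), 2)
  expect_true(all(diff(sp$energy) >= -1e-15))
  expect_equal(tail(sp$energy, 1), 1)

  # planted rank recovered at 99% energy under small noise (balanced
  # spectrum so no single component hoards the energy)
  set.seed(33)
  U <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))
  V <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  lr <- U %*% diag(c(10, 8, 6, 5)) %*% t(V)
  noisy <- lr + matrix(rnorm(1200, sd = 1e-3), 40, 30)
  expect_equal(energy_rank(noisy), 4L)
})
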