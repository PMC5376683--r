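test_that("spearman_matrix matches a rank-then-Pearson oracle", {
  set.seed(11)
  vals <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("G", 1:5)))
  m <- log2_matrix(vals)
  cg <- spearman_matrix(m, "gene")
  oracle <- cor(apply(vals, 2, rank))
  expect_lt(max(abs(cg$rho - oracle)), 1e-12)
  expect_equal(diag(cg$rho), rep(1, 5), ignore_attr = TRUE)
  expect_identical(cg$rho, t(cg$rho))
  expect_true(all(cg$rho >= -1 & cg$rho <= 1))

  cc <- spearman_matrix(m, "cell")
  expect_equal(dim(cc$rho), c(10L, 10L))
})

test_that("monotone pairs give rho of plus and minus one", {
  vals <- cbind(G1 = 1:6, G2 = (1:6)^2, G3 = 7 - (1:6))
  rho <- spearman_matrix(log2_matrix(vals), "gene")$rho
  expect_equal(rho["G1", "G2"], 1)
  expect_equal(rho["G1", "G3"], -1)
})

test_that("spearman_matrix refuses short vectors", {
  vals <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(spearman_matrix(log2_matrix(vals), "gene"), "at least 3")
})

test_that("hier_cluster recovers planted clusters and honours k limits", {
  tc <- two_cluster_matrix()
  corr <- spearman_matrix(tc$matrix, "cell")
  a2 <- hier_cluster(corr, 2)
  expect_equal(ari_pair_counting(a2$labels, tc$truth), 1)

  flat <- log2_matrix(matrix(rep(c(1, 5, 2, 8), each = 4), 4, 4,
                             dimnames = list(NULL, paste0("G", 1:4))))
  corr_flat <- spearman_matrix(flat, "cell")
  expect_equal(hier_cluster(corr_flat, 1)$k, 1L)

  singles <- hier_cluster(corr, nrow(corr$rho))
  expect_equal(singles$k, nrow(corr$rho))
  expect_error(hier_cluster(corr, nrow(corr$rho) + 1L), "k must be")
})

test_that("curate_subgroups recovers planted clusters despite stray cells", {
  tc <- two_cluster_matrix(n_per = 12)
  # one aberrant cell that average linkage would isolate
  tc$matrix$values[1, ] <- tc$matrix$values[1, ] + c(30, -30, 30, -30, 30, -30)
  corr <- spearman_matrix(tc$matrix, "cell")
  cur <- curate_subgroups(corr, 2)
  expect_equal(cur$k, 2L)
  expect_gte(ari_pair_counting(cur$labels[-1], tc$truth[-1]), 1)
})

test_that("split_mixed_cluster divides by cell class and leaves others", {
  labels <- setNames(c("1", "1", "3", "3", "3", "3"), sprintf("c%02d", 1:6))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:6), sample_id = "s",
                      cell_class = c("control", "control", "control",
                                     "control", "expCAF", "expCAF"))
  assign <- subgroup_assignment(labels, "hier_corr")
  out <- split_mixed_cluster(assign, cells, "3")
  expect_equal(out$k, 3L)
  expect_equal(unname(out$labels[3:6]),
               c("3.control", "3.control", "3.expCAF", "3.expCAF"))
  expect_equal(unname(out$labels[1:2]), c("1", "1"))

  pure <- split_mixed_cluster(assign, cells, "1")
  expect_equal(unname(pure$labels[1:2]), c("1", "1"))  # single class unchanged
  expect_error(split_mixed_cluster(assign, cells, "9"), "not present")
})

test_that("fit_pca agrees with an independent eigendecomposition", {
  set.seed(3)
  vals <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("G", 1:6)))
  fit <- fit_pca(log2_matrix(vals), n_components = 3)
  cen <- sweep(vals, 2, colMeans(vals))
  eig <- eigen(cov(cen))
  for (j in 1:3) {
    v <- eig$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_lt(max(abs(fit$model$loadings[, j] - v)), 1e-8)
    expect_lt(max(abs(fit$scores[, j] - cen %*% v)), 1e-8)
  }
  expect_equal(fit$model$explained_variance_fraction,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-10)
  # loadings columns orthonormal
  expect_lt(max(abs(crossprod(fit$model$loadings) - diag(3))), 1e-10)
})

test_that("pca handles collinear data, centroids and row permutation", {
  vals <- cbind(G1 = c(1, 2, 3, 4), G2 = c(2, 4, 6, 8))
  fit <- fit_pca(log2_matrix(vals), n_components = 1)
  expect_equal(fit$model$explained_variance_fraction[1], 1)
  # projecting the training centroid lands at the origin
  expect_lt(max(abs(predict(fit$model, matrix(colMeans(vals), 1)))), 1e-12)

  set.seed(5)
  vals2 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("G", 1:4)))
  f1 <- fit_pca(log2_matrix(vals2), 2)
  perm <- c(5, 1, 12, 7, 3, 9, 2, 11, 4, 10, 6, 8)
  f2 <- fit_pca(log2_matrix(vals2[perm, ]), 2)
  expect_lt(max(abs(f2$scores - f1$scores[perm, ])), 1e-10)
  expect_error(fit_pca(log2_matrix(vals2), 13), "n_components")
})

test_that("fit_som separates planted clusters and is seed-deterministic", {
  tc <- two_cluster_matrix()
  s1 <- fit_som(tc$matrix, grid = c(1, 2), seed = 7)
  expect_equal(ari_pair_counting(s1$labels, tc$truth), 1)
  s2 <- fit_som(tc$matrix, grid = c(1, 2), seed = 7)
  expect_identical(s1$labels, s2$labels)

  const <- log2_matrix(matrix(5, 8, 4, dimnames = list(NULL, paste0("G", 1:4))))
  sc <- fit_som(const, grid = c(1, 2), seed = 1)
  expect_equal(sc$k, 1L)  # all cells on one unit

  expect_warning(fit_som(tc$matrix, grid = c(5, 5), seed = 1), "more units")
})
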