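test_that("summarize_groups reproduces hand-computed statistics", {
  vals <- matrix(c(2, 4, 6, NA,        # gene A: 3 of 4 detected
                   1, 1, 1, 1),        # gene B: all detected
                 4, 2, dimnames = list(NULL, c("A", "B")))
  m <- log2_matrix(vals)
  s <- summarize_groups(m, rep("g1", 4))
  a <- s[s$gene == "A", ]
  expect_equal(a$frequency, 0.75)
  expect_equal(a$level, 4)
  expect_equal(a$sem, 2 / sqrt(3))
  expect_equal(a$n_pos, 3L)
  expect_equal(a$n_total, 4L)
})

test_that("never-detected gene has zero frequency and missing level", {
  vals <- matrix(c(NA, NA, 3, 4), 2, 2, dimnames = list(NULL, c("A", "B")))
  s <- summarize_groups(log2_matrix(vals), rep("g", 2))
  a <- s[s$gene == "A", ]
  expect_equal(a$frequency, 0)
  expect_true(is.na(a$level))
  expect_error(summarize_groups(log2_matrix(vals), factor(c("g", "h"),
                                levels = c("g", "h", "empty"))))
})

test_that("summaries match an independent loop over (gene, group)", {
  set.seed(21)
  vals <- matrix(rnorm(30 * 4, 5), 30, 4, dimnames = list(NULL, paste0("G", 1:4)))
  vals[runif(length(vals)) < 0.3] <- NA
  grp <- rep(c("x", "y", "z"), each = 10)
  s <- summarize_groups(log2_matrix(vals), grp)
  for (i in seq_len(nrow(s))) {
    v <- vals[grp == s$group[i], s$gene[i]]
    det <- v[!is.na(v)]
    expect_lt(abs(s$frequency[i] - mean(!is.na(v))), 1e-12)
    if (length(det) > 0) expect_lt(abs(s$level[i] - mean(det)), 1e-12)
  }
  # invariant to cell order
  perm <- sample(30)
  s2 <- summarize_groups(log2_matrix(vals[perm, ]), grp[perm])
  expect_equal(s2[order(s2$gene, s2$group), c("frequency", "level", "sem")],
               s[order(s$gene, s$group), c("frequency", "level", "sem")],
               ignore_attr = TRUE)
})

test_that("differential_expression matches the closed-form t statistic", {
  a <- log2_matrix(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "G")))
  b <- log2_matrix(matrix(c(4, 5, 6), 3, 1, dimnames = list(NULL, "G")))
  de <- differential_expression(a, b, "student_t")
  # pooled-variance two-sample t on (1,2,3) vs (4,5,6): t = -3/sqrt(2/3)
  t_stat <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(abs(t_stat), df = 4, lower.tail = FALSE)
  expect_lt(abs(de$p_value - p_oracle), 1e-10)
  expect_equal(de$delta_level, 3)
  expect_true(de$significant)

  # one-gene ANOVA with two groups satisfies F = t^2
  de_f <- differential_expression(a, b, "anova")
  expect_lt(abs(de_f$p_value - p_oracle), 1e-10)

  de_w <- differential_expression(a, b, "mann_whitney")
  expect_false(is.na(de_w$p_value))
})

test_that("identical groups give zero delta and p near 1", {
  set.seed(2)
  vals <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "G"))
  m <- log2_matrix(vals)
  de <- differential_expression(m, m, "student_t")
  expect_equal(de$delta_level, 0)
  expect_equal(de$delta_frequency, 0)
  expect_gt(de$p_value, 0.999)
  expect_false(de$significant)
})

test_that("fewer than two detected cells per side marks p missing", {
  a <- log2_matrix(matrix(c(1, NA, NA), 3, 1, dimnames = list(NULL, "G")))
  b <- log2_matrix(matrix(c(4, 5, 6), 3, 1, dimnames = list(NULL, "G")))
  de <- differential_expression(a, b, "student_t")
  expect_true(is.na(de$p_value))
  expect_false(de$significant)
  expect_error(differential_expression(a, b, "chi_squared"))
})

test_that("stratified scatter flags exactly the significant genes", {
  set.seed(31)
  ref <- matrix(rnorm(20 * 3, 5, 1), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  shifted <- matrix(rnorm(20 * 3, 5, 1), 20, 3,
                    dimnames = list(NULL, c("A", "B", "C")))
  shifted[, "B"] <- shifted[, "B"] + 10  # 10 SD shift
  mref <- log2_matrix(ref)
  msh <- log2_matrix(shifted)
  sc <- stratified_mean_scatter(mref, list(s1 = msh))
  expect_true(sc$outside[sc$gene == "B"])
  de <- differential_expression(mref, msh, "student_t")
  expect_equal(sc$outside, de$significant)  # definitional consistency

  same <- stratified_mean_scatter(mref, list(s1 = mref))
  expect_false(any(same$outside))
  one_cell <- log2_matrix(ref[1, , drop = FALSE])
  expect_error(stratified_mean_scatter(mref, list(s1 = one_cell)),
               "fewer than 2")
})

test_that("two-component mixture is recovered and selected by BIC", {
  set.seed(101)
  x <- c(rnorm(100, 2, 0.5), rnorm(100, 6, 0.5))
  fit <- fit_bimodal(x)
  expect_equal(fit$k, 2L)
  expect_lt(abs(fit$means[1] - 2), 0.3)
  expect_lt(abs(fit$means[2] - 6), 0.3)
  expect_equal(sum(fit$weights), 1)
  expect_true(fit$boundary > fit$means[1] && fit$boundary < fit$means[2])

  # independent mixture fitter agrees on both k and the means
  mclustBIC <- mclust::mclustBIC
  mc <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  expect_equal(mc$G, 2L)
  expect_lt(max(abs(sort(mc$parameters$mean) - fit$means)), 0.05)
})

test_that("unimodal and degenerate samples select one component", {
  set.seed(102)
  fit1 <- fit_bimodal(rnorm(200, 4, 1))
  expect_equal(fit1$k, 1L)
  expect_lt(abs(fit1$means - 4), 0.2)

  const <- fit_bimodal(rep(3, 20))
  expect_equal(const$k, 1L)
  expect_equal(const$sds, 1e-3)  # sd floor
  expect_error(fit_bimodal(rnorm(5)), "at least 10")
})

test_that("BIC detection of bimodality grows with separation", {
  rate <- sapply(c(1, 4, 8), function(sep) {
    hits <- sapply(1:10, function(i) {
      set.seed(1000 + i)
      x <- c(rnorm(60, 2, 1), rnorm(60, 2 + sep, 1))
      fit_bimodal(x, mixture_config(seed = i))$k == 2L
    })
    mean(hits)
  })
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[3], 1)
})

test_that("stratify_by_gene splits detected cells at the boundary", {
  set.seed(103)
  truth <- rep(c("low", "high"), each = 60)
  x <- c(rnorm(60, 2, 0.5), rnorm(60, 6, 0.5))
  vals <- matrix(c(x, rnorm(120, 5)), 120, 2, dimnames = list(NULL, c("A", "B")))
  m <- log2_matrix(vals)
  fit <- fit_bimodal(x)
  s <- stratify_by_gene(m, "A", fit)
  expect_equal(unname(s$labels[which.min(abs(x - fit$means[1]))]), "low")
  expect_equal(unname(s$labels[which.min(abs(x - fit$means[2]))]), "high")
  expect_gte(mean(s$labels == truth), 0.95)

  # non-detects always fall in the low stratum
  vals_nd <- vals; vals_nd[1, "A"] <- NA
  s_nd <- stratify_by_gene(log2_matrix(vals_nd), "A", fit)
  expect_equal(unname(s_nd$labels[1]), "low")

  fit1 <- fit_bimodal(rnorm(50, 4, 1), mixture_config(seed = 2))
  expect_error(stratify_by_gene(m, "A", fit1), "no bimodal")
})
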