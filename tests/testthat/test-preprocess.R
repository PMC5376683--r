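test_that("cq_to_rq maps cycles to relative quantities", {
  cq <- matrix(c(28, 25, NA, 30, 18, 20), 3, 2,
               dimnames = list(NULL, c("ACTA2", "GAPDH")))
  m <- cq_to_rq(mini_plate(cq))
  expect_equal(m$values[1, "ACTA2"], 1)     # Cq at cutoff
  expect_equal(m$values[2, "ACTA2"], 8)     # 2^3
  expect_false(m$detected[3, "ACTA2"])      # non-detect stays non-detect
  expect_equal(m$values[3, "ACTA2"], 0)
  expect_false(m$detected[1, "GAPDH"])      # Cq above cutoff clipped
  expect_equal(m$values[1, "GAPDH"], 0)
  expect_equal(m$scale, "linear_rq")
})

test_that("lower Cq gives strictly higher RQ", {
  cqs <- seq(27, 10, by = -0.5)
  cq <- matrix(c(cqs, rep(18, length(cqs))), ncol = 2,
               dimnames = list(NULL, c("ACTA2", "GAPDH")))
  m <- cq_to_rq(mini_plate(cq))
  expect_true(all(diff(m$values[, "ACTA2"]) > 0))
})

test_that("GAPDH gate keeps positive cells and reports positivity", {
  cq <- matrix(20, 10, 2, dimnames = list(NULL, c("ACTA2", "GAPDH")))
  cq[4, "GAPDH"] <- NA
  g <- qc_gapdh_gate(cq_to_rq(mini_plate(cq)))
  expect_equal(nrow(g$matrix$values), 9L)
  expect_equal(g$report$positivity, 0.9)
  expect_true(g$report$pass)

  all_in <- qc_gapdh_gate(cq_to_rq(mini_plate(
    matrix(20, 4, 2, dimnames = list(NULL, c("ACTA2", "GAPDH"))))))
  expect_equal(all_in$report$positivity, 1)
  expect_equal(nrow(all_in$matrix$values), 4L)

  cq_none <- matrix(c(rep(20, 3), rep(NA_real_, 3)), 3, 2,
                    dimnames = list(NULL, c("ACTA2", "GAPDH")))
  expect_warning(g0 <- qc_gapdh_gate(cq_to_rq(mini_plate(cq_none))),
                 "positivity")
  expect_equal(nrow(g0$matrix$values), 0L)
  expect_false(g0$report$pass)
})

test_that("to_log2 transforms and imputes below the per-gene floor", {
  cq <- matrix(c(25, 26, NA, 20, 21, 22), 3, 2,
               dimnames = list(NULL, c("ACTA2", "GAPDH")))
  rq <- cq_to_rq(mini_plate(cq))
  lg <- to_log2(rq, impute = FALSE)
  expect_equal(lg$values[1, "ACTA2"], 3)   # RQ 8 -> 3
  expect_true(is.na(lg$values[3, "ACTA2"]))
  expect_equal(lg$scale, "log2_rq")

  li <- to_log2(rq, impute = TRUE)
  # gene minimum detected log2 is 2 (Cq 26), offset 1 -> imputed at 1
  expect_equal(li$values[3, "ACTA2"], 1)
  expect_equal(li$scale, "log2_rq_imputed")
  # imputation never alters the detection mask
  expect_identical(li$detected, lg$detected)
  expect_error(to_log2(li), "linear_rq")
})

test_that("gene with zero detections imputes at 0", {
  cq <- matrix(c(NA, NA, 20, 21), 2, 2,
               dimnames = list(NULL, c("ACTA2", "GAPDH")))
  li <- to_log2(cq_to_rq(mini_plate(cq)), impute = TRUE)
  expect_equal(unname(li$values[, "ACTA2"]), c(0, 0))
})

test_that("autoscaling matches brute-force column and row statistics", {
  set.seed(7)
  vals <- matrix(rnorm(10 * 5, 5, 2), 10, 5,
                 dimnames = list(NULL, paste0("G", 1:5)))
  m <- log2_matrix(vals)
  m$scale <- "log2_rq_imputed"

  by_gene <- autoscale_by_gene(m)
  oracle <- vals
  for (j in 1:5) oracle[, j] <- (vals[, j] - mean(vals[, j])) / sd(vals[, j])
  expect_lt(max(abs(by_gene$values - oracle)), 1e-12)
  expect_equal(unname(by_gene$values[, 1])[1:3],
               unname(oracle[, 1])[1:3])  # sample (n-1) SD convention

  by_cell <- autoscale_by_cell(m)
  expect_lt(max(abs(rowMeans(by_cell$values))), 1e-12)
  expect_lt(max(abs(apply(by_cell$values, 1, sd) - 1)), 1e-12)

  # z-scoring an already z-scored row is the identity
  twice <- autoscale_by_cell(by_cell)
  expect_lt(max(abs(twice$values - by_cell$values)), 1e-10)
})

test_that("simple column example and constant columns behave as documented", {
  m <- log2_matrix(matrix(c(2, 4, 6, 5, 5, 5), 3, 2,
                          dimnames = list(NULL, c("A", "B"))))
  expect_warning(sc <- autoscale_by_gene(m), "constant")
  expect_equal(unname(sc$values[, "A"]), c(-1, 0, 1))
  expect_equal(unname(sc$values[, "B"]), c(0, 0, 0))

  cen <- mean_center_by_gene(m)
  expect_equal(unname(cen$values[, "A"]), c(-2, 0, 2))
  expect_lt(max(abs(colMeans(cen$values))), 1e-12)
  again <- mean_center_by_gene(cen)
  expect_equal(again$values, cen$values)
})

test_that("combine_mean_centered centres each dataset independently", {
  a <- log2_matrix(matrix(c(1, 3, 2, 6), 2, 2,
                          dimnames = list(c("a1", "a2"), c("G1", "G2"))))
  b <- log2_matrix(matrix(c(10, 30, 20, 60), 2, 2,
                          dimnames = list(c("b1", "b2"), c("G1", "G2"))))
  comb <- combine_mean_centered(list(A = a, B = b), c("G1", "G2"))
  expect_equal(nrow(comb$values), 4L)
  for (ds in c("A", "B")) {
    rows <- comb$cells$dataset == ds
    expect_lt(max(abs(colMeans(comb$values[rows, ]))), 1e-12)
  }
  # single-cell datasets centre to exactly zero
  one <- log2_matrix(matrix(c(5, 7), 1, 2, dimnames = list("x1", c("G1", "G2"))))
  both <- combine_mean_centered(list(p = one, q = one), c("G1", "G2"))
  expect_true(all(both$values == 0))
  expect_equal(nrow(both$values), 2L)  # self-combination duplicates rows

  expect_error(combine_mean_centered(list(A = a), c("G1", "NOPE")), "NOPE")
})

test_that("transform chain preserves the detection mask", {
  cq <- matrix(c(20, NA, 22, 19, 21, 18), 3, 2,
               dimnames = list(NULL, c("ACTA2", "GAPDH")))
  rq <- cq_to_rq(mini_plate(cq))
  mask <- rq$detected
  li <- to_log2(rq, impute = TRUE)
  expect_identical(autoscale_by_gene(li)$detected, mask)
  expect_identical(autoscale_by_cell(li)$detected, mask)
  expect_identical(mean_center_by_gene(li)$detected, mask)
})
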