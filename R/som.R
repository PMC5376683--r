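# Online Kohonen SOM on a rectangular grid with a Gaussian neighbourhood.
# Prototypes are initialized on the plane spanned by the first two principal
# components (linear initialization; deterministic) or from a seeded sample
# of data rows; at each iteration one row (seeded random order) updates the
# best-matching unit and its neighbours with linearly decaying learning rate
# and radius.

som_train <- function(x, rows, cols, n_iter = 1000L, seed = 1L,
                      alpha0 = 0.5, alpha_min = 0.01,
                      init = c("linear", "sample")) {
  x <- as.matrix(x)
  n <- nrow(x)
  init <- match.arg(init)
  n_units <- rows * cols
  assert_that(n >= 1L, "need at least one observation")
  grid <- as.matrix(expand.grid(row = seq_len(rows), col = seq_len(cols)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  codes <- if (init == "linear") {
    axis <- function(g) {
      s <- stats::sd(g)
      if (is.na(s) || s == 0) rep(0, length(g)) else (g - mean(g)) / s
    }
    pc <- stats::prcomp(x, rank. = min(2L, ncol(x), n))
    base <- matrix(rep(colMeans(x), each = n_units), n_units)
    span <- outer(axis(grid[, 1]), pc$rotation[, 1] * pc$sdev[1])
    if (ncol(pc$rotation) > 1L) {
      span <- span + outer(axis(grid[, 2]), pc$rotation[, 2] * pc$sdev[2])
    }
    base + span
  } else {
    x[sample.int(n, n_units, replace = n_units > n), , drop = FALSE]
  }
  order_idx <- sample.int(n, n_iter, replace = TRUE)
  r0 <- max(rows, cols) / 2
  r_min <- 0.5
  for (t in seq_len(n_iter)) {
    frac <- (t - 1) / max(n_iter - 1, 1)
    alpha <- alpha0 + (alpha_min - alpha0) * frac
    radius <- r0 + (r_min - r0) * frac
    xi <- x[order_idx[t], ]
    d2 <- rowSums(sweep(codes, 2L, xi)^2)
    bmu <- which.min(d2)  # which.min takes the lowest index on ties
    gd2 <- (grid[, 1] - grid[bmu, 1])^2 + (grid[, 2] - grid[bmu, 2])^2
    h <- alpha * exp(-gd2 / (2 * radius^2))
    codes <- codes + h * sweep(-codes, 2L, xi, "+")
  }
  d <- outer(rowSums(x^2), rowSums(codes^2), "+") - 2 * x %*% t(codes)
  assignment <- apply(d, 1L, which.min)  # lowest unit index wins ties
  list(codes = codes, grid = grid, assignment = assignment)
}
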