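.group_vector <- function(matrix, groups) {
  if (inherits(groups, "subgroup_assignment")) {
    g <- groups$labels[match(matrix$cells$cell_id, names(groups$labels))]
    assert_that(!anyNA(g), "every cell must be labelled in the assignment")
    g
  } else if (length(groups) == 1L && groups == "cell_class") {
    matrix$cells$cell_class
  } else {
    assert_that(length(groups) == nrow(matrix$values),
                "groups must cover every cell")
    if (is.factor(groups)) groups else as.character(groups)
  }
}

#' Per-gene per-group frequency and expression level
#'
#' For each (gene, group): the detection frequency (fraction of cells with
#' the gene detected), the mean log2 RQ over detected cells only, its
#' standard error (sample SD / sqrt(n_pos)), and the counts. Genes never
#' detected in a group get frequency 0 and a missing level.
#'
#' @param matrix A log2-scale [expr_matrix()] with its detection mask; level
#'   statistics use detected entries only, so an imputed matrix gives the
#'   same answer as an unimputed one.
#' @param groups A [subgroup_assignment()], the string `"cell_class"`, or a
#'   vector of group labels (one per cell).
#' @return A `group_summary` data frame: `gene`, `group`, `frequency`,
#'   `level`, `sem`, `n_pos`, `n_total`.
#' @export
summarize_groups <- function(matrix, groups = "cell_class") {
  stopifnot(inherits(matrix, "expr_matrix"))
  assert_that(matrix$scale %in% c("log2_rq", "log2_rq_imputed"),
              "summarize_groups expects a log2-scale matrix")
  g <- .group_vector(matrix, groups)
  tab <- table(g)
  assert_that(all(tab > 0L), "empty group")
  res <- expand.grid(gene = matrix$genes$gene, group = names(tab),
                     stringsAsFactors = FALSE)
  res$frequency <- res$level <- res$sem <- NA_real_
  res$n_pos <- res$n_total <- NA_integer_
  for (i in seq_len(nrow(res))) {
    j <- match(res$gene[i], matrix$genes$gene)
    rows <- g == res$group[i]
    det <- matrix$detected[rows, j]
    vals <- matrix$values[rows, j][det]
    res$n_total[i] <- sum(rows)
    res$n_pos[i] <- sum(det)
    res$frequency[i] <- mean(det)
    if (res$n_pos[i] > 0L) {
      res$level[i] <- mean(vals)
      res$sem[i] <- if (res$n_pos[i] > 1L) sd_sample(vals) / sqrt(length(vals))
        else NA_real_
    }
  }
  structure(res, class = c("group_summary", "data.frame"))
}

.detected_values <- function(matrix, j) {
  matrix$values[, j][matrix$detected[, j]]
}

#' Per-gene differential expression between two matrices
#'
#' Two-sided tests on log2 levels of detected cells (minimum 2 detected
#' cells per side, otherwise the p-value is marked missing), plus level and
#' frequency differences (B minus A). No multiple-testing correction by
#' default, with an optional Benjamini-Hochberg adjustment.
#'
#' @param matrixA,matrixB Log2-scale [expr_matrix()] objects sharing a gene
#'   panel.
#' @param test `student_t` (pooled-variance two-sample t), `anova` (one-way,
#'   identical to t via F = t^2 for two groups), or `mann_whitney`.
#' @param alpha Significance level for the flag (default 0.05).
#' @param adjust P-value adjustment method (`"none"` or `"BH"`).
#' @return Data frame: `gene`, `delta_level`, `delta_frequency`, `p_value`,
#'   `significant`.
#' @export
differential_expression <- function(matrixA, matrixB,
                                    test = c("student_t", "anova",
                                             "mann_whitney"),
                                    alpha = 0.05, adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(inherits(matrixA, "expr_matrix"), inherits(matrixB, "expr_matrix"))
  assert_that(identical(matrixA$genes$gene, matrixB$genes$gene),
              "matrices must share the same gene panel")
  genes <- matrixA$genes$gene
  out <- data.frame(gene = genes, delta_level = NA_real_,
                    delta_frequency = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(genes)) {
    a <- .detected_values(matrixA, j)
    b <- .detected_values(matrixB, j)
    out$delta_frequency[j] <- mean(matrixB$detected[, j]) -
      mean(matrixA$detected[, j])
    if (length(a) > 0L && length(b) > 0L) {
      out$delta_level[j] <- mean(b) - mean(a)
    }
    if (length(a) >= 2L && length(b) >= 2L) {
      out$p_value[j] <- switch(test,
        student_t = stats::t.test(a, b, var.equal = TRUE)$p.value,
        anova = {
          v <- c(a, b)
          grp <- factor(rep(c("A", "B"), c(length(a), length(b))))
          stats::anova(stats::lm(v ~ grp))[["Pr(>F)"]][1]
        },
        mann_whitney = stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
  }
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Stratified mean-vs-mean comparison with a significance area
#'
#' For each stratum and gene, pairs the reference mean log2 level with the
#' stratum mean and flags genes lying outside the significance area — the
#' region where a two-sided Student t-test on detected cells is
#' non-significant at `alpha`. Used to compare e.g. marker-low cells of an
#' activated condition against control cells.
#'
#' @param reference A log2-scale [expr_matrix()] (the reference group's
#'   cells).
#' @param strata Named list of log2-scale [expr_matrix()] objects, one per
#'   stratum.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `stratum`, `gene`, `reference_level`,
#'   `stratum_level`, `p_value`, `outside`.
#' @export
stratified_mean_scatter <- function(reference, strata, alpha = 0.05) {
  stopifnot(inherits(reference, "expr_matrix"))
  nm <- names(strata) %||% paste0("stratum", seq_along(strata))
  parts <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    assert_that(nrow(s$values) >= 2L,
                sprintf("stratum '%s' has fewer than 2 cells", nm[i]))
    de <- differential_expression(reference, s, test = "student_t",
                                  alpha = alpha)
    ref_sum <- summarize_groups(reference,
                                rep("ref", nrow(reference$values)))
    str_sum <- summarize_groups(s, rep("s", nrow(s$values)))
    data.frame(stratum = nm[i], gene = de$gene,
               reference_level = ref_sum$level[match(de$gene, ref_sum$gene)],
               stratum_level = str_sum$level[match(de$gene, str_sum$gene)],
               p_value = de$p_value, outside = de$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Mixture-fit configuration
#'
#' @param n_restarts EM restarts for the two-component fit (default 10; the
#'   first start splits at the median, the rest use seeded random
#'   responsibilities).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param sd_floor Lower bound on component standard deviations (default
#'   1e-3).
#' @param min_n Minimum number of detected values (default 10).
#' @param seed RNG seed for the random restarts.
#' @return A `mixture_config` list.
#' @export
mixture_config <- function(n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                           sd_floor = 1e-3, min_n = 10L, seed = 1L) {
  structure(list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 sd_floor = sd_floor, min_n = min_n, seed = seed),
            class = "mixture_config")
}

.gauss_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(c)
    w[c] * stats::dnorm(x, mu[c], sd[c]), numeric(length(x)))
  sum(log(rowSums(as.matrix(dens))))
}

.em_two_gauss <- function(x, resp, cfg) {
  n <- length(x)
  ll_old <- -Inf
  w <- mu <- sd <- NULL
  converged <- FALSE
  for (iter in seq_len(cfg$max_iter)) {
    # M step
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sd <- pmax(sd, cfg$sd_floor)
    # E step
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    resp <- cbind(d1 / tot, d2 / tot)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < cfg$tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = ll_old, converged = converged)
}

#' Fit a one- vs two-component Gaussian mixture to expression levels
#'
#' Models the log2 expression of detected cells as either a single Gaussian
#' (closed form) or a sum of two Gaussians (EM with restarts), selecting the
#' number of components by BIC. For a two-component fit the low/high
#' boundary is the point between the sorted means where the posterior
#' responsibility crosses 0.5. Non-detects are excluded: the histogram being
#' modelled is of expression levels.
#'
#' @param values Numeric vector of per-cell log2 expression (detected cells
#'   of one gene in one group).
#' @param config A [mixture_config()].
#' @return A `mixture_fit`: `k`, `weights`, `means`, `sds` (means sorted
#'   ascending), `bic` (both candidates), `loglik`, `boundary` (k = 2 only),
#'   `converged`.
#' @export
fit_bimodal <- function(values, config = mixture_config()) {
  x <- values[is.finite(values)]
  n <- length(x)
  assert_that(n >= config$min_n,
              sprintf("need at least %d detected values, got %d",
                      config$min_n, n))
  # k = 1: closed-form maximum likelihood
  mu1 <- mean(x)
  sd1 <- max(sqrt(mean((x - mu1)^2)), config$sd_floor)
  ll1 <- sum(stats::dnorm(x, mu1, sd1, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  # k = 2: EM with restarts
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  best <- NULL
  any_converged <- FALSE
  for (r in seq_len(config$n_restarts)) {
    resp <- if (r == 1L) {
      # k-means-style init: split at the median
      cbind(as.numeric(x <= stats::median(x)), as.numeric(x > stats::median(x)))
    } else {
      p <- stats::runif(n)
      cbind(p, 1 - p)
    }
    fit <- .em_two_gauss(x, resp, config)
    any_converged <- any_converged || fit$converged
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!any_converged) {
    warning("EM did not converge in any restart; best likelihood kept",
            call. = FALSE)
  }
  ll2 <- best$loglik
  bic2 <- -2 * ll2 + 5 * log(n)
  ord <- order(best$mu)
  w2 <- best$w[ord]; mu2 <- best$mu[ord]; s2 <- best$sd[ord]
  k <- if (bic2 < bic1 && diff(mu2) > .Machine$double.eps^0.5) 2L else 1L
  boundary <- NA_real_
  if (k == 2L) {
    post_diff <- function(v) {
      w2[2] * stats::dnorm(v, mu2[2], s2[2]) -
        w2[1] * stats::dnorm(v, mu2[1], s2[1])
    }
    boundary <- if (post_diff(mu2[1]) < 0 && post_diff(mu2[2]) > 0) {
      stats::uniroot(post_diff, c(mu2[1], mu2[2]))$root
    } else mean(mu2)
  }
  structure(list(k = k,
                 weights = if (k == 2L) w2 else 1,
                 means = if (k == 2L) mu2 else mu1,
                 sds = if (k == 2L) s2 else sd1,
                 bic = c(k1 = bic1, k2 = bic2),
                 loglik = if (k == 2L) ll2 else ll1,
                 boundary = boundary,
                 converged = any_converged,
                 n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit: k =", x$k, "(BIC k1 =",
      sprintf("%.2f", x$bic["k1"]), ", k2 =", sprintf("%.2f", x$bic["k2"]),
      ")\n")
  comp <- data.frame(weight = x$weights, mean = x$means, sd = x$sds)
  print(comp, digits = 4)
  if (x$k == 2L) cat("low/high boundary:", sprintf("%.3f", x$boundary), "\n")
  invisible(x)
}

#' Stratify cells into low/high expressors of a bimodal gene
#'
#' Detected cells below the mixture boundary go to the low stratum, cells at
#' or above it to the high stratum; non-detect cells are low.
#'
#' @param matrix A log2-scale [expr_matrix()].
#' @param gene The bimodal gene.
#' @param fit A two-component [fit_bimodal()] result.
#' @return A [subgroup_assignment()] (method `manual_split`) with labels
#'   `low` / `high`.
#' @export
stratify_by_gene <- function(matrix, gene, fit) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(fit, "mixture_fit"))
  assert_that(fit$k == 2L, "no bimodal structure (k = 1 fit)")
  j <- match(gene, matrix$genes$gene)
  assert_that(!is.na(j), paste0("gene not in matrix: ", gene))
  high <- matrix$detected[, j] & !is.na(matrix$values[, j]) &
    matrix$values[, j] >= fit$boundary
  labels <- ifelse(high, "high", "low")
  names(labels) <- matrix$cells$cell_id
  subgroup_assignment(labels, "manual_split")
}
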