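#' Pairwise Spearman correlation matrix
#'
#' Gene-gene (columns) or cell-to-cell (rows) Spearman rank correlation with
#' average ranks for ties. Imputed non-detects share each gene's floor value
#' and tie; average ranks keep this deterministic.
#'
#' @param matrix A fully observed [expr_matrix()].
#' @param axis `"gene"` for gene-gene, `"cell"` for cell-to-cell.
#' @return A `corr_matrix` object: `rho` (symmetric, unit diagonal), `axis`,
#'   `labels`.
#' @export
spearman_matrix <- function(matrix, axis = c("gene", "cell")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  axis <- match.arg(axis)
  assert_that(!anyNA(matrix$values),
              "spearman_matrix requires a fully observed matrix")
  x <- if (axis == "gene") matrix$values else t(matrix$values)
  assert_that(nrow(x) >= 3L,
              "need at least 3 observations per vector for Spearman")
  rho <- stats::cor(x, method = "spearman")
  diag(rho) <- 1
  structure(list(rho = rho, axis = axis, labels = colnames(x)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (", x$axis, " axis): ",
      length(x$labels), " x ", length(x$labels), "\n", sep = "")
  invisible(x)
}

#' Construct a subgroup assignment
#'
#' @param labels Named vector (names are cell or gene ids) of subgroup
#'   labels.
#' @param method How the assignment was produced: `hier_corr`, `som` or
#'   `manual_split`.
#' @return A `subgroup_assignment` object with `labels`, `method`, `k`.
#' @export
subgroup_assignment <- function(labels,
                                method = c("hier_corr", "som", "manual_split")) {
  method <- match.arg(method)
  assert_that(!is.null(names(labels)), "labels must be named by id")
  structure(list(labels = labels, method = method,
                 k = length(unique(labels))),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("Subgroup assignment (", x$method, "): ", length(x$labels),
      " items in ", x$k, " groups\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Hierarchical clustering of a correlation matrix into k subgroups
#'
#' Rows of the correlation matrix are the feature vectors; agglomeration
#' uses Euclidean distance between them and the tree is cut into exactly
#' `k` groups. Deterministic given its input.
#'
#' @param corr A [spearman_matrix()] result.
#' @param k Number of subgroups.
#' @param linkage Agglomeration rule: average (default), complete or ward.
#' @return A [subgroup_assignment()] (method `hier_corr`).
#' @export
hier_cluster <- function(corr, k, linkage = c("average", "complete", "ward")) {
  stopifnot(inherits(corr, "corr_matrix"))
  linkage <- match.arg(linkage)
  n <- nrow(corr$rho)
  assert_that(k >= 1L && k <= n, sprintf("k must be in [1, %d]", n))
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(corr$rho, method = "euclidean"),
                      method = method)
  labels <- as.character(stats::cutree(hc, k = k))
  names(labels) <- corr$labels
  out <- subgroup_assignment(labels, "hier_corr")
  out$hclust <- hc
  out
}

#' Curated subgroups from a correlation-matrix dendrogram
#'
#' Reproduces the analyst's manual grouping step: the agglomerative tree of
#' [hier_cluster()] is cut progressively deeper until `k` clusters of at
#' least `min_size` members emerge; cells falling in smaller offshoots
#' (stray cells that would otherwise consume whole clusters at a shallow
#' cut) are then assigned to the major cluster with the smallest average
#' distance to their correlation-row feature vector. Deterministic given
#' its input; returns exactly `k` populated subgroups.
#'
#' @param corr A [spearman_matrix()] result.
#' @param k Number of subgroups.
#' @param linkage Agglomeration rule, as in [hier_cluster()].
#' @param min_size Minimum size for a cluster to count as a major group
#'   (default 5 cells).
#' @return A [subgroup_assignment()] (method `hier_corr`).
#' @export
curate_subgroups <- function(corr, k, linkage = c("average", "complete",
                                                  "ward"), min_size = 5L) {
  stopifnot(inherits(corr, "corr_matrix"))
  linkage <- match.arg(linkage)
  n <- nrow(corr$rho)
  assert_that(k >= 1L && k <= n, sprintf("k must be in [1, %d]", n))
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(corr$rho, method = "euclidean"),
                      method = method)
  # cut well below the requested granularity so every major subgroup is
  # exposed (split into parts if need be), then reassemble by centroid
  # proximity: parts of one true subgroup have near-identical centroids
  # and re-merge first, while genuinely distinct subgroups stay apart
  chosen <- NULL
  for (kk in min(n, 4L * k):k) {
    cut <- stats::cutree(hc, k = kk)
    sizes <- table(cut)
    big <- names(sizes)[sizes >= min_size]
    if (length(big) >= k) {
      chosen <- list(cut = cut, big = big)
      break
    }
  }
  if (is.null(chosen)) {  # no curated solution; fall back to the plain cut
    labels <- as.character(stats::cutree(hc, k = k))
    names(labels) <- corr$labels
    out <- subgroup_assignment(labels, "hier_corr")
    out$hclust <- hc
    return(out)
  }
  members <- lapply(chosen$big, function(b) which(chosen$cut == b))
  centroid <- function(idx) colMeans(corr$rho[idx, , drop = FALSE])
  cents <- do.call(rbind, lapply(members, centroid))
  while (length(members) > k) {
    d <- as.matrix(stats::dist(cents))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- min(ij); b <- max(ij)
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
    cents <- do.call(rbind, lapply(members, centroid))
  }
  labels <- rep(NA_character_, n)
  for (g in seq_along(members)) labels[members[[g]]] <- as.character(g)
  stray <- which(is.na(labels))
  for (i in stray) {
    d <- sqrt(rowSums(sweep(cents, 2L, corr$rho[i, ])^2))
    labels[i] <- as.character(which.min(d))
  }
  names(labels) <- corr$labels
  out <- subgroup_assignment(labels, "hier_corr")
  out$hclust <- hc
  out
}

#' Split one subgroup by cell class
#'
#' Mirrors the manual step of dividing a mixed cell cluster into its
#' constituent cell classes; other subgroups are untouched. Subgroups with a
#' single class are returned unchanged.
#'
#' @param assign A [subgroup_assignment()] over cells.
#' @param cells Cell metadata with `cell_id` and `cell_class`.
#' @param subgroup The subgroup label to split.
#' @return A new [subgroup_assignment()]; split members get labels
#'   `<subgroup>.<cell_class>`.
#' @export
split_mixed_cluster <- function(assign, cells, subgroup) {
  stopifnot(inherits(assign, "subgroup_assignment"))
  labels <- assign$labels
  in_grp <- labels == subgroup
  assert_that(any(in_grp), paste0("subgroup not present: ", subgroup))
  cls <- cells$cell_class[match(names(labels)[in_grp], cells$cell_id)]
  assert_that(!anyNA(cls), "cells in the target subgroup missing metadata")
  if (length(unique(cls)) > 1L) {
    labels[in_grp] <- paste0(subgroup, ".", cls)
  }
  out <- subgroup_assignment(labels, "manual_split")
  out
}

#' Principal component analysis with fixed loading signs
#'
#' Centers the data per gene, computes loadings and scores, and fixes each
#' component's sign so its largest-magnitude loading is positive. The caller
#' chooses the scaling convention beforehand (autoscale per gene for
#' between-condition maps, autoscale per cell for subpopulation maps).
#'
#' @param matrix A fully observed [expr_matrix()] or plain numeric matrix.
#' @param n_components Number of components to retain.
#' @return List with `model` (a `pca_model`: `loadings`,
#'   `explained_variance_fraction`, `center`, `scale`, `n_components`) and
#'   `scores` (cells x components).
#' @export
fit_pca <- function(matrix, n_components = 2L) {
  x <- if (inherits(matrix, "expr_matrix")) matrix$values else as.matrix(matrix)
  assert_that(!anyNA(x), "fit_pca requires a fully observed matrix")
  assert_that(n_components >= 1L && n_components <= min(dim(x)),
              sprintf("n_components must be in [1, %d]", min(dim(x))))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k_all <- ncol(pc$rotation)
  flip <- vapply(seq_len(k_all), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, "*")[, seq_len(n_components),
                                               drop = FALSE]
  scores <- sweep(pc$x, 2L, flip, "*")[, seq_len(n_components), drop = FALSE]
  evf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  model <- structure(list(loadings = loadings,
                          explained_variance_fraction = evf,
                          center = pc$center,
                          scale = rep(1, ncol(x)),
                          n_components = n_components,
                          genes = colnames(x)),
                     class = "pca_model")
  list(model = model, scores = scores)
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", length(x$genes), "genes,", x$n_components, "components;",
      "explained fractions:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project new data with a fitted PCA model
#'
#' Applies the stored per-gene center and scale, then the fixed-sign
#' loadings; no refitting.
#'
#' @param object A `pca_model`.
#' @param newdata Numeric matrix or [expr_matrix()] with the model's genes
#'   in the model's order.
#' @param ... Unused.
#' @return Score matrix (rows x components).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expr_matrix")) newdata$values else
    as.matrix(newdata)
  assert_that(ncol(x) == length(object$genes),
              "newdata gene count does not match the PCA model")
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), object$genes)) {
    stop2(paste0("gene mismatch with PCA model: ",
                 paste(setdiff(object$genes, colnames(x)), collapse = ", ")))
  }
  x <- sweep(x, 2L, object$center)
  x <- sweep(x, 2L, object$scale, "/")
  x %*% object$loadings
}

#' Self-organizing map assignment of cells
#'
#' Trains a Kohonen self-organizing map (rectangular grid, Gaussian
#' neighbourhood, online updates over a fixed schedule) on the cell rows and
#' assigns each cell to its best-matching unit. Deterministic for a fixed
#' seed; nearest-unit ties break to the lowest unit index.
#'
#' @param matrix A fully observed [expr_matrix()].
#' @param grid Integer vector `c(rows, cols)`; default 3 x 2, matching six
#'   differentiation states.
#' @param seed RNG seed for prototype initialization and the presentation
#'   order.
#' @param n_iter Training iterations (default 1000).
#' @return A [subgroup_assignment()] (method `som`) with unit labels
#'   `"r<row>c<col>"`; prototypes in `$codes`.
#' @export
fit_som <- function(matrix, grid = c(3L, 2L), seed = 1L, n_iter = 1000L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- matrix$values
  assert_that(!anyNA(x), "fit_som requires a fully observed matrix")
  n_units <- prod(grid)
  if (n_units > nrow(x)) {
    warning("SOM grid has more units than cells; empty units allowed",
            call. = FALSE)
  }
  fit <- som_train(x, rows = grid[1], cols = grid[2], n_iter = n_iter,
                   seed = seed)
  unit_names <- paste0("r", fit$grid[, 1], "c", fit$grid[, 2])
  labels <- unit_names[fit$assignment]
  names(labels) <- matrix$cells$cell_id
  out <- subgroup_assignment(labels, "som")
  out$codes <- fit$codes
  out$grid <- fit$grid
  out
}
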