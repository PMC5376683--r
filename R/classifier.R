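#' Fit the reference PCA space with per-state centroids
#'
#' Fits a PCA on per-cell-autoscaled, fully observed reference cells and
#' places one centroid per differentiation state at the mean of that state's
#' scores in the first `n_pcs` components. New cells are later projected
#' into this space and assigned to the nearest centroid.
#'
#' @param matrix A per-cell autoscaled, fully observed [expr_matrix()].
#' @param cell_states Named character vector mapping every cell id to its
#'   state label.
#' @param state_order Character vector of states in timeline order (used for
#'   deterministic tie-breaking toward the earlier state).
#' @param n_pcs Number of principal components (default 3: the first two
#'   components carry the activation and matrix-remodelling axes, the third
#'   the stem/pluripotency axis).
#' @return A `reference_space`: `pca`, `centroids` (state x n_pcs),
#'   `n_pcs`, `state_order`, `genes`.
#' @export
fit_reference <- function(matrix, cell_states, state_order, n_pcs = 3L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  ids <- matrix$cells$cell_id
  st <- cell_states[match(ids, names(cell_states))]
  assert_that(!anyNA(st), "every cell must be labelled with a state")
  assert_that(all(st %in% state_order), "cell states must appear in state_order")
  tab <- table(st)
  small <- names(tab)[tab < 2L]
  assert_that(length(small) == 0L,
              paste0("state(s) with < 2 cells: ", paste(small, collapse = ", ")))
  fit <- fit_pca(matrix, n_components = n_pcs)
  rank_ok <- fit$model$explained_variance_fraction > .Machine$double.eps^0.5
  assert_that(all(rank_ok), "n_pcs exceeds the rank of the data")
  states <- intersect(state_order, unique(st))
  centroids <- do.call(rbind, lapply(states, function(s)
    colMeans(fit$scores[st == s, , drop = FALSE])))
  rownames(centroids) <- states
  structure(list(pca = fit$model, centroids = centroids, n_pcs = n_pcs,
                 state_order = states, genes = matrix$genes$gene),
            class = "reference_space")
}

#' @export
print.reference_space <- function(x, ...) {
  cat("Reference space:", length(x$genes), "genes,", x$n_pcs,
      "components,", nrow(x$centroids), "state centroids\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Classify cells by projection into a reference space
#'
#' Test cells (already autoscaled per cell with their own statistics) are
#' projected with the reference center, scale and loadings — no refit — and
#' assigned to the nearest state centroid by Euclidean distance in the
#' reference components. Distance ties break toward the earlier timeline
#' state.
#'
#' @param space A [fit_reference()] result.
#' @param test A per-cell autoscaled [expr_matrix()] on the reference gene
#'   panel, genes in reference order.
#' @return A `classification_result`: `cells` (data frame with `cell_id`,
#'   `cell_class`, `state`, score coordinates), `distances` (cells x
#'   states), `space`.
#' @export
classify_cells <- function(space, test) {
  stopifnot(inherits(space, "reference_space"), inherits(test, "expr_matrix"))
  if (!identical(test$genes$gene, space$genes)) {
    diffs <- union(setdiff(space$genes, test$genes$gene),
                   setdiff(test$genes$gene, space$genes))
    stop2(paste0("gene mismatch with reference: ",
                 if (length(diffs)) paste(diffs, collapse = ", ")
                 else "gene order differs"))
  }
  scores <- predict(space$pca, test)
  cent <- space$centroids
  d <- sqrt(outer(rowSums(scores^2), rowSums(cent^2), "+") -
              2 * scores %*% t(cent))
  d[!is.finite(d) | d < 0] <- 0
  # ties break toward the earlier timeline state: centroids are stored in
  # timeline order and which.min returns the first minimum
  assigned <- space$state_order[apply(d, 1L, which.min)]
  cells <- data.frame(cell_id = test$cells$cell_id,
                      cell_class = test$cells$cell_class,
                      state = assigned, stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(scores))
  colnames(d) <- space$state_order
  rownames(d) <- test$cells$cell_id
  structure(list(cells = cells, distances = d, space = space),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Classification of", nrow(x$cells), "cells:\n")
  print(table(x$cells$cell_class, x$cells$state))
  invisible(x)
}

#' Cohort summary of a classification
#'
#' Per cell class: the frequency of each assigned state (summing to 1 within
#' a class) and the mean distance to the assigned centroid.
#'
#' @param result A [classify_cells()] result.
#' @return Data frame: `cell_class`, `state`, `n`, `frequency`,
#'   `mean_distance`.
#' @export
cohort_report <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  assert_that(nrow(result$cells) > 0L, "empty classification result")
  cells <- result$cells
  dmin <- result$distances[cbind(seq_len(nrow(cells)),
                                 match(cells$state,
                                       colnames(result$distances)))]
  out <- expand.grid(cell_class = unique(cells$cell_class),
                     state = result$space$state_order,
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(cc, s) sum(cells$cell_class == cc & cells$state == s),
                  out$cell_class, out$state)
  class_n <- table(cells$cell_class)
  out$frequency <- out$n / as.integer(class_n[out$cell_class])
  out$mean_distance <- mapply(function(cc, s) {
    sel <- cells$cell_class == cc & cells$state == s
    if (any(sel)) mean(dmin[sel]) else NA_real_
  }, out$cell_class, out$state)
  out
}
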