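#' Preprocessing configuration
#'
#' @param cq_cutoff Off-scale Cq limit (cycles). Relative quantity is
#'   2^(cq_cutoff - Cq), so a reaction at the cutoff has RQ 1; reactions with
#'   Cq above the cutoff are treated as non-detects. Default 28 cycles, a
#'   conventional bound for pre-amplified single-cell qPCR.
#' @param min_gapdh_positivity Minimum fraction of GAPDH-positive cells for
#'   the sort-efficiency gate to pass (default 0.80).
#' @param imputation_offset How far below a gene's minimum detected log2
#'   value non-detects are imputed, in log2 units (default 1.0).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cq_cutoff = 28, min_gapdh_positivity = 0.80,
                              imputation_offset = 1.0) {
  assert_that(is_scalar_number(cq_cutoff) && cq_cutoff > 0,
              "cq_cutoff must be > 0")
  assert_that(is_scalar_number(min_gapdh_positivity) &&
                min_gapdh_positivity > 0 && min_gapdh_positivity <= 1,
              "min_gapdh_positivity must be in (0, 1]")
  assert_that(is_scalar_number(imputation_offset) && imputation_offset >= 0,
              "imputation_offset must be >= 0")
  structure(list(cq_cutoff = cq_cutoff,
                 min_gapdh_positivity = min_gapdh_positivity,
                 imputation_offset = imputation_offset),
            class = "preprocess_config")
}

#' Convert Cq cycles to linear relative quantities
#'
#' RQ = 2^(cq_cutoff - Cq) for detected reactions; reactions with Cq above
#' the cutoff are re-flagged as non-detects. Non-detects get RQ exactly 0.
#' No reference-gene normalization is performed; expression is per cell.
#'
#' @param plate A [cq_plate()].
#' @param config A [preprocess_config()].
#' @return An [expr_matrix()] on the `linear_rq` scale.
#' @export
cq_to_rq <- function(plate, config = preprocess_config()) {
  stopifnot(inherits(plate, "cq_plate"))
  cq <- plate$cq
  det <- plate$detected & !is.na(cq) & cq <= config$cq_cutoff
  rq <- matrix(0, nrow(cq), ncol(cq))
  rq[det] <- 2^(config$cq_cutoff - cq[det])
  genes <- data.frame(gene = plate$assays,
                      group = panel_group(plate$panel, plate$assays),
                      stringsAsFactors = FALSE)
  expr_matrix(rq, det, plate$cells, genes, "linear_rq",
              provenance = sprintf("cq_to_rq(cutoff=%g)", config$cq_cutoff))
}

#' GAPDH positivity gate
#'
#' Sort efficiency is monitored through GAPDH: only GAPDH-positive cells are
#' kept for downstream analysis, and the per-plate positivity fraction is
#' checked against the configured bar (>80% by default).
#'
#' @param matrix An [expr_matrix()].
#' @param config A [preprocess_config()].
#' @return List with `matrix` (GAPDH-positive cells only) and `report`
#'   (`n_total`, `n_positive`, `positivity`, `pass`).
#' @export
qc_gapdh_gate <- function(matrix, config = preprocess_config()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  gi <- match("GAPDH", matrix$genes$gene)
  assert_that(!is.na(gi), "GAPDH column absent from matrix")
  keep <- matrix$detected[, gi]
  n_total <- length(keep)
  positivity <- if (n_total == 0L) NA_real_ else mean(keep)
  pass <- isTRUE(positivity > config$min_gapdh_positivity)
  if (!pass) {
    warning(sprintf("GAPDH positivity %.3f below gate %.2f",
                    positivity, config$min_gapdh_positivity), call. = FALSE)
  }
  gated <- expr_matrix(matrix$values[keep, , drop = FALSE],
                       matrix$detected[keep, , drop = FALSE],
                       matrix$cells[keep, , drop = FALSE],
                       matrix$genes, matrix$scale,
                       c(matrix$provenance, "qc_gapdh_gate"))
  list(matrix = gated,
       report = list(n_total = n_total, n_positive = sum(keep),
                     positivity = positivity, pass = pass))
}

#' Log2-transform a linear RQ matrix
#'
#' Detected entries become log2(RQ). With `impute = TRUE`, each gene's
#' non-detects are set one `imputation_offset` below that gene's minimum
#' detected log2 value (genes with no detected cells are imputed at 0) and
#' the scale becomes `log2_rq_imputed`; the detection mask is unchanged, so
#' frequency statistics are unaffected. Without imputation non-detects stay
#' `NA` (`log2_rq`). Imputed matrices feed the multivariate steps (PCA,
#' correlation, clustering, SOM); level statistics always use detected cells
#' only through the mask.
#'
#' @param matrix An [expr_matrix()] on the `linear_rq` scale.
#' @param impute Impute non-detects below the per-gene detected floor?
#' @param config A [preprocess_config()].
#' @return An [expr_matrix()] on the `log2_rq` or `log2_rq_imputed` scale.
#' @export
to_log2 <- function(matrix, impute = TRUE, config = preprocess_config()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  assert_that(matrix$scale == "linear_rq",
              paste0("to_log2 expects linear_rq input, got ", matrix$scale))
  v <- matrix$values
  det <- matrix$detected
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[det] <- log2(v[det])
  if (impute) {
    for (j in seq_len(ncol(out))) {
      nd <- !det[, j]
      if (!any(nd)) next
      floor_j <- if (any(det[, j])) {
        min(out[det[, j], j]) - config$imputation_offset
      } else 0
      out[nd, j] <- floor_j
    }
  }
  expr_matrix(out, det, matrix$cells, matrix$genes,
              if (impute) "log2_rq_imputed" else "log2_rq",
              c(matrix$provenance,
                if (impute) sprintf("to_log2(impute, offset=%g)",
                                    config$imputation_offset) else "to_log2"))
}

.scale_columns <- function(v, center_only) {
  mu <- colMeans(v)
  out <- sweep(v, 2L, mu)
  if (!center_only) {
    s <- apply(v, 2L, stats::sd)
    const <- s == 0 | !is.finite(s)
    if (any(const)) {
      warning(sprintf("%d constant column(s) mapped to zeros", sum(const)),
              call. = FALSE)
      s[const] <- 1
      out[, const] <- 0
    }
    out <- sweep(out, 2L, s, "/")
  }
  out
}

#' Autoscale per gene (column z-score)
#'
#' Each gene column is standardized to mean 0 and sample (n-1) standard
#' deviation 1 — the convention for PCA of cells. Constant columns become
#' all-zero with a warning.
#'
#' @param matrix A fully observed (imputed) log-scale [expr_matrix()].
#' @return An [expr_matrix()] on the `autoscaled_by_gene` scale.
#' @export
autoscale_by_gene <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  assert_that(!anyNA(matrix$values),
              "autoscale_by_gene requires a fully observed (imputed) matrix")
  out <- .scale_columns(matrix$values, center_only = FALSE)
  expr_matrix(out, matrix$detected, matrix$cells, matrix$genes,
              "autoscaled_by_gene", c(matrix$provenance, "autoscale_by_gene"))
}

#' Autoscale per cell (row z-score, global normalization)
#'
#' Each cell's expression vector is standardized to mean 0 and sample SD 1
#' across genes, removing cell-to-cell differences in global RNA level.
#'
#' @param matrix A fully observed (imputed) log-scale [expr_matrix()].
#' @return An [expr_matrix()] on the `autoscaled_by_cell` scale.
#' @export
autoscale_by_cell <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  assert_that(!anyNA(matrix$values),
              "autoscale_by_cell requires a fully observed (imputed) matrix")
  out <- t(.scale_columns(t(matrix$values), center_only = FALSE))
  expr_matrix(out, matrix$detected, matrix$cells, matrix$genes,
              "autoscaled_by_cell", c(matrix$provenance, "autoscale_by_cell"))
}

#' Mean-center per gene
#'
#' Subtracts each gene's mean across cells; variances are untouched. The
#' convention for unsupervised clustering heatmaps.
#'
#' @param matrix A log-scale [expr_matrix()] without missing values.
#' @return An [expr_matrix()] on the `mean_centered_by_gene` scale.
#' @export
mean_center_by_gene <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  assert_that(!anyNA(matrix$values),
              "mean_center_by_gene requires a fully observed matrix")
  out <- .scale_columns(matrix$values, center_only = TRUE)
  expr_matrix(out, matrix$detected, matrix$cells, matrix$genes,
              "mean_centered_by_gene",
              c(matrix$provenance, "mean_center_by_gene"))
}

#' Combine datasets by per-dataset mean-centering
#'
#' Each dataset is mean-centred per gene independently, restricted to a
#' shared gene subset, and the rows are concatenated; the dataset of origin
#' is kept in the cell metadata. Used to place cell-line and patient-derived
#' cells on a common scale for joint PCA.
#'
#' @param datasets Named list of fully observed log-scale [expr_matrix()]
#'   objects.
#' @param genes Character vector of genes every dataset must contain.
#' @return An [expr_matrix()] on the `mean_centered_by_gene` scale with a
#'   `dataset` column in the cell metadata.
#' @export
combine_mean_centered <- function(datasets, genes) {
  assert_that(length(datasets) >= 1L, "need at least one dataset")
  nm <- names(datasets) %||% paste0("dataset", seq_along(datasets))
  nm[nm == ""] <- paste0("dataset", which(nm == ""))
  parts <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    m <- datasets[[i]]
    stopifnot(inherits(m, "expr_matrix"))
    missing <- setdiff(genes, m$genes$gene)
    assert_that(length(missing) == 0L,
                sprintf("dataset '%s' is missing gene(s): %s", nm[i],
                        paste(missing, collapse = ", ")))
    gi <- match(genes, m$genes$gene)
    sub <- expr_matrix(m$values[, gi, drop = FALSE],
                       m$detected[, gi, drop = FALSE],
                       m$cells, m$genes[gi, , drop = FALSE], m$scale,
                       m$provenance)
    cen <- mean_center_by_gene(sub)
    cen$cells$dataset <- nm[i]
    parts[[i]] <- cen
  }
  cells <- do.call(rbind, lapply(parts, function(p)
    p$cells[, c("cell_id", "sample_id", "cell_class", "dataset")]))
  expr_matrix(do.call(rbind, lapply(parts, `[[`, "values")),
              do.call(rbind, lapply(parts, `[[`, "detected")),
              cells, parts[[1]]$genes, "mean_centered_by_gene",
              c("combine_mean_centered"))
}
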