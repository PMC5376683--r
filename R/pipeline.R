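#' Pipeline configuration
#'
#' A single structured configuration for the end-to-end run. Can be built
#' programmatically or loaded from a YAML file whose keys mirror the
#' arguments.
#'
#' @param seed Master seed; the reference generator uses it directly and
#'   the patient generator uses `seed + 1000`.
#' @param k_clusters Number of cell subgroups cut from the cell-to-cell
#'   correlation tree (default 5).
#' @param linkage Agglomeration rule (default average).
#' @param split_min_fraction Minimum minority-class fraction for a subgroup
#'   to count as mixed and be split by cell class (default 0.1).
#' @param som_grid SOM grid `c(rows, cols)` (default 3 x 2).
#' @param som_iter SOM training iterations (default 1000).
#' @param n_pcs Reference-space components for classification (default 3).
#' @param bimodal_gene Gene examined for bimodality in the activated
#'   condition (default ACTA2).
#' @param alpha Significance level (default 0.05).
#' @param preprocess A [preprocess_config()].
#' @param mixture A [mixture_config()].
#' @param reference A [reference_config()]; its seed is overridden by
#'   `seed`.
#' @param patient A [patient_config()]; its seed is overridden by
#'   `seed + 1000`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, k_clusters = 5L, linkage = "average",
                            split_min_fraction = 0.1, som_grid = c(3L, 2L),
                            som_iter = 1000L, n_pcs = 3L,
                            bimodal_gene = "ACTA2", alpha = 0.05,
                            preprocess = preprocess_config(),
                            mixture = mixture_config(),
                            reference = reference_config(),
                            patient = patient_config()) {
  reference$seed <- seed
  patient$seed <- seed + 1000L
  mixture$seed <- seed
  structure(list(seed = seed, k_clusters = k_clusters, linkage = linkage,
                 split_min_fraction = split_min_fraction,
                 som_grid = som_grid, som_iter = som_iter, n_pcs = n_pcs,
                 bimodal_gene = bimodal_gene, alpha = alpha,
                 preprocess = preprocess, mixture = mixture,
                 reference = reference, patient = patient),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar keys (`seed`, `k_clusters`, `linkage`, `split_min_fraction`,
#' `som_grid`, `som_iter`, `n_pcs`, `bimodal_gene`, `alpha`) and the nested
#' `preprocess` / `mixture` blocks are mapped onto [pipeline_config()]
#' arguments; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "k_clusters", "linkage", "split_min_fraction",
             "som_grid", "som_iter", "n_pcs", "bimodal_gene", "alpha",
             "preprocess", "mixture")
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0L,
              paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  if (!is.null(raw$preprocess)) {
    raw$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$mixture)) raw$mixture <- do.call(mixture_config, raw$mixture)
  do.call(pipeline_config, raw)
}

.subgroup_conditions <- function(assign, cells) {
  vapply(sort(unique(assign$labels)), function(s) {
    cls <- cells$cell_class[match(names(assign$labels)[assign$labels == s],
                                  cells$cell_id)]
    maj <- names(sort(table(cls), decreasing = TRUE))[1]
    if (maj %in% c("control", "NF")) "normal" else "activated"
  }, character(1))
}

.find_mixed_subgroups <- function(assign, cells, min_fraction) {
  Filter(function(s) {
    cls <- cells$cell_class[match(names(assign$labels)[assign$labels == s],
                                  cells$cell_id)]
    tab <- table(cls)
    length(tab) > 1L && min(tab) / sum(tab) >= min_fraction
  }, sort(unique(assign$labels)))
}

# Deterministic counterpart of the analyst's manual subgrouping: if class
# splitting produced more than the expected number of subgroups per
# condition, the smallest surplus subgroup is merged into the same-condition
# subgroup with the nearest mean expression profile, until the expected
# counts remain.
.consolidate_subgroups <- function(assign, cells, matrix, n_per_condition = 3L) {
  labels <- assign$labels
  repeat {
    cond <- .subgroup_conditions(subgroup_assignment(labels, "manual_split"),
                                 cells)
    done <- TRUE
    for (cc in unique(cond)) {
      grps <- names(cond)[cond == cc]
      if (length(grps) <= n_per_condition) next
      done <- FALSE
      sizes <- vapply(grps, function(g) sum(labels == g), integer(1))
      small <- grps[which.min(sizes)]
      cent <- function(g) {
        rows <- match(names(labels)[labels == g], matrix$cells$cell_id)
        colMeans(matrix$values[rows, , drop = FALSE])
      }
      others <- setdiff(grps, small)
      d <- vapply(others, function(g) sqrt(sum((cent(g) - cent(small))^2)),
                  numeric(1))
      labels[labels == small] <- others[which.min(d)]
      break
    }
    if (done) break
  }
  subgroup_assignment(labels, "manual_split")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on synthetic (or supplied) plates
#'
#' Executes read/generate, quality gating, the transform chain, gene and
#' cell correlation, hierarchical subgrouping with mixed-cluster splitting,
#' per-subgroup summaries, differential expression, bimodality
#' stratification, the pseudo-temporal differentiation model, SOM
#' confirmation, reference-space training and patient classification, and
#' returns every intermediate object plus a run manifest. If `out_dir` is
#' given, key tables are written there and the manifest records their MD5
#' digests; deterministic stages are bit-identical across reruns of the same
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param reference Optional pre-generated `list(plate, truth)` (defaults to
#'   [generate_reference()] under the config).
#' @param patient Optional pre-generated patient `list(plate, truth)`.
#' @param out_dir Optional output directory.
#' @return A `pipeline_run` list; see details in the package vignette.
#' @export
run_pipeline <- function(config = pipeline_config(), reference = NULL,
                         patient = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- .stage("generate_reference",
                reference %||% generate_reference(config$reference))
  pat <- .stage("generate_patient",
                patient %||% generate_patient_cohort(config$patient))

  # preprocessing
  rq <- .stage("cq_to_rq", cq_to_rq(ref$plate, config$preprocess))
  gate <- .stage("qc_gapdh_gate", qc_gapdh_gate(rq, config$preprocess))
  log2m <- .stage("to_log2",
                  to_log2(gate$matrix, impute = FALSE,
                          config = config$preprocess))
  log2i <- .stage("to_log2_imputed",
                  to_log2(gate$matrix, impute = TRUE,
                          config = config$preprocess))

  # structure discovery
  corr_gene <- .stage("spearman_gene", spearman_matrix(log2i, "gene"))
  corr_cell <- .stage("spearman_cell", spearman_matrix(log2i, "cell"))
  assign5 <- .stage("curate_subgroups",
                    curate_subgroups(corr_cell, k = config$k_clusters,
                                     linkage = config$linkage))
  assign6 <- assign5
  mixed <- .find_mixed_subgroups(assign5, gate$matrix$cells,
                                 config$split_min_fraction)
  for (s in mixed) {
    assign6 <- .stage("split_mixed_cluster",
                      split_mixed_cluster(assign6, gate$matrix$cells, s))
  }
  assign6 <- .stage("consolidate_subgroups",
                    .consolidate_subgroups(assign6, gate$matrix$cells, log2i))
  cellscaled <- .stage("autoscale_by_cell", autoscale_by_cell(log2i))
  som <- .stage("fit_som",
                fit_som(cellscaled, grid = config$som_grid,
                        seed = config$seed, n_iter = config$som_iter))
  pca_genes <- .stage("fit_pca_genescaled",
                      fit_pca(autoscale_by_gene(log2i), n_components = 2L))

  # expression statistics
  summary6 <- .stage("summarize_groups", summarize_groups(log2m, assign6))
  is_caf <- gate$matrix$cells$cell_class %in% c("expCAF", "CAF")
  subm <- function(m, rows) expr_matrix(m$values[rows, , drop = FALSE],
                                        m$detected[rows, , drop = FALSE],
                                        m$cells[rows, , drop = FALSE],
                                        m$genes, m$scale, m$provenance)
  ctrl_m <- subm(log2m, !is_caf)
  caf_m <- subm(log2m, is_caf)
  diffexp <- .stage("differential_expression",
                    differential_expression(ctrl_m, caf_m,
                                            test = "student_t",
                                            alpha = config$alpha))
  gi <- match(config$bimodal_gene, log2m$genes$gene)
  caf_gene_vals <- caf_m$values[, gi][caf_m$detected[, gi]]
  bimodal <- .stage("fit_bimodal",
                    fit_bimodal(caf_gene_vals, config$mixture))
  strata <- NULL
  scatter <- NULL
  if (bimodal$k == 2L) {
    strata <- .stage("stratify_by_gene",
                     stratify_by_gene(caf_m, config$bimodal_gene, bimodal))
    low_rows <- is_caf
    low_rows[is_caf] <- strata$labels == "low"
    high_rows <- is_caf
    high_rows[is_caf] <- strata$labels == "high"
    scatter <- .stage("stratified_mean_scatter",
                      stratified_mean_scatter(ctrl_m,
                                              list(low = subm(log2m, low_rows),
                                                   high = subm(log2m, high_rows)),
                                              alpha = config$alpha))
  }

  # differentiation model
  states <- sort(unique(assign6$labels))
  profile <- .stage("pseudotemporal_profile",
                    pseudotemporal_profile(summary6, states))
  cond <- .subgroup_conditions(assign6, gate$matrix$cells)
  model <- .stage("label_states",
                  label_states(profile, ref$plate$panel, cond))
  model <- .stage("order_states", order_states(model))
  gene_clusters <- .stage("cluster_profiles", cluster_profiles(model$profile))

  # reference space + patient classification
  state_of_subgroup <- stats::setNames(model$states$label,
                                       model$states$state_id)
  cell_states <- stats::setNames(
    unname(state_of_subgroup[assign6$labels]), names(assign6$labels))
  space <- .stage("fit_reference",
                  fit_reference(cellscaled, cell_states,
                                state_order = model$states$label,
                                n_pcs = config$n_pcs))
  pat_rq <- .stage("patient_cq_to_rq", cq_to_rq(pat$plate, config$preprocess))
  pat_gate <- .stage("patient_qc", qc_gapdh_gate(pat_rq, config$preprocess))
  pat_log2i <- .stage("patient_log2",
                      to_log2(pat_gate$matrix, impute = TRUE,
                              config = config$preprocess))
  pat_scaled <- .stage("patient_autoscale", autoscale_by_cell(pat_log2i))
  classification <- .stage("classify_cells", classify_cells(space, pat_scaled))
  report <- .stage("cohort_report", cohort_report(classification))

  run <- list(config = config, reference = ref, patient = pat,
              qc = gate$report, patient_qc = pat_gate$report,
              log2 = log2m, log2_imputed = log2i, cellscaled = cellscaled,
              corr_gene = corr_gene, corr_cell = corr_cell,
              assign5 = assign5, assign6 = assign6, som = som,
              pca = pca_genes, summary = summary6, diffexp = diffexp,
              bimodal = bimodal, strata = strata, scatter = scatter,
              profile = profile, model = model,
              gene_clusters = gene_clusters, space = space,
              classification = classification, cohort = report)
  run$manifest <- .write_run(run, out_dir)
  class(run) <- "pipeline_run"
  run
}

.write_run <- function(run, out_dir) {
  manifest <- list(seed = run$config$seed,
                   patient_seed = run$config$patient$seed,
                   n_reference_cells = nrow(run$reference$plate$cq),
                   n_patient_cells = nrow(run$patient$plate$cq),
                   gapdh_positivity = run$qc$positivity,
                   stages = c("generate", "preprocess", "correlate",
                              "cluster", "som", "pca", "summarize",
                              "diffexp", "bimodal", "diffmodel", "classify"),
                   files = character())
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- c(
    wr(run$summary, "group_summary.tsv"),
    wr(run$diffexp, "differential_expression.tsv"),
    wr(data.frame(cell_id = names(run$assign6$labels),
                  subgroup = unname(run$assign6$labels)),
       "subgroups.tsv"),
    wr(run$model$states, "state_model.tsv"),
    wr(data.frame(gene = rownames(run$profile$score), run$profile$score,
                  check.names = FALSE), "pseudotemporal_profile.tsv"),
    wr(run$classification$cells, "patient_classification.tsv"),
    wr(run$cohort, "cohort_report.tsv"))
  manifest$files <- stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))
  manifest
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  reference: %d cells, GAPDH positivity %.3f\n",
              x$manifest$n_reference_cells, x$qc$positivity))
  cat("  subgroups:", x$assign6$k, "| states:",
      paste(x$model$states$label, collapse = " > "), "\n")
  cat(sprintf("  bimodal %s: k = %d\n", x$config$bimodal_gene, x$bimodal$k))
  cat("  patient cohort:\n")
  print(table(x$classification$cells$cell_class, x$classification$cells$state))
  invisible(x)
}
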