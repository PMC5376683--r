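VALID_CELL_CLASSES <- c("control", "expCAF", "NF", "CAF")

VALID_SCALES <- c("linear_rq", "log2_rq", "log2_rq_imputed", "autoscaled_by_gene",
                  "autoscaled_by_cell", "mean_centered_by_gene")

#' Construct a Cq plate
#'
#' A Cq plate holds the raw quantification cycles of a single-cell qPCR run:
#' one row per sorted cell, one column per gene assay. Non-detected reactions
#' (no amplification) are stored as `NA` with `detected = FALSE`.
#'
#' @param cq Numeric matrix (cells x assays) of Cq cycles; `NA` for
#'   non-detects. Detected values must be finite and positive.
#' @param cells Data frame with columns `cell_id`, `sample_id`, `cell_class`
#'   (one of control, expCAF, NF, CAF).
#' @param assays Character vector of gene symbols, one per column.
#' @param panel A [gene_panel()] the assays must resolve in.
#' @return A `cq_plate` object.
#' @export
cq_plate <- function(cq, cells, assays, panel) {
  cq <- as.matrix(cq)
  assert_that(nrow(cq) == nrow(cells), "cq rows must match cells metadata")
  assert_that(ncol(cq) == length(assays), "cq columns must match assays")
  assert_that(all(c("cell_id", "sample_id", "cell_class") %in% names(cells)),
              "cells must have cell_id, sample_id, cell_class")
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  assert_that(length(dup) == 0L,
              paste0("duplicate cell_id(s): ", paste(unique(dup), collapse = ", ")))
  bad_class <- setdiff(unique(cells$cell_class), VALID_CELL_CLASSES)
  assert_that(length(bad_class) == 0L,
              paste0("unknown cell_class value(s): ",
                     paste(bad_class, collapse = ", ")))
  missing_assay <- setdiff(assays, panel$gene)
  assert_that(length(missing_assay) == 0L,
              paste0("assay(s) not in panel: ",
                     paste(missing_assay, collapse = ", ")))
  det <- !is.na(cq)
  assert_that(all(is.finite(cq[det]) & cq[det] > 0),
              "detected Cq values must be finite and > 0")
  dimnames(cq) <- dimnames(det) <- list(cells$cell_id, assays)
  structure(list(cq = cq, detected = det, cells = as.data.frame(cells),
                 assays = assays, panel = panel),
            class = "cq_plate")
}

#' @export
print.cq_plate <- function(x, ...) {
  cat("Cq plate:", nrow(x$cq), "cells x", ncol(x$cq), "assays;",
      sprintf("%.1f%% reactions detected\n", 100 * mean(x$detected)))
  invisible(x)
}

#' Read a Cq plate from delimited text
#'
#' Expects a header row; the first three columns are `cell_id`, `sample_id`
#' and `cell_class`, the remaining columns are gene assays. Non-detects are
#' encoded as empty fields or a sentinel token ("ND", case-insensitive, by
#' default). The delimiter is auto-detected among tab and comma, preferring
#' tab.
#'
#' @param path Path to the file.
#' @param panel A [gene_panel()]; every assay column must resolve in it.
#' @param nd_tokens Sentinel strings marking a non-detect (case-insensitive);
#'   empty fields always count.
#' @param delim Optional explicit delimiter (`"\t"` or `","`).
#' @return A [cq_plate()].
#' @export
read_cq_plate <- function(path, panel, nd_tokens = c("ND", "NA"), delim = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, encoding = "UTF-8")
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           na.strings = NULL)
  meta_cols <- c("cell_id", "sample_id", "cell_class")
  assert_that(all(meta_cols %in% names(tab)[1:3]),
              "first columns must be cell_id, sample_id, cell_class")
  assays <- setdiff(names(tab), meta_cols)
  raw <- as.matrix(tab[, assays, drop = FALSE])
  is_nd <- raw == "" | toupper(trimws(raw)) %in% toupper(nd_tokens)
  cq <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(!is_nd & is.na(cq), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop2(sprintf("unparseable Cq value '%s' at row %d, column '%s'",
                  raw[bad[1, 1], bad[1, 2]], bad[1, 1], assays[bad[1, 2]]))
  }
  cq[is_nd] <- NA_real_
  cq_plate(cq, tab[, meta_cols], assays, panel)
}

#' Construct an expression matrix
#'
#' Cells x genes expression values on a declared scale, with a detection mask
#' and a provenance trail of the transforms applied. On the `linear_rq` scale
#' values are relative quantities (2^(cutoff - Cq)); non-detected entries are
#' exactly 0.
#'
#' @param values Numeric matrix (cells x genes).
#' @param detected Logical matrix of the same shape.
#' @param cells,genes Metadata data frames (cells: `cell_id`, `sample_id`,
#'   `cell_class`; genes: `gene`, `group`).
#' @param scale One of `r paste(VALID_SCALES, collapse = ", ")`.
#' @param provenance Character vector of transforms applied, in order.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, detected, cells, genes, scale,
                        provenance = character()) {
  values <- as.matrix(values)
  detected <- as.matrix(detected)
  assert_that(identical(dim(values), dim(detected)),
              "detection mask shape must equal value shape")
  assert_that(scale %in% VALID_SCALES, paste0("unknown scale: ", scale))
  assert_that(nrow(values) == nrow(cells), "values rows must match cells")
  assert_that(ncol(values) == nrow(genes), "values columns must match genes")
  if (scale == "linear_rq") {
    assert_that(all(values[!is.na(values)] >= 0),
                "linear_rq values must be >= 0")
    assert_that(all(values[!detected] == 0),
                "linear_rq values must be exactly 0 where not detected")
  }
  dimnames(values) <- dimnames(detected) <- list(cells$cell_id, genes$gene)
  structure(list(values = values, detected = detected,
                 cells = as.data.frame(cells), genes = as.data.frame(genes),
                 scale = scale, provenance = as.character(provenance)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes, scale =", x$scale, "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Write an expression matrix with a sidecar metadata record
#'
#' The values go to a TSV (full double precision); the scale, provenance,
#' gene groups and detection mask go to a JSON sidecar at `<path>.meta.json`.
#' `read_matrix(write_matrix(m))` restores `m` exactly.
#'
#' @param matrix An [expr_matrix()].
#' @param path Output TSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals), ncol = ncol(vals))
  chr[is.na(vals)] <- "NA"
  out <- cbind(matrix$cells[, c("cell_id", "sample_id", "cell_class")], chr)
  names(out) <- c("cell_id", "sample_id", "cell_class", matrix$genes$gene)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2(paste0("cannot write to ", path, ": ",
                                conditionMessage(ok)))
  meta <- list(scale = matrix$scale,
               provenance = as.list(matrix$provenance),
               genes = matrix$genes,
               detected = unname(apply(matrix$detected, 1L, as.logical,
                                       simplify = FALSE)),
               dataset = matrix$cells$dataset %||% NULL)
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}

#' Read an expression matrix written by [write_matrix()]
#'
#' @param path The TSV path given to [write_matrix()].
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path) {
  sidecar <- paste0(path, ".meta.json")
  assert_that(file.exists(path), paste0("file not found: ", path))
  assert_that(file.exists(sidecar), paste0("sidecar not found: ", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.data.frame(meta$genes)
  vals <- as.matrix(tab[, genes$gene, drop = FALSE])
  storage.mode(vals) <- "double"
  if (nrow(vals) == 0L) {
    det <- matrix(logical(0), nrow = 0L, ncol = nrow(genes))
  } else if (is.matrix(meta$detected)) {
    det <- meta$detected
    storage.mode(det) <- "logical"
  } else {
    det <- do.call(rbind, lapply(meta$detected, as.logical))
  }
  cells <- tab[, c("cell_id", "sample_id", "cell_class"), drop = FALSE]
  if (!is.null(meta$dataset)) cells$dataset <- meta$dataset
  expr_matrix(vals, det, cells, genes, meta$scale,
              unlist(meta$provenance) %||% character())
}
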