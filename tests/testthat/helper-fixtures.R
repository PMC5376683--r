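# Small in-code fixtures shared across the suite.

mini_panel <- function() {
  gene_panel(c("ACTA2", "COL1A1", "CAV1", "POU5F1", "GAPDH"),
             c("fibroblast", "fibroblast", "fibroblast", "pluripotency",
               "reference"))
}

# A tiny valid Cq plate: `cq` is a cells x assays matrix (NA = non-detect).
mini_plate <- function(cq, classes = NULL, panel = mini_panel()) {
  n <- nrow(cq)
  classes <- classes %||% rep("control", n)
  cells <- data.frame(cell_id = sprintf("c%02d", seq_len(n)),
                      sample_id = "s1", cell_class = classes,
                      stringsAsFactors = FALSE)
  cq_plate(cq, cells, colnames(cq), panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a log2-scale expr_matrix directly from a value matrix; NA = non-detect.
log2_matrix <- function(values, classes = NULL, groups = NULL) {
  n <- nrow(values)
  cells <- data.frame(cell_id = rownames(values) %||% sprintf("c%02d", seq_len(n)),
                      sample_id = "s1",
                      cell_class = classes %||% rep("control", n),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene = colnames(values),
                      group = groups %||% rep("fibroblast", ncol(values)),
                      stringsAsFactors = FALSE)
  expr_matrix(values, !is.na(values), cells, genes, "log2_rq")
}

# Independent pair-counting adjusted Rand index (oracle).
ari_pair_counting <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(0)
  (sum_ij - expected) / (maximum - expected)
}

# Two planted well-separated cell clusters on a handful of genes.
two_cluster_matrix <- function(n_per = 10, delta = 20, seed = 42) {
  set.seed(seed)
  g <- 6
  mu <- rbind(matrix(rep(c(2, delta), each = g / 2), n_per, g, byrow = TRUE),
              matrix(rep(c(delta, 2), each = g / 2), n_per, g, byrow = TRUE))
  vals <- mu + matrix(rnorm(2 * n_per * g, 0, 0.3), 2 * n_per, g)
  colnames(vals) <- paste0("G", seq_len(g))
  rownames(vals) <- sprintf("c%02d", seq_len(2 * n_per))
  list(matrix = log2_matrix(vals),
       truth = rep(c("A", "B"), each = n_per))
}
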