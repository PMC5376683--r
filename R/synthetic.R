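REF_STATES <- STATE_LABELS
NORMAL_STATES <- STATE_LABELS[1:3]
ACTIVATED_STATES <- STATE_LABELS[4:6]

# Per-gene per-state detection probabilities (f) and detected log2 RQ means
# (mu) for the six planted differentiation states, in timeline order
# stem-like, naive, primed, proto-, ECM-, secretory myofibroblast. The
# trajectories encode: activation markers ramping up along the timeline,
# COL1A1/FN1 peaking in the ECM state and soluble factors in the secretory
# state, CAV1/CD44/VIM ramping down, FSP1/MMP2 peaking in primed cells,
# switch-like (frequency-driven) regulation of pluripotency, CCL5, HGF and
# BCSC genes, near-silent epithelial genes, and primed/proto adjacency.
default_trajectories <- function(panel) {
  tr <- list(
    #              f (6 states)                          mu (6 states)
    ACTA2   = list(f = c(0.30, 0.90, 0.90, 0.90, 0.90, 0.90),
                   mu = c(2.0, 3.0, 3.0, 5.0, 5.0, 5.0)),
    COL1A1  = list(f = c(0.90, 0.90, 0.95, 0.95, 1.00, 0.95),
                   mu = c(5.5, 2.5, 6.0, 6.5, 10.5, 6.0)),
    TNC     = list(f = c(0.10, 0.10, 0.90, 0.95, 0.95, 0.95),
                   mu = c(2.0, 2.0, 5.5, 7.5, 7.0, 7.0)),
    FN1     = list(f = c(0.90, 0.90, 0.95, 0.95, 1.00, 0.95),
                   mu = c(6.0, 3.0, 6.0, 6.5, 10.0, 5.5)),
    FAP     = list(f = c(0.10, 0.10, 0.90, 0.90, 0.90, 0.90),
                   mu = c(3.0, 3.0, 5.5, 5.75, 6.5, 6.5)),
    FSP1    = list(f = c(0.90, 0.90, 0.95, 0.95, 0.90, 0.90),
                   mu = c(4.0, 4.0, 8.0, 7.5, 4.0, 4.0)),
    MMP2    = list(f = c(0.90, 0.90, 0.95, 0.95, 0.90, 0.90),
                   mu = c(6.5, 3.5, 8.0, 7.5, 6.0, 6.0)),
    LOX     = list(f = c(0.10, 0.10, 0.90, 0.90, 0.95, 0.90),
                   mu = c(3.0, 3.0, 5.0, 5.0, 9.0, 5.0)),
    LOXL2   = list(f = c(0.10, 0.10, 0.90, 0.90, 0.95, 0.90),
                   mu = c(3.0, 3.0, 5.0, 5.0, 8.5, 5.0)),
    VIM     = list(f = rep(0.95, 6), mu = c(7.5, 9.5, 8.25, 7.25, 6.0, 5.5)),
    CD44    = list(f = rep(0.95, 6), mu = c(7.0, 9.0, 7.0, 6.75, 5.0, 4.5)),
    CAV1    = list(f = rep(0.95, 6), mu = c(7.0, 9.0, 7.5, 6.0, 4.5, 4.0)),
    CDH1    = list(f = rep(0.05, 6), mu = rep(2.0, 6)),
    EPCAM   = list(f = rep(0.05, 6), mu = rep(2.0, 6)),
    CXCL12  = list(f = c(0.10, 0.10, 0.10, 0.15, 0.15, 0.95),
                   mu = c(2.0, 2.0, 3.0, 3.5, 4.5, 10.0)),
    PDGFA   = list(f = c(0.10, 0.10, 0.10, 0.15, 0.15, 0.95),
                   mu = c(3.0, 3.0, 3.5, 4.0, 4.5, 9.0)),
    VEGFA   = list(f = c(0.15, 0.15, 0.15, 0.20, 0.20, 0.90),
                   mu = c(3.0, 3.0, 4.0, 4.25, 4.5, 8.5)),
    HGF     = list(f = c(0.90, 0.10, 0.10, 0.15, 0.15, 0.90), mu = rep(5, 6)),
    CCL5    = list(f = c(0.95, 0.10, 0.10, 0.10, 0.10, 0.10),
                   mu = c(7.5, 5.0, 5.0, 5.0, 5.0, 5.0)),
    IL6     = list(f = c(0.10, 0.10, 0.10, 0.15, 0.15, 0.90),
                   mu = c(3.0, 3.0, 3.5, 3.75, 3.75, 7.0)),
    CTGF    = list(f = c(0.10, 0.90, 0.90, 0.90, 0.90, 0.90),
                   mu = c(4.0, 4.0, 5.0, 5.25, 6.5, 6.0)),
    FOXF1   = list(f = c(0.30, 0.95, 0.30, 0.15, 0.15, 0.15),
                   mu = c(5.0, 7.0, 5.0, 4.5, 4.0, 4.0)),
    GLI1    = list(f = c(0.10, 0.10, 0.50, 0.50, 0.90, 0.90),
                   mu = c(3.0, 3.0, 4.0, 4.25, 5.0, 5.0)),
    HEY1    = list(f = c(0.10, 0.90, 0.90, 0.90, 0.90, 0.90), mu = rep(5.0, 6)),
    RUNX2   = list(f = c(0.10, 0.60, 0.60, 0.60, 0.90, 0.90),
                   mu = c(4.0, 4.0, 4.5, 4.75, 5.5, 5.5)),
    STAT3   = list(f = c(0.30, 0.90, 0.90, 0.90, 0.90, 0.90),
                   mu = c(5.0, 6.0, 6.0, 6.0, 6.0, 6.0)),
    CCNA2   = list(f = c(0.10, 0.90, 0.80, 0.70, 0.15, 0.15),
                   mu = c(4.5, 6.5, 6.0, 5.75, 4.5, 4.5)),
    MKI67   = list(f = c(0.10, 0.90, 0.80, 0.70, 0.15, 0.15),
                   mu = c(4.5, 6.5, 6.0, 5.75, 4.5, 4.5)),
    CDKN1A  = list(f = c(0.95, 0.70, 0.70, 0.70, 0.80, 0.90),
                   mu = c(7.0, 4.0, 4.5, 4.75, 5.5, 6.0)),
    ALDH1A3 = list(f = c(0.10, 0.10, 0.60, 0.80, 0.95, 0.95),
                   mu = c(2.0, 2.0, 3.5, 6.0, 6.5, 7.5)),
    ALDH1A1 = list(f = c(0.90, 0.20, 0.20, 0.20, 0.20, 0.20),
                   mu = c(6.5, 5.0, 5.0, 5.0, 5.0, 5.0)),
    ITGA6   = list(f = c(0.90, 0.50, 0.50, 0.50, 0.20, 0.20),
                   mu = c(6.5, 5.0, 5.0, 4.5, 4.5, 4.5)),
    PROM1   = list(f = c(0.70, 0.10, 0.10, 0.05, 0.05, 0.05),
                   mu = c(5.0, 4.0, 4.0, 4.0, 4.0, 4.0)),
    POU5F1  = list(f = c(0.95, 0.08, 0.05, 0.05, 0.05, 0.05), mu = rep(9.0, 6)),
    SOX2    = list(f = c(0.90, 0.06, 0.05, 0.05, 0.05, 0.05), mu = rep(9.0, 6)),
    NANOG   = list(f = c(0.95, 0.05, 0.05, 0.05, 0.05, 0.05), mu = rep(9.0, 6)),
    KLF4    = list(f = c(0.95, 0.10, 0.08, 0.05, 0.05, 0.05), mu = rep(9.0, 6)),
    LIN28A  = list(f = c(0.85, 0.05, 0.05, 0.05, 0.05, 0.05), mu = rep(8.5, 6)),
    SNAI1   = list(f = c(0.20, 0.50, 0.50, 0.60, 0.70, 0.70),
                   mu = c(3.0, 3.0, 3.5, 4.0, 4.5, 4.5)),
    SNAI2   = list(f = c(0.90, 0.80, 0.70, 0.60, 0.60, 0.60),
                   mu = c(6.0, 5.5, 5.0, 4.5, 4.5, 4.5)),
    TWIST1  = list(f = c(0.20, 0.50, 0.50, 0.60, 0.65, 0.70),
                   mu = c(3.0, 3.0, 3.5, 3.75, 4.0, 4.5)),
    ZEB1    = list(f = c(0.25, 0.50, 0.55, 0.625, 0.70, 0.70),
                   mu = c(4.0, 4.0, 4.0, 4.25, 4.5, 4.5)),
    GAPDH   = list(f = rep(0.95, 6), mu = rep(10.0, 6))
  )
  assert_that(setequal(names(tr), panel$gene),
              "trajectory table does not match the panel")
  genes <- panel$gene
  f <- do.call(rbind, lapply(tr[genes], `[[`, "f"))
  mu <- do.call(rbind, lapply(tr[genes], `[[`, "mu"))
  dimnames(f) <- dimnames(mu) <- list(genes, REF_STATES)
  list(f = f, mu = mu)
}

#' Generator configuration for the reference (cell-line) cohort
#'
#' Defaults emulate the cell-line study design: 92 control fibroblasts and
#' 91 experimentally generated CAFs over six planted differentiation states
#' (the stem-like state rare, ~10% of controls), 43 gene assays, biological
#' SD 1.0 log2 units, technical Cq noise 0.5 cycles, per-cell global scale
#' SD 0.5 log2 units, ACTA2 bimodal (components 4 log2 units apart) in the
#' activated condition, and 95% GAPDH detection so the quality gate is
#' exercised.
#'
#' @param n_control,n_caf Cohort sizes (default 92 and 91).
#' @param sigma_bio Biological SD of detected log2 expression (default 1.0).
#' @param sigma_tech Technical Cq noise SD in cycles (default 0.5).
#' @param global_sd Per-cell global scale SD in log2 units (default 0.5).
#' @param separation Multiplier on between-state mean contrasts (1 =
#'   default planted separation).
#' @param gapdh_detection GAPDH detection probability (default 0.95).
#' @param gapdh_dropout If `FALSE`, GAPDH is always detected.
#' @param bimodal Bimodal gene spec: `gene`, component `means` (low, high),
#'   per-activated-state `low_weight`.
#' @param censoring If `TRUE`, draws falling below the detection limit are
#'   censored to non-detects instead of clamped at the limit.
#' @param cq_cutoff Cq off-scale limit used to write the plate (default 28).
#' @param seed RNG seed.
#' @param panel Gene panel (default [load_default_panel()]).
#' @return A `generator_config` list with per-gene per-state `f` and `mu`.
#' @export
reference_config <- function(n_control = 92L, n_caf = 91L, sigma_bio = 1.0,
                             sigma_tech = 0.5, global_sd = 0.5,
                             separation = 1.0, gapdh_detection = 0.95,
                             gapdh_dropout = TRUE,
                             bimodal = list(gene = "ACTA2",
                                            means = c(low = 5, high = 9),
                                            sd = 0.6,
                                            low_weight = c(
                                              proto_myofibroblast = 0.7,
                                              ecm_myofibroblast = 0.5,
                                              secretory_myofibroblast = 0.4)),
                             censoring = FALSE, cq_cutoff = 28, seed = 1L,
                             panel = load_default_panel()) {
  tr <- default_trajectories(panel)
  tr$f["GAPDH", ] <- gapdh_detection
  if (separation != 1) {
    m <- rowMeans(tr$mu)
    tr$mu <- m + separation * (tr$mu - m)
  }
  # state sizes: stem-like rare (~10% of the cohort), others near-equal
  n_stem <- max(2L, round(0.10 * (n_control + n_caf)))
  n_rest <- n_control - n_stem
  n_naive <- floor(n_rest / 2)
  n_states <- c(stem_like = n_stem, naive = n_naive,
                primed = n_rest - n_naive,
                proto_myofibroblast = floor(n_caf / 3),
                ecm_myofibroblast = floor(n_caf / 3),
                secretory_myofibroblast = n_caf - 2L * floor(n_caf / 3))
  structure(list(states = REF_STATES,
                 state_condition = stats::setNames(
                   rep(c("normal", "activated"), each = 3L), REF_STATES),
                 n_states = n_states, f = tr$f, mu = tr$mu,
                 sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                 global_sd = global_sd, gapdh_detection = gapdh_detection,
                 gapdh_dropout = gapdh_dropout, bimodal = bimodal,
                 censoring = censoring, cq_cutoff = cq_cutoff, seed = seed,
                 panel = panel),
            class = "generator_config")
}

.validate_generator_config <- function(config) {
  assert_that(all(config$f >= 0 & config$f <= 1),
              "detection probabilities must be in [0, 1]")
  assert_that(config$sigma_bio >= 0 && config$sigma_tech >= 0 &&
                config$global_sd >= 0, "SDs must be >= 0")
  assert_that(all(config$n_states >= 0), "cell counts must be >= 0")
  invisible(TRUE)
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Draw one block of cells sharing per-gene (f, mu) columns. Returns log2
# values (NA = non-detect) plus the bimodal component labels.
.draw_cells <- function(config, f_vec, mu_vec, n, offsets, bimodal_low_weight) {
  genes <- rownames(config$f)
  sd_tot <- sqrt(config$sigma_bio^2 + config$sigma_tech^2)
  vals <- matrix(NA_real_, n, length(genes), dimnames = list(NULL, genes))
  comp <- rep(NA_character_, n)
  for (j in seq_along(genes)) {
    g <- genes[j]
    fj <- if (g == "GAPDH" && !config$gapdh_dropout) 1 else f_vec[j]
    det <- stats::runif(n) < fj
    if (!any(det)) next
    mu_j <- rep(mu_vec[j], n)
    sd_j <- sd_tot
    if (g == config$bimodal$gene && !is.na(bimodal_low_weight)) {
      low <- stats::runif(n) < bimodal_low_weight
      mu_j <- ifelse(low, config$bimodal$means[["low"]],
                     config$bimodal$means[["high"]])
      comp <- ifelse(low, "low", "high")
      # the mixture components carry the biological variation; within a
      # component only the component SD and technical noise apply
      sd_j <- sqrt((config$bimodal$sd %||% 0.6)^2 + config$sigma_tech^2)
    }
    x <- mu_j[det] + offsets[det] + stats::rnorm(sum(det), 0, sd_j)
    if (config$censoring) {
      det[det] <- x > 0
      x <- x[x > 0]
    } else {
      x <- pmax(x, 0.05)  # keep detected draws above the detection limit
    }
    vals[det, j] <- x
  }
  list(values = vals, component = comp)
}

.assemble_plate <- function(config, values, cells_df) {
  cq <- config$cq_cutoff - values
  cq_plate(cq, cells_df, colnames(values), config$panel)
}

#' Generate a synthetic reference plate with planted ground truth
#'
#' Simulates the cell-line experiment: for each cell and gene the reaction
#' is detected with the planted state-specific probability, and detected
#' log2 RQ values are drawn around the planted state mean plus the cell's
#' global scale offset. The bimodal gene draws its mixture component first
#' in activated states. Values are written back to Cq cycles via the
#' preprocessing convention. The truth records each cell's condition, state,
#' five-subgroup cluster (primed and proto-myofibroblast cells form the
#' mixed cluster), global offset and bimodal component.
#'
#' @param config A [reference_config()].
#' @return List with `plate` (a [cq_plate()]) and `truth` (cell table plus
#'   the planted `f` and `mu` matrices).
#' @export
generate_reference <- function(config = reference_config()) {
  .validate_generator_config(config)
  .with_seed(config$seed, {
    blocks <- list()
    cells <- list()
    for (s in config$states) {
      n <- config$n_states[[s]]
      if (n == 0L) next
      offsets <- stats::rnorm(n, 0, config$global_sd)
      low_w <- if (s %in% names(config$bimodal$low_weight))
        config$bimodal$low_weight[[s]] else NA_real_
      drawn <- .draw_cells(config, config$f[, s], config$mu[, s], n, offsets,
                           low_w)
      condition <- config$state_condition[[s]]
      cls <- if (condition == "normal") "control" else "expCAF"
      cells[[s]] <- data.frame(state = s, condition = condition,
                               cell_class = cls, offset = offsets,
                               component = drawn$component,
                               stringsAsFactors = FALSE)
      blocks[[s]] <- drawn$values
    }
    values <- do.call(rbind, blocks)
    cell_tab <- do.call(rbind, cells)
    cell_tab$cell_id <- sprintf("ref_%03d", seq_len(nrow(cell_tab)))
    cell_tab$cluster5 <- ifelse(
      cell_tab$state %in% c("primed", "proto_myofibroblast"),
      "primed_proto", cell_tab$state)
    cells_df <- data.frame(cell_id = cell_tab$cell_id,
                           sample_id = paste0("ref_", cell_tab$cell_class),
                           cell_class = cell_tab$cell_class,
                           stringsAsFactors = FALSE)
    plate <- .assemble_plate(config, values, cells_df)
    truth <- structure(list(cells = cell_tab[, c("cell_id", "cell_class",
                                                 "condition", "state",
                                                 "cluster5", "offset",
                                                 "component")],
                            f = config$f, mu = config$mu, config = config),
                       class = "synthetic_truth")
    list(plate = plate, truth = truth)
  })
}

#' Generator configuration for the patient-derived cohort
#'
#' Defaults emulate the patient experiment: 77 normal fibroblasts drawn from
#' a stem-like/naive/primed mixture and 75 CAFs drawn along a primed to
#' proto-myofibroblast interpolation (early-onset activation), with doubled
#' per-cell global scale SD to exercise per-cell autoscaling.
#'
#' @param n_nf,n_caf Cohort sizes (default 77 and 75).
#' @param nf_mix Mixture proportions over the normal states for NF cells.
#' @param caf_lambda_range Range of the primed-to-proto interpolation weight
#'   for CAF cells (0 = primed archetype, 1 = proto).
#' @param global_sd Per-cell global scale SD (default 1.0, twice the
#'   reference).
#' @param ... Passed to [reference_config()] (noise, panel, seed, ...).
#' @return A `generator_config` with patient fields.
#' @export
patient_config <- function(n_nf = 77L, n_caf = 75L,
                           nf_mix = c(stem_like = 0.15, naive = 0.60,
                                      primed = 0.25),
                           caf_lambda_range = c(0.25, 0.75),
                           global_sd = 1.0, ...) {
  config <- reference_config(global_sd = global_sd, ...)
  config$n_nf <- n_nf
  config$n_caf <- n_caf
  config$nf_mix <- nf_mix / sum(nf_mix)
  config$caf_lambda_range <- caf_lambda_range
  config
}

#' Generate a synthetic patient-derived cohort with ground truth
#'
#' Normal fibroblasts are drawn from the configured mixture over the normal
#' states; CAF cells interpolate the primed and proto-myofibroblast
#' archetypes (per-gene f and mu blended by a per-cell weight), with the
#' true state recorded as the nearer archetype. The bimodal-gene machinery
#' is not applied: patient CAFs emulate early-onset activation with minimal
#' induction of the bimodal marker.
#'
#' @param config A [patient_config()].
#' @return List with `plate` and `truth` as in [generate_reference()].
#' @export
generate_patient_cohort <- function(config = patient_config()) {
  .validate_generator_config(config)
  assert_that(!is.null(config$n_nf), "config must come from patient_config()")
  .with_seed(config$seed, {
    # NF cells: mixture over normal states
    nf_states <- sample(names(config$nf_mix), config$n_nf, replace = TRUE,
                        prob = config$nf_mix)
    values <- list(); cell_rows <- list()
    i <- 0L
    for (s in names(config$nf_mix)) {
      n <- sum(nf_states == s)
      if (n == 0L) next
      i <- i + 1L
      offsets <- stats::rnorm(n, 0, config$global_sd)
      drawn <- .draw_cells(config, config$f[, s], config$mu[, s], n, offsets,
                           NA_real_)
      values[[length(values) + 1L]] <- drawn$values
      cell_rows[[length(cell_rows) + 1L]] <-
        data.frame(state = s, condition = "normal", cell_class = "NF",
                   offset = offsets, component = NA_character_,
                   lambda = NA_real_, stringsAsFactors = FALSE)
    }
    # CAF cells: per-cell interpolation between primed and proto archetypes
    lam <- stats::runif(config$n_caf, config$caf_lambda_range[1],
                        config$caf_lambda_range[2])
    offsets <- stats::rnorm(config$n_caf, 0, config$global_sd)
    f_caf <- outer(config$f[, "primed"], 1 - lam) +
      outer(config$f[, "proto_myofibroblast"], lam)
    mu_caf <- outer(config$mu[, "primed"], 1 - lam) +
      outer(config$mu[, "proto_myofibroblast"], lam)
    genes <- rownames(config$f)
    sd_tot <- sqrt(config$sigma_bio^2 + config$sigma_tech^2)
    caf_vals <- matrix(NA_real_, config$n_caf, length(genes),
                       dimnames = list(NULL, genes))
    for (j in seq_along(genes)) {
      fj <- if (genes[j] == "GAPDH" && !config$gapdh_dropout) 1
        else f_caf[j, ]
      det <- stats::runif(config$n_caf) < fj
      if (!any(det)) next
      x <- mu_caf[j, det] + offsets[det] + stats::rnorm(sum(det), 0, sd_tot)
      if (config$censoring) {
        det[det] <- x > 0
        x <- x[x > 0]
      } else x <- pmax(x, 0.05)
      caf_vals[det, j] <- x
    }
    values[[length(values) + 1L]] <- caf_vals
    cell_rows[[length(cell_rows) + 1L]] <-
      data.frame(state = ifelse(lam > 0.5, "proto_myofibroblast", "primed"),
                 condition = "activated", cell_class = "CAF",
                 offset = offsets, component = NA_character_, lambda = lam,
                 stringsAsFactors = FALSE)
    values <- do.call(rbind, values)
    cell_tab <- do.call(rbind, cell_rows)
    cell_tab$cell_id <- sprintf("pat_%03d", seq_len(nrow(cell_tab)))
    cell_tab$cluster5 <- ifelse(
      cell_tab$state %in% c("primed", "proto_myofibroblast"),
      "primed_proto", cell_tab$state)
    cells_df <- data.frame(cell_id = cell_tab$cell_id,
                           sample_id = paste0("patient_", cell_tab$cell_class),
                           cell_class = cell_tab$cell_class,
                           stringsAsFactors = FALSE)
    plate <- .assemble_plate(config, values, cells_df)
    truth <- structure(list(cells = cell_tab[, c("cell_id", "cell_class",
                                                 "condition", "state",
                                                 "cluster5", "offset",
                                                 "component", "lambda")],
                            f = config$f, mu = config$mu, config = config),
                       class = "synthetic_truth")
    list(plate = plate, truth = truth)
  })
}

#' Compare a result against planted ground truth
#'
#' For a subgroup assignment: the adjusted Rand index between the predicted
#' partition and the planted one (the five-subgroup truth when the
#' assignment has five groups, the six-state truth otherwise). For a
#' classification result: accuracy, confusion table and ARI against the
#' planted states.
#'
#' @param truth A `synthetic_truth`.
#' @param result A [subgroup_assignment()] or a [classify_cells()] result.
#' @param truth_labels Optionally, which truth column to compare against
#'   (`"state"` or `"cluster5"`); by default chosen from the result's group
#'   count.
#' @return List with `ari`, `confusion`, and `accuracy` (classifications
#'   only).
#' @export
truth_metrics <- function(truth, result, truth_labels = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (inherits(result, "subgroup_assignment")) {
    ids <- names(result$labels)
    pred <- unname(result$labels)
  } else if (inherits(result, "classification_result")) {
    ids <- result$cells$cell_id
    pred <- result$cells$state
  } else stop2("result must be a subgroup_assignment or classification_result")
  idx <- match(ids, truth$cells$cell_id)
  assert_that(!anyNA(idx), "result ids do not align with the truth table")
  if (is.null(truth_labels)) {
    truth_labels <- if (inherits(result, "subgroup_assignment") &&
                          result$k == 5L) "cluster5" else "state"
  }
  true <- truth$cells[[truth_labels]][idx]
  out <- list(ari = mclust::adjustedRandIndex(pred, true),
              confusion = table(truth = true, predicted = pred))
  if (inherits(result, "classification_result")) {
    out$accuracy <- mean(pred == true)
  }
  out
}
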