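STATE_LABELS <- c("stem_like", "naive", "primed", "proto_myofibroblast",
                  "ecm_myofibroblast", "secretory_myofibroblast")

#' Pseudo-temporal gene profile across ordered subgroups
#'
#' The per-state score of a gene is the product of its detection frequency
#' and its mean log2 RQ over detected cells, with negative mean levels
#' clipped to 0 so the product cannot invert sign. Zero frequency (or a
#' missing level) gives score 0. Combining the frequency and level channels
#' treats switch-like regulation (changing frequency) and transitional
#' regulation (changing level) on an equal footing.
#'
#' @param summary A [summarize_groups()] result covering all listed states.
#' @param states Ordered character vector of subgroup ids (the pseudotime
#'   order).
#' @return A `pseudo_profile`: `score` (genes x states), `states`,
#'   `level_convention`.
#' @export
pseudotemporal_profile <- function(summary, states) {
  stopifnot(inherits(summary, "group_summary"))
  missing <- setdiff(states, unique(summary$group))
  assert_that(length(missing) == 0L,
              paste0("state(s) absent from summary: ",
                     paste(missing, collapse = ", ")))
  genes <- unique(summary$gene)
  score <- matrix(0, length(genes), length(states),
                  dimnames = list(genes, states))
  for (s in states) {
    sub <- summary[summary$group == s, ]
    lev <- pmax(sub$level, 0)
    lev[is.na(lev)] <- 0
    score[match(sub$gene, genes), s] <- sub$frequency * lev
  }
  structure(list(score = score, states = states,
                 level_convention = "mean log2 RQ over detected cells, floored at 0"),
            class = "pseudo_profile")
}

#' @export
print.pseudo_profile <- function(x, ...) {
  cat("Pseudo-temporal profile:", nrow(x$score), "genes x",
      length(x$states), "states\n")
  invisible(x)
}

#' Default marker rule set for state labelling
#'
#' Gene lists behind each labelling criterion: the pluripotency group
#' defines the stem-like state; an activation-marker score separates naive
#' (lowest) from primed among normal fibroblast states; among activated
#' states a soluble-factor score picks the secretory myofibroblast and an
#' ECM score (COL1A1, FN1) the ECM-regulating myofibroblast, with the
#' remaining state proto-myofibroblastic.
#'
#' @return Named list of rule gene sets (editable).
#' @export
marker_rules <- function() {
  list(pluripotency_group = "pluripotency",
       activation_genes = c("ACTA2", "COL1A1", "TNC", "FN1", "FAP", "MMP2"),
       soluble_genes = c("CXCL12", "PDGFA", "VEGFA", "HGF"),
       ecm_genes = c("COL1A1", "FN1"))
}

.rule_score <- function(profile, genes) {
  idx <- match(genes, rownames(profile$score))
  assert_that(!anyNA(idx),
              paste0("rule references gene(s) not in profile: ",
                     paste(genes[is.na(idx)], collapse = ", ")))
  colMeans(profile$score[idx, , drop = FALSE])
}

.argbest <- function(score, states, decreasing) {
  s <- score[states]
  best <- if (decreasing) max(s) else min(s)
  hits <- states[s == best]
  if (length(hits) > 1L) {
    warning(sprintf("tie on labelling criterion among %s; lowest state id wins",
                    paste(hits, collapse = ", ")), call. = FALSE)
  }
  hits[1L]
}

#' Assign differentiation-state labels to subgroups by marker rules
#'
#' Labels the normal-condition states stem-like (highest mean pluripotency
#' score), naive (lowest activation-marker score among the remaining normal
#' states) and primed (the remaining one); among activated states, secretory
#' myofibroblast (highest soluble-factor score), ECM-regulating
#' myofibroblast (highest ECM score among the rest) and proto-myofibroblast
#' (the remainder). Ties break deterministically to the lower state id with
#' a warning.
#'
#' @param profile A [pseudotemporal_profile()].
#' @param panel A [gene_panel()] resolving the rule genes and the
#'   pluripotency group.
#' @param state_condition Named character vector mapping each state id to
#'   `"normal"` or `"activated"`.
#' @param rules A [marker_rules()] list.
#' @return A `state_model`: `states` (data frame `state_id`, `label`,
#'   `condition` in input order), `profile`, `marker_scores`.
#' @export
label_states <- function(profile, panel, state_condition,
                         rules = marker_rules()) {
  stopifnot(inherits(profile, "pseudo_profile"))
  states <- profile$states
  assert_that(all(states %in% names(state_condition)),
              "state_condition must cover every state")
  cond <- state_condition[states]
  assert_that(all(cond %in% c("normal", "activated")),
              "state_condition values must be 'normal' or 'activated'")
  pluri_genes <- panel$gene[panel$group == rules$pluripotency_group]
  assert_that(length(pluri_genes) > 0L, "no genes in the pluripotency group")
  sc_pluri <- .rule_score(profile, pluri_genes)
  sc_act <- .rule_score(profile, rules$activation_genes)
  sc_sol <- .rule_score(profile, rules$soluble_genes)
  sc_ecm <- .rule_score(profile, rules$ecm_genes)

  labels <- stats::setNames(rep(NA_character_, length(states)), states)
  normal <- states[cond == "normal"]
  activated <- states[cond == "activated"]

  if (length(normal) > 0L) {
    stem <- .argbest(sc_pluri, states, decreasing = TRUE)
    assert_that(stem %in% normal,
                sprintf("stem-like criterion selects activated state '%s'", stem))
    labels[stem] <- "stem_like"
    rest <- setdiff(normal, stem)
    if (length(rest) >= 1L) {
      naive <- .argbest(sc_act, rest, decreasing = FALSE)
      labels[naive] <- "naive"
      rest <- setdiff(rest, naive)
    }
    if (length(rest) == 1L) labels[rest] <- "primed"
    assert_that(length(rest) <= 1L,
                "more than three normal-condition states; cannot label uniquely")
  }
  if (length(activated) > 0L) {
    secretory <- .argbest(sc_sol, activated, decreasing = TRUE)
    labels[secretory] <- "secretory_myofibroblast"
    rest <- setdiff(activated, secretory)
    if (length(rest) >= 1L) {
      ecm <- .argbest(sc_ecm, rest, decreasing = TRUE)
      labels[ecm] <- "ecm_myofibroblast"
      rest <- setdiff(rest, ecm)
    }
    if (length(rest) == 1L) labels[rest] <- "proto_myofibroblast"
    assert_that(length(rest) <= 1L,
                "more than three activated states; cannot label uniquely")
  }
  assert_that(!anyDuplicated(stats::na.omit(labels)),
              paste0("two rules selected the same state: ",
                     paste(labels, collapse = ", ")))
  marker_scores <- rbind(pluripotency = sc_pluri, activation = sc_act,
                         soluble = sc_sol, ecm = sc_ecm)
  structure(list(states = data.frame(state_id = states,
                                     label = unname(labels),
                                     condition = unname(cond),
                                     stringsAsFactors = FALSE),
                 profile = profile,
                 marker_scores = marker_scores[, states, drop = FALSE]),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("Differentiation state model:\n")
  print(x$states)
  invisible(x)
}

#' Order states into the canonical differentiation timeline
#'
#' Reorders the model's states into the pseudo-timeline stem-like, naive,
#' primed, proto-, ECM-regulating, secretory myofibroblast (or the
#' corresponding subsequence for a reduced run). Every state must carry a
#' label.
#'
#' @param model A [label_states()] result.
#' @return The model with `states` (and the profile's columns) in timeline
#'   order.
#' @export
order_states <- function(model) {
  stopifnot(inherits(model, "state_model"))
  assert_that(!anyNA(model$states$label),
              "every state must be labelled before ordering")
  ord <- order(match(model$states$label, STATE_LABELS))
  model$states <- model$states[ord, , drop = FALSE]
  rownames(model$states) <- NULL
  new_states <- model$states$state_id
  model$profile$score <- model$profile$score[, new_states, drop = FALSE]
  model$profile$states <- new_states
  model$marker_scores <- model$marker_scores[, new_states, drop = FALSE]
  model
}

#' Cluster pseudo-temporal gene profiles
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the gene
#' rows of a pseudo-temporal profile, cut into `k` flat clusters. Genes with
#' extreme dynamic range (score range more than `extreme_factor` times the
#' median gene range) are split out and reported separately, mirroring the
#' practice of plotting them apart.
#'
#' @param profile A [pseudotemporal_profile()].
#' @param k Number of flat gene clusters (default 4).
#' @param extreme_factor Range multiple above which a gene is split out
#'   (default 5).
#' @return List: `clusters` (named vector over clustered genes), `hclust`,
#'   `extreme` (gene names split out).
#' @export
cluster_profiles <- function(profile, k = 4L, extreme_factor = 5) {
  stopifnot(inherits(profile, "pseudo_profile"))
  sc <- profile$score
  assert_that(all(is.finite(sc)), "profile must be finite")
  rng <- apply(sc, 1L, function(r) diff(range(r)))
  extreme <- rownames(sc)[rng > extreme_factor * stats::median(rng)]
  keep <- setdiff(rownames(sc), extreme)
  if (length(keep) < 2L) {
    clusters <- stats::setNames(rep(1L, length(keep)), keep)
    return(list(clusters = clusters, hclust = NULL, extreme = extreme))
  }
  hc <- stats::hclust(stats::dist(sc[keep, , drop = FALSE]), method = "average")
  clusters <- stats::cutree(hc, k = min(k, length(keep)))
  list(clusters = clusters, hclust = hc, extreme = extreme)
}
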