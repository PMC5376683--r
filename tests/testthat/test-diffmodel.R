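# A deterministic group summary for profile tests.
toy_summary <- function() {
  genes <- c("P1", "ACT", "SOL")
  states <- c("s1", "s2")
  df <- expand.grid(gene = genes, group = states, stringsAsFactors = FALSE)
  df$frequency <- c(0.5, 0, 1, 0.2, 0.8, 0.6)
  df$level <- c(4, 7, 2, 5, -1, 3)
  df$sem <- 0.1
  df$n_pos <- 5L
  df$n_total <- 10L
  structure(df, class = c("group_summary", "data.frame"))
}

test_that("pseudo-temporal score is frequency times non-negative level", {
  p <- pseudotemporal_profile(toy_summary(), c("s1", "s2"))
  expect_equal(p$score["P1", "s1"], 0.5 * 4)
  expect_equal(p$score["ACT", "s1"], 0)          # zero frequency wins
  expect_equal(p$score["ACT", "s2"], 0.8 * 0)    # negative level clipped to 0
  expect_equal(p$score["SOL", "s2"], 0.6 * 3)
  expect_true(all(is.finite(p$score)))
  expect_error(pseudotemporal_profile(toy_summary(), c("s1", "nope")), "nope")
})

test_that("profile matches a two-loop recomputation and scales linearly", {
  set.seed(41)
  vals <- matrix(rnorm(40 * 6, 4, 2), 40, 6, dimnames = list(NULL, paste0("G", 1:6)))
  vals[runif(length(vals)) < 0.25] <- NA
  grp <- rep(c("a", "b", "c", "d"), each = 10)
  s <- summarize_groups(log2_matrix(vals), grp)
  p <- pseudotemporal_profile(s, c("a", "b", "c", "d"))
  for (g in paste0("G", 1:6)) {
    for (st in c("a", "b", "c", "d")) {
      row <- s[s$gene == g & s$group == st, ]
      lev <- if (is.na(row$level)) 0 else max(row$level, 0)
      expect_lt(abs(p$score[g, st] - row$frequency * lev), 1e-12)
    }
  }
  s2 <- s
  s2$level <- s$level * 2
  p2 <- pseudotemporal_profile(s2, c("a", "b", "c", "d"))
  pos <- p$score > 0 & !is.na(p$score)
  expect_lt(max(abs(p2$score[pos] - 2 * p$score[pos])), 1e-12)
})

# A profile with unambiguous marker structure over six states.
fixture_profile <- function(states = paste0("st", 1:6)) {
  panel <- load_default_panel()
  score <- matrix(1, nrow(panel), 6, dimnames = list(panel$gene, states))
  pluri <- panel$gene[panel$group == "pluripotency"]
  act <- marker_rules()$activation_genes
  sol <- marker_rules()$soluble_genes
  ecm <- marker_rules()$ecm_genes
  score[pluri, ] <- 0.2; score[pluri, "st1"] <- 6
  score[act, ] <- 3
  score[act, "st1"] <- 1.5; score[act, "st2"] <- 1; score[act, "st3"] <- 4
  score[sol, c("st4", "st5")] <- 2; score[sol, "st6"] <- 7
  score[ecm, "st4"] <- 4; score[ecm, "st5"] <- 8; score[ecm, "st6"] <- 3
  structure(list(score = score, states = states,
                 level_convention = "test"), class = "pseudo_profile")
}

state_cond <- function(states = paste0("st", 1:6)) {
  setNames(rep(c("normal", "activated"), each = 3), states)
}

test_that("marker rules label the six states as in the fixture", {
  model <- label_states(fixture_profile(), load_default_panel(), state_cond())
  got <- setNames(model$states$label, model$states$state_id)
  expect_equal(unname(got[paste0("st", 1:6)]),
               c("stem_like", "naive", "primed", "proto_myofibroblast",
                 "ecm_myofibroblast", "secretory_myofibroblast"))
})

test_that("labelling is invariant to state input order and breaks ties low", {
  p <- fixture_profile()
  perm <- c(4, 1, 6, 2, 5, 3)
  p_perm <- p
  p_perm$score <- p$score[, perm]
  p_perm$states <- p$states[perm]
  m1 <- label_states(p, load_default_panel(), state_cond())
  m2 <- label_states(p_perm, load_default_panel(), state_cond())
  l1 <- setNames(m1$states$label, m1$states$state_id)
  l2 <- setNames(m2$states$label, m2$states$state_id)
  expect_equal(l1[sort(names(l1))], l2[sort(names(l2))])

  tied <- p
  tied$score[marker_rules()$ecm_genes, "st4"] <-
    tied$score[marker_rules()$ecm_genes, "st5"]
  expect_warning(mt <- label_states(tied, load_default_panel(), state_cond()),
                 "tie")
  got <- setNames(mt$states$label, mt$states$state_id)
  expect_equal(unname(got["st4"]), "ecm_myofibroblast")  # lower id wins

  bad_rules <- marker_rules()
  bad_rules$ecm_genes <- c("COL1A1", "NOTAGENE")
  expect_error(label_states(p, load_default_panel(), state_cond(), bad_rules),
               "NOTAGENE")
})

test_that("order_states produces the canonical timeline", {
  model <- label_states(fixture_profile(), load_default_panel(), state_cond())
  shuffled <- model
  perm <- c(5, 2, 6, 1, 4, 3)
  shuffled$states <- shuffled$states[perm, ]
  ordered <- order_states(shuffled)
  expect_equal(ordered$states$label,
               c("stem_like", "naive", "primed", "proto_myofibroblast",
                 "ecm_myofibroblast", "secretory_myofibroblast"))
  expect_equal(ordered$profile$states, ordered$states$state_id)
  again <- order_states(ordered)
  expect_identical(again$states, ordered$states)
})

test_that("a normal-only run keeps the stem/naive/primed order", {
  p <- fixture_profile()
  p$score <- p$score[, 1:3]
  p$states <- p$states[1:3]
  cond <- state_cond()[1:3]
  model <- order_states(label_states(p, load_default_panel(), cond))
  expect_equal(model$states$label, c("stem_like", "naive", "primed"))
})

test_that("profile clustering separates planted gene archetypes", {
  states <- paste0("s", 1:6)
  up <- t(sapply(1:5, function(i) seq(0, 5, length.out = 6) + i * 0.05))
  off <- t(sapply(1:5, function(i) c(5, 5, 0.2, 0.2, 0.2, 0.2) + i * 0.05))
  score <- rbind(up, off)
  rownames(score) <- paste0("g", 1:10)
  colnames(score) <- states
  p <- structure(list(score = score, states = states,
                      level_convention = "test"), class = "pseudo_profile")
  cl <- cluster_profiles(p, k = 2, extreme_factor = 100)
  expect_equal(length(unique(cl$clusters[1:5])), 1L)
  expect_equal(length(unique(cl$clusters[6:10])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[10])

  # duplicated gene rows sit at distance zero and merge first
  dup <- p
  dup$score <- rbind(dup$score, g1copy = dup$score["g1", ])
  cld <- cluster_profiles(dup, k = 2, extreme_factor = 100)
  expect_equal(unname(cld$clusters["g1"]), unname(cld$clusters["g1copy"]))
  expect_equal(cld$hclust$height[1], 0)

  # extreme-range genes are split out
  ext <- p
  ext$score["g1", ] <- ext$score["g1", ] * 100
  cle <- cluster_profiles(ext, k = 2, extreme_factor = 5)
  expect_true("g1" %in% cle$extreme)
  expect_false("g1" %in% names(cle$clusters))
})
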