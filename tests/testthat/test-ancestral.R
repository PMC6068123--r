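test_that("threshold classification follows the >90% rule", {
  tr <- tree4()
  est <- data.frame(node = c("nd1", "nd2", "nd3"),
                    p_island = c(0.95, 0.50, 0.05))
  cats <- classify_and_categorize(tr, est, c(A = 1, B = 1, C = 0, D = 0))
  cl <- attr(cats, "classification")
  expect_equal(cl$classification[match(c("nd1", "nd2", "nd3"), cl$node)],
               c("island", "unclassified", "continent"))
})

test_that("three-tip example yields the textbook beta and gamma categories", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # root continental, inner node island, A and B island tips
  est <- data.frame(node = c("nd1", "nd2"), p_island = c(0.99, 0.01))
  cats <- classify_and_categorize(tr, est, c(A = 1, B = 1, C = 0))
  root_rows <- cats[cats$ancestor == "nd2", ]
  expect_true("beta" %in% root_rows$category)   # continent -> island child
  inner <- cats[cats$ancestor == "nd1", ]
  expect_true(all(inner$category == "gamma"))
})

test_that("raising the threshold never classifies more nodes", {
  sc <- island_scenario(n_tips = 60, min_island_tips = 6, seed = 70)
  ds <- quiet(simulate_dataset(sc))
  est <- quiet(reconstruct_island_states(ds$tree, ds$history$tip_states,
                                         quick_config(seed = 71)))
  n_cls <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th) {
    cl <- attr(classify_and_categorize(ds$tree, est, ds$history$tip_states,
                                       threshold = th), "classification")
    sum(cl$classification != "unclassified")
  }, 0)
  expect_true(all(diff(n_cls) <= 0))
})

test_that("categories partition classified ancestor-child links", {
  sc <- island_scenario(n_tips = 80, min_island_tips = 8, seed = 72)
  ds <- quiet(simulate_dataset(sc))
  est <- quiet(reconstruct_island_states(ds$tree, ds$history$tip_states,
                                         quick_config(seed = 73)))
  cats <- classify_and_categorize(ds$tree, est, ds$history$tip_states)
  expect_false(anyDuplicated(paste(cats$ancestor, cats$child)) > 0)
  expect_true(all(cats$category %in% c("alpha", "beta", "gamma", "delta")))
  expect_true(all(cats$insufficient_for_modelling ==
                    (cats$category == "delta")))
})

test_that("true node states reproduce brute-force category counts", {
  sc <- island_scenario(n_tips = 70, min_island_tips = 6, seed = 74)
  ds <- quiet(simulate_dataset(sc))
  st <- ds$history$states
  internal <- grepl("^nd", names(st))
  est <- data.frame(node = names(st)[internal], p_island = st[internal])
  cats <- classify_and_categorize(ds$tree, est, ds$history$tip_states,
                                  threshold = 0)
  # brute force over edges with the true states
  ids <- node_ids(ds$tree)
  want <- c(alpha = 0, beta = 0, gamma = 0, delta = 0)
  for (k in seq_len(nrow(ds$tree$edge))) {
    sa <- st[ids[as.character(ds$tree$edge[k, 1])]]
    sc_ <- st[ids[as.character(ds$tree$edge[k, 2])]]
    key <- if (sa == 0 && sc_ == 0) "alpha" else if (sa == 0) "beta"
    else if (sc_ == 1) "gamma" else "delta"
    want[key] <- want[key] + 1
  }
  got <- table(factor(cats$category, levels = names(want)))
  expect_equal(as.numeric(got), unname(want))
})

test_that("monomorphic tip states warn and saturate node probabilities", {
  tr <- simulate_tree(island_scenario(n_tips = 20, seed = 75))
  states <- stats::setNames(rep(1, 20), tr$tip.label)
  expect_warning(
    est <- suppressMessages(
      reconstruct_island_states(tr, states, quick_config(seed = 76))),
    "monomorphic")
  expect_true(all(est$p_island > 0.9))
})

test_that("ancestral values: constants, symmetric root, dense-formula oracle", {
  tr <- tree4()
  vals <- ancestral_brain_values(tr, c(A = 3, B = 3, C = 3, D = 3))
  expect_equal(unname(vals), rep(3, 3), tolerance = 1e-8)

  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  v2 <- ancestral_brain_values(tr2, c(A = 1, B = 5))
  expect_equal(unname(v2), 3)

  # 20-tip tree: conditional-normal formula with an independent dense solve
  tr3 <- simulate_tree(island_scenario(n_tips = 20, seed = 77))
  set.seed(77)
  y <- stats::setNames(rnorm(20), tr3$tip.label)
  got <- ancestral_brain_values(tr3, y)
  Vf <- vcv_phylo(tr3, include_internal = TRUE)
  Vtt <- Vf[tr3$tip.label, tr3$tip.label]
  Vnt <- Vf[names(got), tr3$tip.label]
  iv <- solve(Vtt)
  mu <- sum(iv %*% y) / sum(iv)
  ref <- mu + Vnt %*% iv %*% (y - mu)
  expect_equal(unname(got), as.numeric(ref), tolerance = 1e-6)
  # estimates stay within the tip range (convexity)
  expect_true(all(got >= min(y) - 1e-9 & got <= max(y) + 1e-9))
})

test_that("ancestral values agree with the reference ML reconstruction", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(island_scenario(n_tips = 40, seed = 78))
  set.seed(78)
  y <- stats::setNames(cumsum(rnorm(40, 0, 0.1)), tr$tip.label)
  got <- ancestral_brain_values(tr, y)
  fa <- phytools::fastAnc(tr, y)
  ids <- node_ids(tr)
  expect_equal(unname(got[ids[names(fa)]]), unname(as.numeric(fa)),
               tolerance = 1e-5)
})

test_that("transition model recovers an in-situ shift as gamma minus beta", {
  # true node states isolate the contrast model from reconstruction noise
  sc <- island_scenario(n_tips = 260, island_effect = 0.1,
                        island_mode = "insitu", min_island_tips = 12,
                        min_island_nodes = 4, min_colonizations = 5,
                        seed = 79)
  ds <- quiet(simulate_dataset(sc))
  rbs <- relative_brain_size(ds$traits, ds$tree)
  st <- ds$history$states
  est <- data.frame(node = names(st)[grepl("^nd", names(st))],
                    p_island = st[grepl("^nd", names(st))])
  cats <- classify_and_categorize(ds$tree, est, ds$history$tip_states,
                                  threshold = 0)
  vals <- ancestral_brain_values(ds$tree, rbs, propagate_uncertainty = TRUE,
                                 seed = 81)
  m <- quiet(fit_transition_model(vals, cats, ds$tree,
                                  quick_config(seed = 80)))
  ctr <- m$contrasts
  gmb <- ctr[ctr$contrast == "gamma_minus_beta", ]
  expect_equal(nrow(gmb), 1L)
  expect_gt(gmb$mode, 0)
  # every retained category meets the minimum node count
  obs <- unique(cats[, c("ancestor", "category")])
  kept <- names(table(obs$category))[table(obs$category) >= 3]
  expect_true(all(c("alpha", "gamma") %in% kept))
})
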