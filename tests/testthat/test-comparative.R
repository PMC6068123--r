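test_that("sister pairing follows the minimal patristic distance", {
  tr <- ape::read.tree(text = "((I:1,C1:1):1,C2:3);")
  flags <- c(I = 1, C1 = 0, C2 = 0)
  p <- find_sister_pairs(tr, flags)
  expect_equal(p$island_species, "I")
  expect_equal(p$sister_species, "C1")
  expect_equal(p$distance, 2)

  # tied continental sisters are grouped
  tr2 <- ape::read.tree(text = "((I:1,(C1:0.5,C2:0.5):0.5):1,C3:3);")
  p2 <- find_sister_pairs(tr2, c(I = 1, C1 = 0, C2 = 0, C3 = 0))
  expect_setequal(p2$sister_species, c("C1", "C2"))
  expect_equal(unique(p2$distance), 2)
  expect_equal(length(unique(p2$pair_id)), 1L)

  expect_error(find_sister_pairs(tr, c(I = 1, C1 = 1, C2 = 1)),
               "at least one")
})

test_that("pairing is permutation-invariant and matches brute force", {
  sc <- island_scenario(n_tips = 40, min_island_tips = 5, seed = 44)
  ds <- quiet(simulate_dataset(sc))
  flags <- ds$history$tip_states
  p1 <- quiet(find_sister_pairs(ds$tree, flags))
  perm <- sample(names(flags))
  p2 <- quiet(find_sister_pairs(ds$tree, flags[perm]))
  expect_identical(p1[, c("island_species", "sister_species", "distance")],
                   p2[, c("island_species", "sister_species", "distance")])
  # each recorded distance is the brute-force minimum over continental taxa
  D <- patristic_matrix(ds$tree)
  con <- names(flags)[flags == 0]
  for (i in seq_len(nrow(p1))) {
    expect_lte(min(D[p1$island_species[i], con]), p1$distance[i] + 1e-9)
  }
  # a continental species never serves two pairs
  expect_false(anyDuplicated(p1$sister_species) > 0)
})

test_that("global model recovers a simulated island effect", {
  sc <- island_scenario(n_tips = 150, island_effect = 0.05,
                        island_mode = "sorting", min_island_tips = 8,
                        seed = 55)
  ds <- quiet(simulate_dataset(sc))
  fits <- quiet(fit_global_models(ds$traits, ds$tree,
                                  quick_config(seed = 56)))
  s1 <- fits$model1$summary
  i <- s1$parameter == "insularity"
  expect_gt(s1$ci_high[i], 0.05)
  expect_lt(s1$ci_low[i], 0.05 + 0.1)
  # model 2 runs on the filtered subset
  expect_lte(fits$model2$n, fits$model1$n)
  # model 4 carries the extra fixed effects
  expect_true(all(c("migratory", "dev_modeprecocial") %in%
                    fits$model4$summary$parameter))
})

test_that("permuting insularity destroys the global-model signal", {
  sc <- island_scenario(n_tips = 120, island_effect = 0.1,
                        island_mode = "sorting", min_island_tips = 8,
                        seed = 57)
  ds <- quiet(simulate_dataset(sc))
  tab <- ds$traits
  set.seed(58)
  ps <- vapply(1:5, function(r) {
    tab$insularity <- sample(tab$insularity)
    f <- quiet(fit_bpmm(log(brain_mm3) ~ insularity + log(body_g), tab,
                        tree = ds$tree, species = "species",
                        config = quick_config(seed = 58 + r)))
    pmcmc(f$draws[, "insularity"])
  }, 0)
  expect_gte(sum(ps > 0.05), 4L)  # at most one spurious rejection
})

test_that("family-level colonization model is null when brain-independent", {
  sc <- island_scenario(n_tips = 150, island_effect = 0,
                        min_island_tips = 8, seed = 60,
                        sem = list(rbs_ive = 0, rbs_dvp = 0))
  ds <- quiet(simulate_dataset(sc))
  fam_tree <- family_tree(ds$tree, ds$traits$family, ds$traits$species)
  res <- quiet(family_island_model(ds$traits, fam_tree, ds$tree,
                                   quick_config(seed = 61)))
  s <- res$summary
  i <- s$parameter == "rbs"
  expect_gt(s$ci_high[i], 0)
  expect_lt(s$ci_low[i], 0)
  # degenerate response refuses
  tab0 <- ds$traits; tab0$insularity <- 0
  expect_error(quiet(family_island_model(tab0, fam_tree, ds$tree,
                                         quick_config(seed = 62))),
               "degenerate")
})

test_that("sister models recover a paired island brain effect", {
  sc <- island_scenario(n_tips = 150, island_effect = 0.06,
                        island_mode = "sorting", min_island_tips = 10,
                        seed = 63)
  ds <- quiet(simulate_dataset(sc))
  pairs <- quiet(find_sister_pairs(ds$tree, ds$history$tip_states))
  fits <- quiet(fit_sister_models(pairs, ds$traits, ds$tree,
                                  quick_config(seed = 64)))
  s <- fits$brain$summary
  i <- s$parameter == "insularity"
  expect_gt(s$ci_high[i], 0.0)
  expect_gt(s$mode[i], 0)
  expect_true(all(table(fits$data$pair_id) >= 2))
})

test_that("the island-rule interaction is detected in paired body models", {
  # power per the design: about 100 island-continent pairs
  sc <- island_scenario(n_tips = 400, island_effect = 0, gain = 0.4,
                        island_body_small = 0.4, island_body_large = -0.4,
                        min_island_tips = 100, seed = 65)
  ds <- quiet(simulate_dataset(sc))
  pairs <- quiet(find_sister_pairs(ds$tree, ds$history$tip_states))
  fits <- quiet(fit_sister_models(pairs, ds$traits, ds$tree,
                                  quick_config(seed = 66)))
  s <- fits$body$summary
  i <- s$parameter == "insularity:size_catlarge"
  # small grow, large shrink: negative insularity-by-large interaction
  expect_lt(s$mode[i], 0)
  expect_lt(s$pMCMC[i], 0.05)
})
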