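test_that("simulated trees are ultrametric with the requested tip count", {
  sc <- island_scenario(n_tips = 50, seed = 7)
  tr <- simulate_tree(sc)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 50)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(islandbrains:::node_depths(tr)), 1)
})

test_that("the same seed reproduces a byte-identical Newick string", {
  sc <- island_scenario(n_tips = 30, seed = 99)
  expect_identical(ape::write.tree(simulate_tree(sc)),
                   ape::write.tree(simulate_tree(sc)))
})

test_that("pure-birth crown height matches the analytic expectation", {
  # stop at n tips plus one exponential extension:
  # E[h] = sum_{k=2}^{n-1} 1/(k b) + 1/(n b)
  n <- 8; b <- 1
  expected <- sum(1 / (b * (2:(n - 1)))) + 1 / (n * b)
  hs <- vapply(1:400, function(s) {
    tr <- simulate_tree(island_scenario(n_tips = n, birth = b, death = 0,
                                        seed = s), scale_height = FALSE)
    max(islandbrains:::node_depths(tr))
  }, 0)
  expect_lt(abs(mean(hs) - expected), 3 * sd(hs) / sqrt(length(hs)))
})

test_that("island history: absorbing start, stationarity, Poisson events", {
  tr <- simulate_tree(island_scenario(n_tips = 40, seed = 3))
  h0 <- simulate_island_history(tr, island_scenario(n_tips = 40, gain = 0,
                                                    seed = 3))
  expect_true(all(h0$states == 0))

  # long branches with symmetric rates reach the 50/50 stationary state
  star <- ape::stree(400, type = "star")
  star$edge.length <- rep(50, 400)
  star$tip.label <- paste0("s", 1:400)
  sc <- island_scenario(n_tips = 400, gain = 1, loss = 1,
                        min_island_tips = 0, seed = 5)
  hs <- simulate_island_history(star, sc)
  expect_lt(abs(mean(hs$tip_states) - 0.5), 3 * 0.5 / sqrt(400))

  # with equal rates the event count over all branches is Poisson(rate * L)
  sc2 <- island_scenario(n_tips = 40, gain = 0.5, loss = 0.5,
                         min_island_tips = 0, seed = 8)
  h2 <- simulate_island_history(tr, sc2)
  lam <- 0.5 * sum(tr$edge.length)
  expect_lt(abs(sum(h2$events$transitions) - lam), 4 * sqrt(lam))
})

test_that("generators are reproducible from the scenario seed", {
  sc <- island_scenario(n_tips = 25, seed = 31)
  d1 <- quiet(simulate_dataset(sc))
  d2 <- quiet(simulate_dataset(sc))
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$history$states, d2$history$states)
})

test_that("null island effect leaves island and mainland brains equal", {
  gaps <- vapply(1:20, function(s) {
    sc <- island_scenario(n_tips = 100, island_effect = 0, seed = s,
                          min_island_tips = 5,
                          sem = list(ive = 0, sve = 0, dvp = 0,
                                     rbs_ive = 0, rbs_dvp = 0))
    ds <- quiet(simulate_dataset(sc))
    rb <- relative_brain_size(ds$traits, ds$tree)
    isl <- ds$traits$insularity == 1
    mean(rb[isl]) - mean(rb[!isl])
  }, 0)
  expect_lt(abs(mean(gaps)), 2 * sd(gaps) / sqrt(length(gaps)))
})

test_that("in-situ island effect appears as the PGLS residual gap", {
  gaps <- vapply(1:12, function(s) {
    sc <- island_scenario(n_tips = 150, island_effect = 0.06,
                          island_mode = "insitu", seed = s * 11,
                          min_island_tips = 8,
                          sem = list(ive = 0, sve = 0, dvp = 0,
                                     rbs_ive = 0, rbs_dvp = 0))
    ds <- quiet(simulate_dataset(sc))
    rb <- relative_brain_size(ds$traits, ds$tree)
    isl <- ds$traits$insularity == 1
    mean(rb[isl]) - mean(rb[!isl])
  }, 0)
  expect_lt(abs(mean(gaps) - 0.06), 3 * sd(gaps) / sqrt(length(gaps)))
})

test_that("Brownian rate is recovered by independent contrasts", {
  sc <- island_scenario(n_tips = 250, body_sigma2 = 0.1, seed = 17)
  tr <- simulate_tree(sc)
  h <- quiet(simulate_island_history(tr, sc))
  tab <- quiet(simulate_traits(tr, h, sc))
  pic <- ape::pic(stats::setNames(log(tab$body_g), tab$species), tr)
  v <- mean(pic^2)
  expect_lt(abs(v - 0.1), 3 * 0.1 * sqrt(2 / length(pic)))
})

test_that("emitted ingredient columns reproduce the latent variables", {
  sc <- island_scenario(n_tips = 80, seed = 23)
  ds <- quiet(simulate_dataset(sc))
  truth <- attr(ds$traits, "truth")
  # log CV of EVI is affine in the latent inter-annual variable
  expect_gt(cor(log(ds$traits$evi_interannual), truth$ive_z), 0.999)
  expect_gt(cor(log(ds$traits$evi_seasonal), truth$sve_z), 0.999)
  # developmental period is exactly exp-affine in the latent variable
  expect_gt(cor(log(ds$traits$incubation_d + ds$traits$fledging_d),
                truth$dvp_z), 0.999)
  # coded diet frequencies track the latent breadth coarsely
  expect_gt(cor(ds$traits$diet_breadth, truth$dbr_z), 0.7)
  # diet codes stay in the coded set
  dcols <- as.matrix(ds$traits[, paste0("diet_", food_types())])
  expect_true(all(dcols %in% c(0, 0.1, 0.5, 1)))
  expect_equal(unname(diet_breadth(dcols)), unname(ds$traits$diet_breadth))
})
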