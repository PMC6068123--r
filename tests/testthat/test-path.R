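test_that("basis sets match textbook examples", {
  chain <- causal_model(c("A -> B", "B -> C"))
  bs <- basis_set(chain)
  expect_length(bs, 1L)
  expect_setequal(c(bs[[1]]$x, bs[[1]]$y), c("A", "C"))
  expect_equal(bs[[1]]$given, "B")

  complete3 <- causal_model(c("A -> B", "A -> C", "B -> C"))
  expect_length(basis_set(complete3), 0L)

  best <- causal_model(c("INS -> IVE", "INS -> DVP", "INS -> RBS",
                         "IVE -> RBS", "DVP -> RBS"))
  bs2 <- basis_set(best)
  expect_length(bs2, 1L)
  expect_setequal(c(bs2[[1]]$x, bs2[[1]]$y), c("IVE", "DVP"))
  expect_equal(bs2[[1]]$given, "INS")

  expect_error(causal_model(c("A -> B", "B -> A")), "cycle")
  expect_error(causal_model("A -> A"), "self-edges")
})

test_that("basis-set size equals pairs minus edges on random DAGs", {
  set.seed(90)
  for (rep in 1:30) {
    nv <- sample(3:5, 1)
    vars <- LETTERS[1:nv]
    pairs <- t(combn(vars, 2))  # i < j: acyclic by construction
    m <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
    model <- causal_model(if (nrow(m)) m else matrix(c("A", "B"), 1),
                          variables = vars)
    expect_length(basis_set(model),
                  choose(nv, 2) - nrow(model$edges))
  }
})

test_that("Fisher's C closed forms", {
  expect_equal(fisher_c(c(1, 1)), list(C = 0, df = 4L, p = 1))
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  expect_equal(fisher_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  expect_error(fisher_c(c(0.5, 0)), "p-values")
})

test_that("Fisher's C is chi-squared distributed under the null", {
  set.seed(91)
  C <- replicate(1000, fisher_c(runif(3))$C)
  ks <- stats::ks.test(C, stats::pchisq, df = 6)
  expect_gt(ks$p.value, 0.01)
})

test_that("CICc closed forms and monotonicity in q", {
  expect_equal(cicc(0, 10, 0), 0)
  expect_equal(cicc(2.7726, 100, 8), 2.7726 + 1600 / 91, tolerance = 1e-10)
  expect_equal(cicc(10, 1195, 10), 10 + 23900 / 1184, tolerance = 1e-10)
  expect_error(cicc(1, 5, 5), "undefined")
  v <- vapply(0:8, function(q) cicc(5, 100, q), 0)
  expect_true(all(diff(v) > 0))
})

test_that("GLS claim p-values equal partial-regression t-tests on a star", {
  set.seed(92)
  n <- 60
  d <- data.frame(A = rnorm(n))
  d$B <- 0.5 * d$A + rnorm(n)
  d$C <- 0.7 * d$B + rnorm(n)
  claims <- basis_set(causal_model(c("A -> B", "B -> C")))
  res <- test_independencies(claims, d)
  ref <- summary(lm(scale(C) ~ scale(A) + scale(B), d))$coefficients
  expect_equal(res$p, ref["scale(A)", 4], tolerance = 1e-10)
  # a duplicated column is maximally dependent
  d$D <- d$A
  res2 <- test_independencies(list(list(x = "A", y = "D",
                                        given = character(0))), d)
  expect_lt(res2$p, 1e-20)
})

test_that("an omitted strong effect is detected in the claim test", {
  sc <- island_scenario(n_tips = 500, seed = 93,
                        sem = list(dvp = 0.6, rbs_dvp = 0))
  ds <- quiet(simulate_dataset(sc))
  truth <- attr(ds$traits, "truth")
  d <- data.frame(species = ds$traits$species, INS = ds$traits$insularity,
                  DVP = truth$dvp_z)
  res <- test_independencies(list(list(x = "INS", y = "DVP",
                                       given = character(0))),
                             d, tree = ds$tree)
  expect_lt(res$p, 0.01)
})

test_that("gls and bpmm engines agree on a small dataset", {
  sc <- island_scenario(n_tips = 60, seed = 94)
  ds <- quiet(simulate_dataset(sc))
  truth <- attr(ds$traits, "truth")
  d <- data.frame(species = ds$traits$species, INS = ds$traits$insularity,
                  IVE = truth$ive_z, DVP = truth$dvp_z)
  claims <- list(list(x = "IVE", y = "DVP", given = "INS"))
  gls <- test_independencies(claims, d, tree = ds$tree, engine = "gls")
  bp <- quiet(test_independencies(claims, d, tree = ds$tree, engine = "bpmm",
                                  config = quick_config(seed = 95)))
  expect_equal(gls$estimate, bp$estimate, tolerance = 0.12)
  expect_equal(gls$p > 0.05, bp$p > 0.05)
})

test_that("model ranking is stable and rejects IVE with SVE together", {
  sc <- island_scenario(n_tips = 120, seed = 96)
  ds <- quiet(simulate_dataset(sc))
  truth <- attr(ds$traits, "truth")
  d <- data.frame(species = ds$traits$species, INS = ds$traits$insularity,
                  IVE = truth$ive_z, DVP = truth$dvp_z, DBR = truth$dbr_z,
                  RBS = truth$rbs_z)
  models <- default_path_models()
  rk <- rank_models(models, d, tree = ds$tree)
  expect_equal(nrow(rk$table), 8L)
  expect_true(all(diff(rk$table$CICc) >= 0))
  expect_equal(rk$best$id, rk$table$model_id[1])
  # identical models tie and keep input order
  two <- list(models$direct, models$direct)
  two[[2]]$id <- "direct_copy"
  rk2 <- rank_models(two, d, tree = ds$tree)
  expect_equal(rk2$table$CICc[1], rk2$table$CICc[2])
  expect_equal(rk2$table$model_id, c("direct", "direct_copy"))

  bad <- causal_model(c("INS -> IVE", "INS -> SVE"), id = "bad")
  expect_error(rank_models(list(bad, models$direct), d, tree = ds$tree),
               "IVE and SVE")
})

test_that("default model set has eight DAGs spanning the mechanisms", {
  ms <- default_path_models()
  expect_length(ms, 8L)
  expect_true(all(vapply(ms, inherits, TRUE, "causal_model")))
  kv <- vapply(ms, function(m) length(basis_set(m)), 0L)
  # the full model still claims DBR/IVE/DVP mutual independence given INS
  expect_equal(unname(kv[["full"]]), 3L)
  sv <- default_path_models(seasonal = TRUE)
  expect_true(all(vapply(sv, function(m) "SVE" %in% m$variables, TRUE)))
})
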