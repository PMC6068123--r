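test_that("retained-draw bookkeeping is exact", {
  cfg <- mcmc_config(seed = 1)  # reference schedule
  expect_equal(cfg$retained, 1000L)
  cfg2 <- mcmc_config(iterations = 5050, burnin = 1000, thin = 40, seed = 1)
  expect_equal(cfg2$retained, floor((5050 - 1000) / 40))
  expect_error(mcmc_config(iterations = 3000, burnin = 1000, thin = 40,
                           seed = 1), "at least 100")
  expect_error(mcmc_config(), "seed is mandatory")
})

test_that("retained draws per chain equal the configured count", {
  set.seed(1)
  d <- data.frame(y = rnorm(30))
  cfg <- quick_config(seed = 2, n_chains = 2)
  ch <- quiet(fit_bpmm(y ~ 1, d, config = cfg))
  expect_equal(nrow(ch$draws), 2 * cfg$retained)
  expect_equal(as.vector(table(ch$chain)), rep(cfg$retained, 2))
})

test_that("intercept-only model on a constant-ish response recovers it", {
  d <- data.frame(y = rep(5, 40) + rnorm(40, 0, 1e-3))
  ch <- quiet(fit_bpmm(y ~ 1, d, config = quick_config(seed = 3)))
  expect_equal(mean(ch$draws[, "(Intercept)"]), 5, tolerance = 0.01)
})

test_that("Gaussian sampler matches the closed-form conjugate solution", {
  set.seed(4)
  n <- 100
  x <- rnorm(n); y <- 1.5 + 2 * x + rnorm(n, 0, 0.7)
  d <- data.frame(y = y, x = x)
  ch <- quiet(fit_bpmm(y ~ x, d, config = quick_config(seed = 4)))
  ols <- coef(lm(y ~ x, d))
  for (j in 1:2) {
    mcse <- sd(ch$draws[, j]) / sqrt(effective_size(ch$draws[, j]))
    expect_lt(abs(mean(ch$draws[, j]) - ols[j]), 3 * mcse + 1e-3)
  }
  # posterior variance of the slope matches the frequentist variance
  expect_equal(var(ch$draws[, "x"]),
               summary(lm(y ~ x, d))$coefficients[2, 2]^2,
               tolerance = 0.35)
})

test_that("variance-component draws are strictly positive", {
  sc <- island_scenario(n_tips = 60, seed = 6)
  ds <- quiet(simulate_dataset(sc))
  tab <- derive_columns(ds$traits)
  ch <- quiet(fit_bpmm(log_brain ~ log_body, tab, tree = ds$tree,
                       species = "species", config = quick_config(seed = 6)))
  expect_true(all(ch$draws[, "var_phylo"] > 0))
  expect_true(all(ch$draws[, "var_resid"] > 0))
})

test_that("chains combine by concatenation with preserved identity", {
  d <- data.frame(y = rnorm(30, 1))
  c1 <- quiet(fit_bpmm(y ~ 1, d, config = quick_config(seed = 7)))
  c2 <- quiet(fit_bpmm(y ~ 1, d, config = quick_config(seed = 8)))
  both <- combine_chains(list(c1, c2))
  expect_equal(nrow(both$draws), nrow(c1$draws) + nrow(c2$draws))
  expect_equal(length(unique(both$chain)), 2L)
  # identity on a single chain
  alone <- combine_chains(list(c1))
  expect_identical(alone$draws, c1$draws)
  # mismatched parameters refuse
  c3 <- quiet(fit_bpmm(y ~ 0 + offset_col,
                       data.frame(y = rnorm(30), offset_col = rnorm(30)),
                       config = quick_config(seed = 9)))
  expect_error(combine_chains(list(c1, c3)), "mismatched")
})

test_that("summaries report mode, HPD, pMCMC, ess and lag-1", {
  d <- data.frame(y = rnorm(200, 2))
  ch <- quiet(fit_bpmm(y ~ 1, d, config = quick_config(seed = 10)))
  sm <- summarize_chains(ch)
  expect_setequal(names(sm),
                  c("parameter", "mode", "ci_low", "ci_high", "pMCMC",
                    "ess", "lag1"))
  i <- sm$parameter == "(Intercept)"
  expect_true(sm$ci_low[i] < sm$mode[i] & sm$mode[i] < sm$ci_high[i])
  expect_true(is.na(sm$pMCMC[sm$parameter == "var_resid"]))
  expect_gte(sm$pMCMC[i], 2 / nrow(ch$draws))
})

test_that("binomial counts expand to the binary liability model", {
  # two groups with very different island fractions: slope sign recovered
  set.seed(11)
  d <- data.frame(g = c(1, 2, 3, 4), x = c(-1, -0.5, 0.5, 1),
                  succ = c(1, 2, 8, 12), fail = c(14, 13, 7, 3))
  ch <- quiet(fit_bpmm(cbind(succ, fail) ~ x, d, family = "binomial",
                       config = quick_config(seed = 11)))
  expect_gt(posterior_mode(ch$draws[, "x"]), 0)
  expect_lt(pmcmc(ch$draws[, "x"]), 0.05)
  expect_error(quiet(fit_bpmm(cbind(succ, fail) ~ x,
                              transform(d, succ = 0), family = "binomial",
                              config = quick_config(seed = 1))),
               "degenerate")
})

test_that("high autocorrelation triggers the thinning warning", {
  sc <- island_scenario(n_tips = 40, seed = 12)
  ds <- quiet(simulate_dataset(sc))
  tab <- derive_columns(ds$traits)
  cfg <- scaled_config(seed = 12, iterations = 3100, burnin = 1000, thin = 1,
                       check_autocorr = TRUE)
  expect_warning(
    suppressMessages(fit_bpmm(log_brain ~ log_body, tab, tree = ds$tree,
                              species = "species", config = cfg)),
    "thinning")
})

test_that("chains written to disk round-trip as delimited text", {
  d <- data.frame(y = rnorm(30))
  ch <- quiet(fit_bpmm(y ~ 1, d, config = quick_config(seed = 13)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_chains(ch, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), nrow(ch$draws))
  expect_equal(back$X.Intercept., unname(ch$draws[, 1]), tolerance = 1e-10)
  expect_true(file.exists(paste0(tmp, ".config.txt")))
})
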