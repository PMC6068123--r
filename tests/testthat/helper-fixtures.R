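# Small fixtures shared across test files; everything is built in code.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

tree4 <- function() {
  ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.6,D:0.6):0.4);")
}

# a quick sampler configuration for unit tests (not the desk-scale default)
quick_config <- function(seed, ...) {
  scaled_config(seed = seed, iterations = 7000, burnin = 1000, thin = 20,
                check_autocorr = FALSE, ...)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# random coalescent-ish tree via ape, for property checks
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.01
  tr
}
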