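# Exact node marginals for the binary liability model on tiny trees, by
# grid quadrature over the tip liabilities.  Tip liabilities l ~ N(mu 1,
# s2 Vtt + I) restricted to the orthant matching the observed states; a
# node's liability given l is normal with the usual conditional moments, so
# P(island at node) integrates Phi(m(l)/tau) over the orthant.
exact_node_marginals <- function(tree, states, mu, s2, grid_n = 41) {
  Vfull <- vcv_phylo(tree, include_internal = TRUE)
  tips <- tree$tip.label
  nodes <- setdiff(rownames(Vfull), tips)
  ntip <- length(tips)
  S <- s2 * Vfull[tips, tips] + diag(ntip)
  Si <- solve(S)
  gr <- lapply(tips, function(tp) {
    g <- seq(0, 6, length.out = grid_n)
    if (states[tp] == 1) g else -g
  })
  G <- as.matrix(expand.grid(gr))
  dev <- sweep(G, 2, rep(mu, ntip))
  wts <- exp(-0.5 * rowSums((dev %*% Si) * dev))
  vapply(nodes, function(nd) {
    vn <- s2 * Vfull[nd, tips]
    B <- solve(S, vn)
    tau2 <- s2 * Vfull[nd, nd] - sum(vn * B)
    m <- mu + dev %*% B
    pn <- if (tau2 > 1e-12) pnorm(m / sqrt(tau2)) else as.numeric(m > 0)
    sum(wts * pn) / sum(wts)
  }, 0)
}
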