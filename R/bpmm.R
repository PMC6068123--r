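#' @importFrom Matrix sparseMatrix Diagonal crossprod solve Cholesky bdiag
#'   forceSymmetric update
#' @importFrom stats model.frame model.matrix model.response complete.cases
#'   rnorm runif rgamma qnorm pnorm var acf density sd cor
NULL

#' MCMC configuration for phylogenetic mixed models
#'
#' Defaults follow the reference schedule used for the full-scale analyses:
#' 2,100,000 iterations, 100,000 burn-in, thinning 2,000 (1,000 retained
#' draws per chain), inverse-Wishart variance prior with V = 1, nu = 0.002
#' (implemented for these univariate components as the equivalent
#' inverse-gamma(nu/2, nu V/2)), and diffuse zero-mean normal priors on fixed
#' effects. For binary (liability) models the fixed-effect prior variance
#' defaults to `1 + pi^2/3`, the residual-plus-logistic scaling customary for
#' threshold models. A seed is mandatory: chain r runs with `seed + r`.
#'
#' @param iterations total MCMC iterations per chain.
#' @param burnin discarded initial iterations.
#' @param thin thinning interval; retained draws = floor((iterations - burnin)/thin).
#' @param prior_nu,prior_V inverse-Wishart (here inverse-gamma) variance
#'   hyperparameters.
#' @param fixed_prior_var prior variance of fixed effects; `NULL` means 1e8
#'   for Gaussian responses and `1 + pi^2/3` for binary/binomial ones.
#' @param n_chains replicate chains (the full-scale convention is 5 per tree).
#' @param seed integer base seed (required).
#' @param pmcmc_tails "two" or "one"; how [pmcmc()] is computed in summaries.
#' @param check_autocorr warn when any retained parameter has lag-1
#'   autocorrelation at or above 0.1 (the cue to raise thinning).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 2100000, burnin = 100000, thin = 2000,
                        prior_nu = 0.002, prior_V = 1, fixed_prior_var = NULL,
                        n_chains = 1, seed, pmcmc_tails = c("two", "one"),
                        check_autocorr = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for reproducible runs")
  retained <- floor((iterations - burnin) / thin)
  if (retained < 100) {
    stop("configuration retains ", retained,
         " draws per chain; at least 100 are required")
  }
  structure(list(
    iterations = as.integer(iterations), burnin = as.integer(burnin),
    thin = as.integer(thin), prior_nu = prior_nu, prior_V = prior_V,
    fixed_prior_var = fixed_prior_var, n_chains = as.integer(n_chains),
    seed = as.integer(seed), pmcmc_tails = match.arg(pmcmc_tails),
    check_autocorr = isTRUE(check_autocorr), retained = as.integer(retained)
  ), class = "mcmc_config")
}

#' Desk-scale MCMC configuration
#'
#' The scaled-down schedule used by the test-suite and simulation
#' experiments: 21,000 iterations, 1,000 burn-in, thinning 20 (1,000 retained
#' draws), one chain.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [mcmc_config()].
#' @return an `mcmc_config`.
#' @export
scaled_config <- function(seed, ...) {
  args <- list(iterations = 21000, burnin = 1000, thin = 20,
               n_chains = 1, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(mcmc_config, args)
}

# --- sparse Gaussian sampling ------------------------------------------------

# Draw from N(C^{-1} rhs, C^{-1}) given an (updatable) Cholesky factor of the
# sparse symmetric positive-definite precision C.  With the permuted factor
# P C P' = L L', the draw is  mu + P' L^{-T} z.
sample_gmrf <- function(ch, rhs) {
  mu <- Matrix::solve(ch, rhs, system = "A")
  z <- stats::rnorm(length(rhs))
  v <- Matrix::solve(ch, z, system = "Lt")
  v <- Matrix::solve(ch, v, system = "Pt")
  as.numeric(mu) + as.numeric(v)
}

# Brownian-motion precision over all non-root nodes of a tree (root effect
# pinned at 0, so tip covariance equals the root-to-MRCA path-length matrix).
# Returns list(Q, index) where index maps node numbers -> column of Q.
bm_precision <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- tree$edge[, 2L]
  root <- setdiff(unique(tree$edge[, 1L]), kids)
  free <- setdiff(seq_len(nnode), root)
  index <- integer(nnode)
  index[free] <- seq_along(free)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  len <- tree$edge.length
  if (any(len <= 0)) len[len <= 0] <- max(1e-8, min(len[len > 0]) * 1e-6)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    w <- 1 / len[k]
    ic <- index[ch]
    ii <- c(ii, ic); jj <- c(jj, ic); xx <- c(xx, w)
    if (p != root) {
      ip <- index[p]
      ii <- c(ii, ip, ic, ip); jj <- c(jj, ip, ip, ic); xx <- c(xx, w, -w, -w)
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(free), length(free)))
  Q <- Matrix::forceSymmetric(Q, uplo = "U")
  list(Q = Q, index = index, free = free, n_edges = nrow(tree$edge))
}

truncnorm_draw <- function(mean, positive) {
  lo <- ifelse(positive, stats::pnorm(0, mean, 1), 0)
  hi <- ifelse(positive, 1, stats::pnorm(0, mean, 1))
  u <- stats::runif(length(mean), pmin(lo, hi - 1e-12), pmax(hi, lo + 1e-12))
  q <- mean + stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  # guard the far tail
  ifelse(positive, pmax(q, 1e-10), pmin(q, -1e-10))
}

#' Fit a Bayesian phylogenetic mixed model
#'
#' Gibbs sampler for mixed models whose random effect is structured by a
#' phylogeny (Brownian-motion covariance, realized through its sparse
#' tree-structured precision so ancestral nodes carry effects too), plus any
#' number of i.i.d. grouping random effects (e.g. a sister-pair identifier).
#' Gaussian responses use conjugate location/variance updates; binary and
#' binomial-count responses use probit latent-liability augmentation with the
#' residual variance fixed at 1 (coefficients are reported on the liability
#' scale). Variance components get inverse-gamma(nu/2, nu V/2) priors; fixed
#' effects get independent zero-mean normal priors.
#'
#' @param fixed model formula for the fixed effects, e.g.
#'   `log_brain ~ insularity + log_body` or `value ~ 0 + category` to remove
#'   the global intercept. For `family = "binomial"` the response must be a
#'   two-column `cbind(successes, failures)`.
#' @param data data frame; rows with missing values in any referenced column
#'   are dropped (listwise deletion) and the per-model N is reported via
#'   `message()`.
#' @param family "gaussian", "binary" or "binomial".
#' @param tree optional `phylo`; adds a phylogenetic random effect.
#' @param species column of `data` holding the tree label each row maps to
#'   (tip labels, or internal-node ids `nd#` for node-level responses).
#' @param groups character vector of columns to use as i.i.d. random
#'   intercepts.
#' @param config an [mcmc_config()].
#' @param track_nodes if `TRUE`, retain per-draw latent values
#'   (intercept + node effect) for every tree node; needed for ancestral
#'   state reconstruction.
#' @param fix_var_phylo,fix_var_resid optionally pin a variance component
#'   (used by validation against exact small-tree marginals).
#' @param fix_beta optional numeric vector pinning the fixed effects at given
#'   values (implemented as a degenerate prior; same validation use).
#' @return an object of class `posterior_chains`: list with `draws` (matrix,
#'   one retained draw per row), `chain` (chain id per row), `params`,
#'   `config`, `n`, and optionally `node_draws` + `node_ids`.
#' @export
fit_bpmm <- function(fixed, data, family = c("gaussian", "binary", "binomial"),
                     tree = NULL, species = NULL, groups = character(),
                     config, track_nodes = FALSE,
                     fix_var_phylo = NULL, fix_var_resid = NULL,
                     fix_beta = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(config, "mcmc_config"))

  vars <- unique(c(all.vars(fixed), species, groups))
  vars <- intersect(vars, names(data))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!all(cc)) data <- data[cc, , drop = FALSE]
  message("fit_bpmm: N = ", nrow(data), " complete cases")

  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fixed, mf)
  if (family == "binomial") {
    if (is.null(dim(y)) || ncol(y) != 2L) {
      stop("binomial family needs a cbind(successes, failures) response")
    }
    succ <- y[, 1L]; fail <- y[, 2L]
    if (all(succ == 0) || all(fail == 0)) {
      stop("degenerate binomial response: no variation in outcome")
    }
    rep_idx <- rep(seq_len(nrow(X)), succ + fail)
    ybin <- unlist(mapply(function(s, f) c(rep(1L, s), rep(0L, f)),
                          succ, fail, SIMPLIFY = FALSE))
    X <- X[rep_idx, , drop = FALSE]
    data <- data[rep_idx, , drop = FALSE]
    y <- ybin
    family <- "binary"
  }
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("singular fixed-effect design; check columns: ",
         paste(colnames(X), collapse = ", "))
  }

  # random-effect designs
  Zs <- list(); Qinfo <- NULL; re_sizes <- integer(0); re_names <- character(0)
  if (!is.null(tree)) {
    if (is.null(species)) stop("'species' column required with a phylogeny")
    tree <- validate_tree(tree)
    ids <- node_ids(tree)
    labs <- normalize_labels(as.character(data[[species]]))
    pos <- match(labs, ids)
    if (anyNA(pos)) {
      stop("labels not on tree: ",
           paste(unique(labs[is.na(pos)]), collapse = ", "))
    }
    Qinfo <- bm_precision(tree)
    col <- Qinfo$index[pos]
    nz <- which(col > 0)  # the root's deviation is 0: empty design row
    Zs$phylo <- Matrix::sparseMatrix(i = nz, j = col[nz],
                                     dims = c(n, length(Qinfo$free)))
    re_sizes <- c(re_sizes, length(Qinfo$free))
    re_names <- c(re_names, "phylo")
  }
  for (g in groups) {
    f <- factor(data[[g]])
    Zs[[g]] <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                    dims = c(n, nlevels(f)))
    re_sizes <- c(re_sizes, nlevels(f))
    re_names <- c(re_names, g)
  }

  W <- if (length(Zs)) cbind(Matrix::Matrix(X, sparse = TRUE),
                             do.call(cbind, Zs)) else
    Matrix::Matrix(X, sparse = TRUE)
  K <- Matrix::forceSymmetric(Matrix::crossprod(W))
  d <- ncol(W)

  b_prior_var <- config$fixed_prior_var
  if (is.null(b_prior_var)) {
    b_prior_var <- if (family == "binary") 1 + pi^2 / 3 else 1e8
  }
  if (!is.null(fix_beta)) {
    stopifnot(length(fix_beta) == p)
    b_prior_var <- 1e-10
  }
  prior_rhs <- c(if (is.null(fix_beta)) rep(0, p) else fix_beta / b_prior_var,
                 rep(0, d - p))
  # Precision components share a fixed sparsity pattern; only scalar weights
  # change between iterations, so the heavy symbolic work happens once.
  as_dsc <- function(M) as(as(Matrix::forceSymmetric(M, uplo = "U"),
                              "CsparseMatrix"), "symmetricMatrix")
  embed_block <- function(M, offset) {
    Tm <- as(as(M, "TsparseMatrix"), "symmetricMatrix")
    keep <- Tm@i <= Tm@j  # upper triangle
    Matrix::sparseMatrix(i = Tm@i[keep] + 1L + offset,
                         j = Tm@j[keep] + 1L + offset, x = Tm@x[keep],
                         dims = c(d, d), symmetric = TRUE)
  }
  K <- as_dsc(K)
  comps <- list(K)  # weight 1/se
  comps[[2L]] <- embed_block(Matrix::Diagonal(p, 1 / b_prior_var), 0L)
  off <- p
  for (r in seq_along(re_names)) {
    blk <- if (re_names[r] == "phylo") Qinfo$Q else
      Matrix::Diagonal(re_sizes[r], 1)
    comps[[r + 2L]] <- embed_block(blk, off)
    off <- off + re_sizes[r]
  }
  use_dense <- d <= 150L
  if (use_dense) {
    comps_d <- lapply(comps, as.matrix)
  } else {
    absify <- function(M) { M@x <- abs(M@x) + 1e-300; M }
    S <- Reduce(`+`, lapply(comps, absify))
    S <- as_dsc(S)
    dsc_key <- function(M) {
      j <- rep(seq_len(d), diff(M@p))
      as.numeric(M@i) * d + j
    }
    skey <- dsc_key(S)
    comp_idx <- lapply(comps, function(M) match(dsc_key(as_dsc(M)), skey))
    comp_x <- lapply(comps, function(M) as_dsc(M)@x)
    nx <- length(S@x)
  }

  nu <- config$prior_nu; V0 <- config$prior_V
  n_re <- length(re_names)
  re_df <- vapply(seq_len(n_re), function(r)
    if (re_names[r] == "phylo") Qinfo$n_edges else re_sizes[r], 0)

  par_names <- c(colnames(X),
                 if (n_re) paste0("var_", re_names),
                 if (family == "gaussian") "var_resid")
  n_keep <- config$retained
  ids_all <- if (!is.null(tree)) node_ids(tree) else NULL

  run_chain <- function(chain_id) {
    set.seed(config$seed + chain_id)
    va <- rep(if (family == "gaussian") max(stats::var(y), 0.1) / 2 else 0.5,
              n_re)
    if (!is.null(fix_var_phylo) && "phylo" %in% re_names) {
      va[re_names == "phylo"] <- fix_var_phylo
    }
    se <- if (family == "gaussian") max(stats::var(y), 0.1) else 1
    if (!is.null(fix_var_resid)) se <- fix_var_resid
    lat <- if (family == "binary") ifelse(y > 0, 0.5, -0.5) else as.numeric(y)
    theta <- rep(0, d)
    Wty <- as.numeric(Matrix::crossprod(W, lat))

    weights <- function() c(1 / se, 1, 1 / pmax(va, 1e-10))
    if (!use_dense) {
      Cs <- S
      w <- weights()
      xs <- numeric(nx)
      for (cmp in seq_along(comps)) {
        xs[comp_idx[[cmp]]] <- xs[comp_idx[[cmp]]] + comp_x[[cmp]] * w[cmp]
      }
      Cs@x <- xs
      ch <- Matrix::Cholesky(Cs, LDL = FALSE, perm = TRUE, super = FALSE)
    }

    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    node_draws <- if (track_nodes && !is.null(tree)) {
      matrix(NA_real_, n_keep, length(Qinfo$free))
    } else NULL
    keep_i <- 0L
    total <- config$iterations
    for (it in seq_len(total)) {
      w <- weights()
      rhs <- Wty / se + prior_rhs
      if (use_dense) {
        C <- comps_d[[1L]] * w[1L]
        for (cmp in 2L:length(comps_d)) C <- C + comps_d[[cmp]] * w[cmp]
        R <- chol(C)
        mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
        theta <- mu + backsolve(R, stats::rnorm(d))
      } else {
        xs <- numeric(nx)
        for (cmp in seq_along(comps)) {
          xs[comp_idx[[cmp]]] <- xs[comp_idx[[cmp]]] + comp_x[[cmp]] * w[cmp]
        }
        Cs@x <- xs
        ch <- Matrix::update(ch, Cs)
        theta <- sample_gmrf(ch, rhs)
      }
      if (any(!is.finite(theta))) {
        bad <- par_names[which(!is.finite(theta[seq_len(p)]))[1L]]
        stop("divergent chain: non-finite draw for parameter ",
             if (is.na(bad)) "random effect" else bad)
      }
      eta <- as.numeric(W %*% theta)
      if (family == "binary") {
        lat <- truncnorm_draw(eta, y > 0)
        Wty <- as.numeric(Matrix::crossprod(W, lat))
      }
      # variance updates
      off <- p
      for (r in seq_len(n_re)) {
        u <- theta[off + seq_len(re_sizes[r])]
        ss <- if (re_names[r] == "phylo") {
          as.numeric(Matrix::crossprod(u, Qinfo$Q %*% u))
        } else sum(u^2)
        if (!(re_names[r] == "phylo" && !is.null(fix_var_phylo))) {
          va[r] <- 1 / stats::rgamma(1, shape = (nu + re_df[r]) / 2,
                                     rate = (nu * V0 + ss) / 2)
        }
        off <- off + re_sizes[r]
      }
      if (family == "gaussian" && is.null(fix_var_resid)) {
        rss <- sum((lat - eta)^2)
        se <- 1 / stats::rgamma(1, shape = (nu + n) / 2,
                                rate = (nu * V0 + rss) / 2)
      }
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0 &&
          keep_i < n_keep) {
        keep_i <- keep_i + 1L
        row <- c(theta[seq_len(p)], if (n_re) va,
                 if (family == "gaussian") se)
        draws[keep_i, ] <- row
        if (!is.null(node_draws)) {
          b0 <- if ("(Intercept)" %in% colnames(X)) {
            theta[match("(Intercept)", colnames(X))]
          } else 0
          node_draws[keep_i, ] <- b0 + theta[p + seq_len(re_sizes[1L])]
        }
      }
    }
    list(draws = draws[seq_len(keep_i), , drop = FALSE],
         node_draws = if (!is.null(node_draws))
           node_draws[seq_len(keep_i), , drop = FALSE])
  }

  chains <- lapply(seq_len(config$n_chains), run_chain)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$n_chains),
                  vapply(chains, function(cc) nrow(cc$draws), 0L))
  out <- structure(list(
    draws = draws, chain = chain_id, params = par_names,
    config = config, n = n, family = family
  ), class = "posterior_chains")
  if (track_nodes && !is.null(tree)) {
    nd <- do.call(rbind, lapply(chains, `[[`, "node_draws"))
    colnames(nd) <- ids_all[Qinfo$free]
    out$node_draws <- nd
    out$root_id <- ids_all[setdiff(seq_along(ids_all), Qinfo$free)]
  }
  if (config$check_autocorr) {
    l1 <- apply(draws, 2L, lag1_autocorr)
    if (any(l1 >= 0.1, na.rm = TRUE)) {
      warning("lag-1 autocorrelation >= 0.1 for: ",
              paste(par_names[l1 >= 0.1], collapse = ", "),
              "; raise the thinning interval", call. = FALSE)
    }
  }
  out
}

#' Combine replicate chains
#'
#' Concatenates the retained draws of several runs of the same model (the
#' full-scale convention pools 5 chains per backbone tree), preserving chain
#' identity.
#'
#' @param chains a list of `posterior_chains` with identical parameter sets.
#' @return a single `posterior_chains`.
#' @export
combine_chains <- function(chains) {
  if (inherits(chains, "posterior_chains")) return(chains)
  stopifnot(length(chains) >= 1L)
  params <- chains[[1L]]$params
  for (cc in chains) {
    if (!identical(cc$params, params)) {
      stop("mismatched parameter sets across chains")
    }
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  offset <- 0L
  chain <- integer(0)
  for (cc in chains) {
    chain <- c(chain, cc$chain + offset)
    offset <- offset + max(cc$chain)
  }
  out <- chains[[1L]]
  out$draws <- draws
  out$chain <- chain
  if (!is.null(chains[[1L]]$node_draws) &&
      all(vapply(chains, function(cc) !is.null(cc$node_draws), TRUE))) {
    out$node_draws <- do.call(rbind, lapply(chains, `[[`, "node_draws"))
  }
  out
}

#' Summarize posterior chains
#'
#' Per parameter: posterior mode (Gaussian kernel density, Silverman
#' bandwidth), 95% highest-posterior-density interval, pMCMC (two-tailed
#' 2 x min-tail by default, floored at 2/N; not reported for variance
#' components, which are positive by construction), effective sample size and
#' lag-1 autocorrelation.
#'
#' @param chains a `posterior_chains` object (>= 100 draws per parameter).
#' @param prob credible mass for the HPD interval.
#' @return a `data.frame` of class `posterior_summary` with columns
#'   `parameter, mode, ci_low, ci_high, pMCMC, ess, lag1`.
#' @export
summarize_chains <- function(chains, prob = 0.95) {
  stopifnot(inherits(chains, "posterior_chains"))
  draws <- chains$draws
  if (nrow(draws) < 100L) stop("need at least 100 retained draws")
  tails <- chains$config$pmcmc_tails
  rows <- lapply(colnames(draws), function(pn) {
    x <- draws[, pn]
    data.frame(
      parameter = pn,
      mode = posterior_mode(x),
      ci_low = hpd_interval(x, prob)[1L],
      ci_high = hpd_interval(x, prob)[2L],
      pMCMC = if (startsWith(pn, "var_")) NA_real_ else pmcmc(x, tails),
      ess = effective_size(x),
      lag1 = lag1_autocorr(x)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  attr(out, "n") <- chains$n
  out
}

#' @method print posterior_summary
#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (N =", attr(x, "n"), "observations)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write retained draws as delimited text
#'
#' One column per parameter, one row per retained draw, plus a side-car
#' `<path>.config.txt` recording the sampler configuration.
#'
#' @param chains a `posterior_chains`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  df <- data.frame(chain = chains$chain, chains$draws, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- chains$config
  writeLines(paste0(names(unclass(cfg)), "\t",
                    vapply(unclass(cfg), paste, "", collapse = ",")),
             paste0(path, ".config.txt"))
  invisible(path)
}
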