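#' Ancestral island-state reconstruction
#'
#' First step of the two-step transition analysis: a binary phylogenetic
#' mixed model (probit latent liability, intercept + tree-structured random
#' effect over all nodes) is fitted to the contemporary island/mainland
#' states, and the posterior probability that each internal node is insular
#' is the fraction of retained draws in which the node's latent liability
#' (intercept + node effect) is positive.
#'
#' @param tree a `phylo`.
#' @param tip_states named 0/1 vector over all tips (1 = island).
#' @param config an [mcmc_config()].
#' @param ... passed to [fit_bpmm()] (e.g. `fix_var_phylo` for validation).
#' @return data frame of class `node_state_estimate`: `node` (internal node
#'   id `nd#`), `p_island`. The fitted chains are attached as attribute
#'   `"chains"`.
#' @export
reconstruct_island_states <- function(tree, tip_states, config, ...) {
  tree <- validate_tree(tree)
  tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states)) stop("tip_states must cover every tip")
  if (length(unique(tip_states)) == 1L) {
    warning("monomorphic tip states: reconstruction carries no information ",
            "on transitions")
  }
  dat <- data.frame(species = tree$tip.label, state = as.integer(tip_states))
  ch <- fit_bpmm(state ~ 1, dat, family = "binary", tree = tree,
                 species = "species", config = config, track_nodes = TRUE, ...)
  ids <- colnames(ch$node_draws)
  internal <- grepl("^nd", ids)
  p <- colMeans(ch$node_draws[, internal, drop = FALSE] > 0)
  out <- data.frame(node = ids[internal], p_island = as.numeric(p),
                    row.names = NULL)
  # the root is pinned in the random effect; its liability is the intercept
  root_p <- mean(ch$draws[, "(Intercept)"] > 0)
  out <- rbind(out, data.frame(node = ch$root_id, p_island = root_p))
  class(out) <- c("node_state_estimate", "data.frame")
  attr(out, "chains") <- ch
  out
}

#' Classify nodes and categorize ancestor-descendant transitions
#'
#' Internal nodes are classified island when `p_island > threshold`,
#' continental when `1 - p_island > threshold`, otherwise left unclassified
#' and excluded. Every classified ancestor whose child (the node or tip one
#' edge below) is also classified yields a transition category:
#' alpha (continent -> continent), beta (continent -> island),
#' gamma (island -> island), delta (island -> continent). The delta category
#' is retained in the output but flagged `insufficient_for_modelling`, as
#' island losses are too rare to model.
#'
#' @param tree a `phylo`.
#' @param estimates a `node_state_estimate` (or any data frame with `node`,
#'   `p_island` covering all internal nodes). Tips are classified by their
#'   observed state, which must be supplied via `tip_states`.
#' @param tip_states named 0/1 vector over tips.
#' @param threshold posterior-probability cutoff (default 0.90).
#' @return data frame of class `transition_categories`: `ancestor`, `child`,
#'   `ancestor_state`, `child_state`, `category`,
#'   `insufficient_for_modelling`. Attribute `"classification"` holds the
#'   per-node state table.
#' @export
classify_and_categorize <- function(tree, estimates, tip_states,
                                    threshold = 0.90) {
  ids <- node_ids(tree)
  p <- stats::setNames(estimates$p_island, estimates$node)
  cls <- ifelse(p > threshold, "island",
                ifelse(1 - p > threshold, "continent", "unclassified"))
  tip_cls <- ifelse(tip_states[tree$tip.label] == 1, "island", "continent")
  state_of <- c(cls, stats::setNames(tip_cls, tree$tip.label))

  rows <- list()
  for (k in seq_len(nrow(tree$edge))) {
    anc <- ids[as.character(tree$edge[k, 1L])]
    chd <- ids[as.character(tree$edge[k, 2L])]
    sa <- state_of[anc]; sc <- state_of[chd]
    if (is.na(sa) || is.na(sc)) next
    if (sa == "unclassified" || sc == "unclassified") next
    cat_k <- if (sa == "continent" && sc == "continent") "alpha"
    else if (sa == "continent" && sc == "island") "beta"
    else if (sa == "island" && sc == "island") "gamma"
    else "delta"
    rows[[length(rows) + 1L]] <- data.frame(
      ancestor = anc, child = chd, ancestor_state = sa, child_state = sc,
      category = cat_k, insufficient_for_modelling = cat_k == "delta",
      row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ancestor = character(0), child = character(0),
               ancestor_state = character(0), child_state = character(0),
               category = character(0),
               insufficient_for_modelling = logical(0))
  class(out) <- c("transition_categories", "data.frame")
  attr(out, "classification") <-
    data.frame(node = names(cls), p_island = as.numeric(p[names(cls)]),
               classification = as.character(cls), row.names = NULL)
  out
}

#' Ancestral values of a continuous trait under Brownian motion
#'
#' Generalized-least-squares (conditional-mean) estimates at internal nodes:
#' the root takes the GLS phylogenetic mean mu = (1'V^-1 1)^-1 1'V^-1 y, and
#' every node takes mu + V_nt V_tt^-1 (y - mu), where V_tt is the tip
#' covariance and V_nt the node-tip block. Estimates always lie within the
#' range of the tip values.
#'
#' @param tree a `phylo`.
#' @param tip_values named numeric vector over all tips (e.g. relative brain
#'   size).
#' @param propagate_uncertainty if `TRUE`, each node value is an independent
#'   draw from its conditional posterior (conditional mean plus normal noise
#'   with the node's conditional standard deviation) instead of the bare
#'   conditional mean. Feeding bare conditional means into a downstream
#'   mixed model collapses its residual variance -- the smooth interpolated
#'   field is absorbed entirely by the phylogenetic random effect -- so
#'   propagation is recommended (and is the pipeline default) whenever the
#'   values are modelled further.
#' @param rate Brownian rate used for the conditional variances; `NULL`
#'   estimates it from the mean squared phylogenetically independent
#'   contrast.
#' @param seed seed for the conditional draws (required when propagating).
#' @return named numeric vector over internal node ids (`nd#`).
#' @export
ancestral_brain_values <- function(tree, tip_values,
                                   propagate_uncertainty = FALSE,
                                   rate = NULL, seed = NULL) {
  tree <- validate_tree(tree)
  tip_values <- tip_values[tree$tip.label]
  if (anyNA(tip_values)) stop("tip_values must cover every tip")
  Vfull <- vcv_phylo(tree, include_internal = TRUE)
  tips <- tree$tip.label
  nodes <- setdiff(rownames(Vfull), tips)
  Vtt <- Vfull[tips, tips]
  Vnt <- Vfull[nodes, tips, drop = FALSE]
  # tiny ridge keeps zero-length cherries invertible
  diag(Vtt) <- diag(Vtt) + 1e-10 * max(diag(Vtt))
  Vinv_y <- solve(Vtt, cbind(tip_values, 1))
  mu <- sum(Vinv_y[, 1L]) / sum(Vinv_y[, 2L])
  B <- solve(Vtt, t(Vnt))
  a <- mu + as.numeric(Vnt %*% solve(Vtt, tip_values - mu))
  if (propagate_uncertainty) {
    if (is.null(seed)) stop("a seed is required when propagating uncertainty")
    if (is.null(rate)) {
      pic <- ape::pic(tip_values, ape::multi2di(tree))
      rate <- mean(pic^2)
    }
    margv <- rate * pmax(diag(Vfull[nodes, nodes, drop = FALSE]) -
                           colSums(t(Vnt) * B), 0)
    set.seed(seed)
    a <- a + stats::rnorm(length(nodes), 0, sqrt(margv))
  }
  stats::setNames(a, nodes)
}

#' Transition-category contrasts in ancestral brain size
#'
#' Second step of the two-step analysis: a no-intercept mixed model of
#' ancestral relative brain values on the transition category, with the
#' node-level phylogenetic covariance as random effect, giving the posterior
#' of each category mean. A node contributes one observation per category it
#' instantiates. The derived contrasts answer the two questions of the
#' design: `beta_minus_alpha` (did big brains precede colonization?) and
#' `gamma_minus_beta` (did brains grow in situ after colonization?);
#' `gamma_minus_alpha` is also reported. Categories with fewer than
#' `min_nodes` nodes (typically delta) are dropped with a warning.
#'
#' @param node_values named vector of ancestral brain values
#'   ([ancestral_brain_values()]).
#' @param categories a `transition_categories` data frame.
#' @param tree a `phylo`.
#' @param config an [mcmc_config()].
#' @param min_nodes minimum nodes per category (default 3).
#' @return list: `chains`, `summary` (category means), `contrasts`
#'   (data frame with mode, HPD interval and pMCMC per contrast), `n_nodes`.
#' @export
fit_transition_model <- function(node_values, categories, tree, config,
                                 min_nodes = 3) {
  obs <- unique(categories[, c("ancestor", "category")])
  obs <- obs[obs$ancestor %in% names(node_values), ]
  counts <- table(obs$category)
  drop <- names(counts)[counts < min_nodes]
  if (length(drop)) {
    warning("categories dropped (fewer than ", min_nodes, " nodes): ",
            paste(drop, collapse = ", "))
    obs <- obs[!obs$category %in% drop, ]
  }
  if (length(unique(obs$category)) < 2L) {
    stop("need at least two categories with sufficient nodes")
  }
  obs$value <- node_values[obs$ancestor]
  obs$category <- factor(obs$category)
  ch <- fit_bpmm(value ~ 0 + category, obs, family = "gaussian", tree = tree,
                 species = "ancestor", config = config)
  sm <- summarize_chains(ch)

  draws <- ch$draws
  contrast <- function(a, b) {
    ca <- paste0("category", a); cb <- paste0("category", b)
    if (!all(c(ca, cb) %in% colnames(draws))) return(NULL)
    d <- draws[, ca] - draws[, cb]
    data.frame(contrast = paste0(a, "_minus_", b), mode = posterior_mode(d),
               ci_low = hpd_interval(d)[1L], ci_high = hpd_interval(d)[2L],
               pMCMC = pmcmc(d, ch$config$pmcmc_tails), row.names = NULL)
  }
  ctr <- do.call(rbind, Filter(Negate(is.null), list(
    contrast("beta", "alpha"), contrast("gamma", "beta"),
    contrast("gamma", "alpha"))))
  list(chains = ch, summary = sm, contrasts = ctr, n_nodes = nrow(obs))
}

#' Full ancestral-transition pipeline
#'
#' Reconstruction, classification, ancestral brain values and the
#' category-contrast model in one call.
#'
#' @param tree a `phylo`.
#' @param tip_states named 0/1 island states over tips.
#' @param tip_brain named relative brain size over tips.
#' @param config an [mcmc_config()].
#' @param threshold node classification threshold (default 0.90).
#' @param propagate_uncertainty propagate per-node reconstruction
#'   uncertainty into the contrast model (default `TRUE`; see
#'   [ancestral_brain_values()]).
#' @param n_imputations number of imputed node-value sets when propagating
#'   uncertainty; the contrast model is fitted to each and the chains are
#'   pooled, integrating over reconstruction noise rather than conditioning
#'   on one realization (default 4; ignored when not propagating).
#' @param imputation_config optional lighter [mcmc_config()] for the
#'   per-imputation contrast fits (default: the main `config`).
#' @return list: `estimates`, `categories`, `node_values` (first imputation
#'   when propagating), `model` (the pooled [fit_transition_model()]
#'   result).
#' @export
ancestral_transition_analysis <- function(tree, tip_states, tip_brain, config,
                                          threshold = 0.90,
                                          propagate_uncertainty = TRUE,
                                          n_imputations = 4,
                                          imputation_config = NULL) {
  est <- reconstruct_island_states(tree, tip_states, config)
  cats <- classify_and_categorize(tree, est, tip_states, threshold)
  if (!propagate_uncertainty) n_imputations <- 1L
  base_cfg <- if (is.null(imputation_config)) config else imputation_config
  fits <- vector("list", n_imputations)
  vals1 <- NULL
  for (m in seq_len(n_imputations)) {
    vals <- ancestral_brain_values(tree, tip_brain,
                                   propagate_uncertainty = propagate_uncertainty,
                                   seed = config$seed + 31L * m)
    if (m == 1L) vals1 <- vals
    cfg_m <- base_cfg
    cfg_m$seed <- base_cfg$seed + 97L * m
    fits[[m]] <- fit_transition_model(vals, cats, tree, cfg_m)
  }
  model <- fits[[1L]]
  if (n_imputations > 1L) {
    pooled <- combine_chains(lapply(fits, function(f) f$chains))
    model$chains <- pooled
    model$summary <- summarize_chains(pooled)
    draws <- pooled$draws
    contrast <- function(a, b) {
      ca <- paste0("category", a); cb <- paste0("category", b)
      if (!all(c(ca, cb) %in% colnames(draws))) return(NULL)
      d <- draws[, ca] - draws[, cb]
      data.frame(contrast = paste0(a, "_minus_", b),
                 mode = posterior_mode(d),
                 ci_low = hpd_interval(d)[1L], ci_high = hpd_interval(d)[2L],
                 pMCMC = pmcmc(d, pooled$config$pmcmc_tails),
                 row.names = NULL)
    }
    model$contrasts <- do.call(rbind, Filter(Negate(is.null), list(
      contrast("beta", "alpha"), contrast("gamma", "beta"),
      contrast("gamma", "alpha"))))
  }
  list(estimates = est, categories = cats, node_values = vals1, model = model)
}

#' Write a tree annotated with node classifications
#'
#' Writes Newick with internal-node labels of the form
#' `<node_id>:<classification>` (island / continent / unclassified), for
#' visualizing reconstructed island histories.
#'
#' @param tree a `phylo`.
#' @param classification data frame with `node` and `classification`
#'   columns (the `"classification"` attribute of
#'   [classify_and_categorize()] output).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tree, classification, path) {
  ids <- node_ids(tree)
  ntip <- length(tree$tip.label)
  internal_ids <- ids[as.character((ntip + 1L):(ntip + tree$Nnode))]
  cls <- stats::setNames(classification$classification, classification$node)
  lab <- paste0(internal_ids, ":",
                ifelse(is.na(cls[internal_ids]), "unclassified",
                       cls[internal_ids]))
  tr <- tree
  tr$node.label <- gsub("[():,;]", "_", lab)
  ape::write.tree(tr, file = path)
  invisible(path)
}
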