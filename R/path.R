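#' Define a causal model (DAG)
#'
#' @param edges character vector of directed edges, `"A -> B"` (arrow with or
#'   without spaces), or a two-column matrix/data frame (from, to).
#' @param id optional model label.
#' @param variables optional superset of variable names (isolated variables
#'   are allowed and generate independence claims).
#' @return list of class `causal_model`: `variables`, `edges` (two-column
#'   character matrix), `id`. Cycles and self-edges are rejected.
#' @export
causal_model <- function(edges, id = NULL, variables = NULL) {
  if (is.character(edges) && is.null(dim(edges))) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("edges must look like 'A -> B'")
    em <- cbind(trimws(vapply(parts, `[[`, "", 1L)),
                trimws(vapply(parts, `[[`, "", 2L)))
  } else {
    em <- as.matrix(edges)
    stopifnot(ncol(em) == 2L)
  }
  if (any(em[, 1L] == em[, 2L])) stop("self-edges are not allowed")
  if (anyDuplicated(paste(em[, 1L], em[, 2L]))) stop("duplicate edges")
  vars <- unique(c(variables, as.vector(t(em))))
  # topological sort (Kahn); failure = cycle
  order <- character(0)
  remaining <- em
  pool <- vars
  while (length(pool)) {
    has_parent <- pool %in% remaining[, 2L]
    free <- pool[!has_parent]
    if (!length(free)) stop("the edge set contains a cycle")
    order <- c(order, free)
    remaining <- remaining[!(remaining[, 1L] %in% free), , drop = FALSE]
    pool <- setdiff(pool, free)
  }
  structure(list(variables = vars, edges = em, id = id, topo = order),
            class = "causal_model")
}

parents_of <- function(model, v) {
  model$edges[model$edges[, 2L] == v, 1L]
}

#' D-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent variable pair,
#' conditioned on the union of both variables' parents. Within each claim
#' the regression response is the pair member that comes later in the
#' topological order (so the claim is tested in the direction causally
#' downstream); pairs are enumerated in a deterministic canonical order.
#'
#' @param model a [causal_model()].
#' @return list of claims, each `list(x, y, given)`: the claim is
#'   `y _||_ x | given`. The number of claims k equals the number of
#'   variable pairs minus the number of edges.
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "causal_model"))
  vars <- model$topo
  adjacent <- paste(pmin(model$edges[, 1L], model$edges[, 2L]),
                    pmax(model$edges[, 1L], model$edges[, 2L]))
  claims <- list()
  nv <- length(vars)
  if (nv < 2L) return(claims)
  for (i in seq_len(nv - 1L)) {
    for (j in seq((i + 1L), nv)) {
      a <- vars[i]; b <- vars[j]  # b later in topological order
      if (paste(min(a, b), max(a, b)) %in% adjacent) next
      given <- setdiff(unique(c(parents_of(model, a), parents_of(model, b))),
                       c(a, b))
      claims[[length(claims) + 1L]] <- list(x = a, y = b, given = given)
    }
  }
  claims
}

#' Test the independence claims of a basis set
#'
#' For each claim `y _||_ x | z`, fits the phylogenetic regression of `y` on
#' `x` and `z` and reports the significance of `x`'s coefficient: a GLS
#' t-test under Brownian covariance (`engine = "gls"`, closed-form and
#' deterministic) or the pMCMC of a Bayesian phylogenetic mixed model
#' (`engine = "bpmm"`). Variables are Z-transformed over the complete cases
#' before testing.
#'
#' @param claims list of claims from [basis_set()].
#' @param data data frame holding the path variables; rows are species.
#' @param tree a `phylo`; `data` must have a `species` column mapping rows
#'   to tips (ignored rows dropped). `NULL` means a star phylogeny
#'   (ordinary regression).
#' @param engine "gls" or "bpmm".
#' @param config an [mcmc_config()], required for the bpmm engine.
#' @param V optional precomputed tip covariance (rows named by species);
#'   avoids recomputing it for every candidate model.
#' @return data frame: `x`, `y`, `given`, `estimate`, `p`.
#' @export
test_independencies <- function(claims, data, tree = NULL,
                                engine = c("gls", "bpmm"), config = NULL,
                                V = NULL) {
  engine <- match.arg(engine)
  if (!length(claims)) {
    return(data.frame(x = character(0), y = character(0), given = character(0),
                      estimate = numeric(0), p = numeric(0)))
  }
  vars <- unique(unlist(lapply(claims, function(cl) c(cl$x, cl$y, cl$given))))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  zd <- data
  for (v in vars) zd[[v]] <- z_transform(data[[v]])
  if (!is.null(tree) && engine == "gls") {
    sp <- normalize_labels(as.character(zd$species))
    if (is.null(V)) V <- vcv_phylo(tree)
    V <- V[sp, sp]
  } else V <- NULL
  rows <- lapply(claims, function(cl) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(zd[, c(cl$x, cl$given), drop = FALSE]))
    y <- zd[[cl$y]]
    if (engine == "gls") {
      Vv <- if (is.null(V)) diag(length(y)) else V
      fit <- pgls_fit(y, X, Vv)
      est <- fit$coefficients$estimate[fit$coefficients$term == cl$x]
      p <- fit$coefficients$p[fit$coefficients$term == cl$x]
    } else {
      if (is.null(config)) stop("the bpmm engine needs an mcmc_config")
      fml <- stats::reformulate(c(cl$x, cl$given), response = cl$y)
      ch <- fit_bpmm(fml, zd, family = "gaussian", tree = tree,
                     species = if (!is.null(tree)) "species", config = config)
      est <- posterior_mode(ch$draws[, cl$x])
      p <- pmcmc(ch$draws[, cl$x], config$pmcmc_tails)
    }
    data.frame(x = cl$x, y = cl$y, given = paste(cl$given, collapse = "+"),
               estimate = est, p = p, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Fisher's C statistic
#'
#' C = -2 * sum(log p_i) over the basis-set p-values, referred to a
#' chi-squared distribution with 2k degrees of freedom. A non-significant C
#' means the causal model is consistent with the data. P-values are floored
#' at 1e-12 before logging; an empty claim set gives C = 0, df = 0,
#' model p = 1 (a saturated model always fits).
#'
#' @param p_values numeric vector in (0, 1].
#' @return list: `C`, `df`, `p`.
#' @export
fisher_c <- function(p_values) {
  if (!length(p_values)) return(list(C = 0, df = 0L, p = 1))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  C <- -2 * sum(log(pmax(p_values, 1e-12)))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' CICc information criterion for path models
#'
#' CICc = C + 2q n / (n - q - 1), where C is Fisher's C, n the sample size
#' and q the number of parameters plus linking relationships; lower is
#' better.
#'
#' @param C Fisher's C statistic.
#' @param n sample size (must exceed q + 1).
#' @param q parameter count.
#' @return scalar CICc.
#' @export
cicc <- function(C, n, q) {
  if (n <= q + 1) stop("CICc undefined: n must exceed q + 1")
  C + 2 * q * n / (n - q - 1)
}

#' Fit one causal model to comparative data
#'
#' Runs the d-separation test of a DAG: basis-set claims, per-claim
#' p-values, Fisher's C with its model p-value, CICc (with q = number of
#' edges + number of exogenous variances, reported per model), and the
#' standardized coefficient of every edge from the phylogenetic regression
#' of each endogenous variable on its parents.
#'
#' @param model a [causal_model()].
#' @param data species data frame (needs `species` when a tree is used).
#' @param tree optional `phylo`.
#' @param engine "gls" (default) or "bpmm".
#' @param config an [mcmc_config()] for the bpmm engine.
#' @return list of class `path_fit`: `id`, `k`, `claims` (with p-values),
#'   `C`, `df`, `p`, `q`, `n`, `CICc`, `coefficients` (per edge: estimate
#'   and p or pMCMC).
#' @export
fit_path_model <- function(model, data, tree = NULL,
                           engine = c("gls", "bpmm"), config = NULL,
                           V = NULL) {
  engine <- match.arg(engine)
  claims <- basis_set(model)
  vars <- model$variables
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  tested <- test_independencies(claims, data, tree, engine, config, V = V)
  fc <- fisher_c(tested$p)
  exo <- vars[!vars %in% model$edges[, 2L]]
  q <- nrow(model$edges) + length(exo)

  zd <- data
  for (v in vars) zd[[v]] <- z_transform(data[[v]])
  V <- if (!is.null(tree) && engine == "gls") {
    sp <- normalize_labels(as.character(zd$species))
    if (is.null(V)) V <- vcv_phylo(tree)
    V[sp, sp]
  } else NULL
  coefs <- list()
  for (v in setdiff(vars, exo)) {
    pa <- parents_of(model, v)
    if (engine == "gls") {
      X <- cbind(`(Intercept)` = 1, as.matrix(zd[, pa, drop = FALSE]))
      Vv <- if (is.null(V)) diag(n) else V
      fit <- pgls_fit(zd[[v]], X, Vv)
      cf <- fit$coefficients[fit$coefficients$term %in% pa, ]
      coefs[[v]] <- data.frame(from = cf$term, to = v,
                               estimate = cf$estimate, p = cf$p,
                               row.names = NULL)
    } else {
      fml <- stats::reformulate(pa, response = v)
      ch <- fit_bpmm(fml, zd, family = "gaussian", tree = tree,
                     species = if (!is.null(tree)) "species", config = config)
      coefs[[v]] <- data.frame(
        from = pa, to = v,
        estimate = vapply(pa, function(x) posterior_mode(ch$draws[, x]), 0),
        p = vapply(pa, function(x)
          pmcmc(ch$draws[, x], config$pmcmc_tails), 0),
        row.names = NULL)
    }
  }
  structure(list(
    id = model$id, k = length(claims), claims = tested,
    C = fc$C, df = fc$df, p = fc$p, q = q, n = n,
    CICc = cicc(fc$C, n, q),
    coefficients = do.call(rbind, coefs)
  ), class = "path_fit")
}

#' Rank candidate causal models by CICc
#'
#' Fits every model and orders them by ascending CICc (stable order on
#' ties). Models mixing inter-annual and seasonal environmental-variation
#' variables are rejected up front, since the two summaries of the same
#' vegetation index cannot enter one model together.
#'
#' @param models list of [causal_model()] objects.
#' @param data species data frame.
#' @param tree optional `phylo`.
#' @param engine "gls" or "bpmm".
#' @param config an [mcmc_config()] for the bpmm engine.
#' @param forbid_together character pair that may not co-occur in a model
#'   (default `c("IVE", "SVE")`).
#' @return list: `table` (model_id, k, C, df, p, q, n, CICc, in CICc order),
#'   `fits` (named by model id), `best` (the lowest-CICc `path_fit`).
#' @export
rank_models <- function(models, data, tree = NULL,
                        engine = c("gls", "bpmm"), config = NULL,
                        forbid_together = c("IVE", "SVE")) {
  engine <- match.arg(engine)
  if (length(models) < 2L) stop("need at least two candidate models")
  for (m in models) {
    if (all(forbid_together %in% m$variables)) {
      stop("model '", m$id, "' contains both ",
           paste(forbid_together, collapse = " and "))
    }
  }
  ids <- vapply(seq_along(models), function(i)
    if (is.null(models[[i]]$id)) paste0("model", i) else models[[i]]$id, "")
  V <- if (!is.null(tree) && engine == "gls") vcv_phylo(tree) else NULL
  fits <- lapply(models, fit_path_model, data = data, tree = tree,
                 engine = engine, config = config, V = V)
  names(fits) <- ids
  tab <- data.frame(
    model_id = ids,
    k = vapply(fits, `[[`, 0L, "k"),
    C = vapply(fits, `[[`, 0, "C"),
    df = vapply(fits, `[[`, 0L, "df"),
    p = vapply(fits, `[[`, 0, "p"),
    q = vapply(fits, `[[`, 0, "q"),
    n = vapply(fits, `[[`, 0L, "n"),
    CICc = vapply(fits, `[[`, 0, "CICc"),
    row.names = NULL
  )
  ord <- order(tab$CICc)  # stable: ties keep input order
  tab <- tab[ord, ]
  list(table = tab, fits = fits, best = fits[[tab$model_id[1L]]])
}

#' Default candidate path models
#'
#' Eight causal scenarios over insularity (INS), diet breadth (DBR),
#' developmental period (DVP), inter-annual environmental variation (IVE)
#' and relative brain size (RBS). Every model lets insularity shape the
#' three candidate mediators (INS -> DBR, INS -> DVP, INS -> IVE) and keeps
#' the direct INS -> RBS edge; they differ in which mediators feed brain
#' size: none (direct-only), each alone, each pair, or all three. Use
#' `seasonal = TRUE` for the variant set with seasonal variation (SVE)
#' replacing IVE.
#'
#' @param seasonal use SVE instead of IVE.
#' @return named list of [causal_model()] objects.
#' @export
default_path_models <- function(seasonal = FALSE) {
  env <- if (seasonal) "SVE" else "IVE"
  base <- c(paste("INS ->", c("DBR", "DVP", env)), "INS -> RBS")
  mk <- function(id, extra = character(0)) {
    causal_model(c(base, extra), id = id)
  }
  models <- list(
    direct = mk("direct"),
    niche = mk("niche", "DBR -> RBS"),
    lifehistory = mk("lifehistory", "DVP -> RBS"),
    environment = mk("environment", paste(env, "-> RBS")),
    niche_lifehistory = mk("niche_lifehistory",
                           c("DBR -> RBS", "DVP -> RBS")),
    niche_environment = mk("niche_environment",
                           c("DBR -> RBS", paste(env, "-> RBS"))),
    environment_lifehistory = mk("environment_lifehistory",
                                 c(paste(env, "-> RBS"), "DVP -> RBS")),
    full = mk("full", c("DBR -> RBS", "DVP -> RBS", paste(env, "-> RBS")))
  )
  models
}
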