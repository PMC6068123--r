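#' Global insularity models
#'
#' The cross-species mixed models relating (log) brain volume to oceanic
#' insularity with phylogeny as a random effect:
#' * model 1: `log_brain ~ insularity + log_body`;
#' * model 2: model 1 restricted to species measured on at least
#'   `min_specimens` individuals;
#' * model 4: model 1 plus migratory behaviour and developmental mode.
#' (The numbering follows the supplementary-table convention of the study
#' system; the intermediate variant is not part of the module.)
#'
#' @param table trait table (see [read_trait_table()]); [derive_columns()] is
#'   applied internally.
#' @param tree a `phylo` covering the species.
#' @param config an [mcmc_config()].
#' @param min_specimens specimen-count filter for model 2 (default 3).
#' @return named list of fits; each element has `chains`
#'   (`posterior_chains`), `summary` (`posterior_summary`) and `n`.
#' @export
fit_global_models <- function(table, tree, config, min_specimens = 3) {
  table <- derive_columns(table)
  table$dev_mode <- factor(table$dev_mode)
  fits <- list()
  run <- function(formula, data, label) {
    ch <- fit_bpmm(formula, data, family = "gaussian", tree = tree,
                   species = "species", config = config)
    list(chains = ch, summary = summarize_chains(ch), n = ch$n)
  }
  fits$model1 <- run(log_brain ~ insularity + log_body, table)
  sub <- table[!is.na(table$n_specimens) & table$n_specimens >= min_specimens, ]
  fits$model2 <- run(log_brain ~ insularity + log_body, sub)
  fits$model4 <- run(log_brain ~ insularity + log_body + migratory + dev_mode,
                     table)
  fits
}

#' Family-level colonization model
#'
#' Do families with relatively larger brains contain more island species?
#' Counts of island vs continental species per family are modelled as
#' binomial with the family's mean relative brain size as predictor and the
#' family phylogeny as a random effect. A positive slope would indicate that
#' big-brained clades colonize islands disproportionately (sorting); the
#' in-situ hypothesis predicts a slope near zero.
#'
#' @param table trait table with `family`, `insularity`, brain and body
#'   columns.
#' @param family_tree `phylo` whose tips are family names.
#' @param tree species-level `phylo` used for the relative-brain residuals.
#' @param config an [mcmc_config()].
#' @return list with `chains`, `summary`, `data` (per-family counts and mean
#'   relative brain size).
#' @export
family_island_model <- function(table, family_tree, tree, config) {
  rbs <- relative_brain_size(table, tree)
  table$rbs <- rbs[normalize_labels(table$species)]
  agg <- stats::aggregate(cbind(islands = insularity, total = 1, rbs = rbs) ~ family,
                          data = table, FUN = function(x) sum(x))
  agg$rbs <- agg$rbs / agg$total  # mean relative brain size per family
  agg <- agg[agg$total > 0, ]
  drop <- setdiff(agg$family, family_tree$tip.label)
  if (length(drop)) {
    warning("families missing from family tree, excluded: ",
            paste(drop, collapse = ", "))
    agg <- agg[agg$family %in% family_tree$tip.label, ]
  }
  if (all(agg$islands == 0) || all(agg$islands == agg$total)) {
    stop("degenerate response: no variation in island occupancy across families")
  }
  agg$continental <- agg$total - agg$islands
  ch <- fit_bpmm(cbind(islands, continental) ~ rbs, agg, family = "binomial",
                 tree = family_tree, species = "family", config = config)
  list(chains = ch, summary = summarize_chains(ch), data = agg)
}

#' Pair island species with their closest continental relatives
#'
#' For every island species, the continental species at minimal patristic
#' distance form its sister set (ties within `tol` grouped; tied sets are
#' refined to the members at minimal topological edge-count distance, so an
#' exactly ultrametric tree yields the nearest subclade rather than an
#' entire tied sister clade). Each continental
#' species joins at most one pair: conflicts go to the island species with
#' the smaller distance and the loser is re-paired to its next-closest free
#' continental taxon (each re-pairing is reported via `message()`). The
#' result is permutation-invariant to input species order.
#'
#' @param tree a `phylo`.
#' @param insularity named 0/1 vector over tips (1 = island).
#' @param tol distance tolerance for grouping ties (default 1e-8).
#' @return data frame of class `sister_pairs`: `island_species`,
#'   `sister_species`, `pair_id`, `distance` (one row per continental member).
#' @export
find_sister_pairs <- function(tree, insularity, tol = 1e-8) {
  insularity <- insularity[tree$tip.label]
  isl <- names(insularity)[insularity == 1]
  con <- names(insularity)[insularity == 0]
  if (!length(isl) || !length(con)) {
    stop("need at least one island and one continental species")
  }
  D <- patristic_matrix(tree)[isl, con, drop = FALSE]
  utree <- tree
  utree$edge.length <- rep(1, nrow(tree$edge))
  De <- patristic_matrix(utree)[isl, con, drop = FALSE]  # edge counts
  # deterministic processing order: ascending minimal distance, then name
  dmin <- apply(D, 1L, min)
  ord <- order(dmin, isl)
  taken <- character(0)
  rows <- list()
  pid <- 0L
  for (i in ord) {
    d <- D[i, setdiff(con, taken), drop = TRUE]
    if (!length(d)) break
    nm <- setdiff(con, taken)
    best <- min(d)
    sisters <- nm[d <= best + tol]
    if (length(sisters) > 1L) {
      e <- De[i, sisters]
      sisters <- sisters[e == min(e)]
    }
    if (best > dmin[i] + tol) {
      message("find_sister_pairs: ", isl[i],
              " re-paired to next-closest continental taxon (",
              signif(best, 6), " > ", signif(dmin[i], 6), ")")
    }
    pid <- pid + 1L
    rows[[pid]] <- data.frame(island_species = isl[i],
                              sister_species = sisters,
                              pair_id = paste0("pair", pid),
                              distance = best, row.names = NULL)
    taken <- c(taken, sisters)
  }
  out <- do.call(rbind, rows)
  # stable presentation order: by island species name
  out <- out[order(out$island_species, out$sister_species), ]
  row.names(out) <- NULL
  class(out) <- c("sister_pairs", "data.frame")
  out
}

#' Paired sister-taxa models
#'
#' Three mixed models on the species involved in island-continent sister
#' pairs, each with the pair identifier as a random effect (the paired-test
#' structure):
#' * `brain`: relative brain size ~ insularity;
#' * `body`: log body mass ~ insularity x body-size category (the island-rule
#'   test: small species growing and large species shrinking on islands show
#'   up as a positive interaction);
#' * `brain_x_size`: relative brain size ~ insularity x body-size category.
#' The body-size category (above/below median log body mass, ties = small)
#' is computed on the paired subset. Phylogeny can be added as a second
#' random effect via `include_phylo`.
#'
#' @param pairs a `sister_pairs` data frame from [find_sister_pairs()].
#' @param table trait table covering the paired species.
#' @param tree a `phylo` (used for relative brain size, and optionally as a
#'   random effect).
#' @param config an [mcmc_config()].
#' @param include_phylo add the phylogenetic random effect (default `FALSE`;
#'   the paired design already absorbs shared history within pairs).
#' @return named list of fits (`chains`, `summary`, `n`) plus the assembled
#'   `data`.
#' @export
fit_sister_models <- function(pairs, table, tree, config,
                              include_phylo = FALSE) {
  rbs <- relative_brain_size(table, tree)
  long <- rbind(
    data.frame(species = pairs$island_species, pair_id = pairs$pair_id,
               insularity = 1L),
    data.frame(species = pairs$sister_species, pair_id = pairs$pair_id,
               insularity = 0L)
  )
  long <- unique(long)
  idx <- match(long$species, normalize_labels(table$species))
  long$body_g <- table$body_g[idx]
  long$rbs <- rbs[long$species]
  long$log_body <- log(long$body_g)
  med <- stats::median(long$log_body, na.rm = TRUE)
  long$size_cat <- ifelse(long$log_body > med, "large", "small")
  long$size_cat <- factor(long$size_cat, levels = c("small", "large"))

  ptree <- if (include_phylo) tree else NULL
  spcol <- if (include_phylo) "species" else NULL
  run <- function(formula) {
    ch <- fit_bpmm(formula, long, family = "gaussian", tree = ptree,
                   species = spcol, groups = "pair_id", config = config)
    list(chains = ch, summary = summarize_chains(ch), n = ch$n)
  }
  list(
    brain = run(rbs ~ insularity),
    body = run(log_body ~ insularity * size_cat),
    brain_x_size = run(rbs ~ insularity * size_cat),
    data = long
  )
}

#' Collapse a species tree to one tip per family
#'
#' Keeps the first species of each family and relabels it with the family
#' name: the family-level phylogeny used as random-effect structure in
#' [family_island_model()].
#'
#' @param tree species-level `phylo`.
#' @param families character vector of family assignments.
#' @param species matching species labels.
#' @return a `phylo` with one tip per family.
#' @export
family_tree <- function(tree, families, species) {
  species <- normalize_labels(as.character(species))
  fam <- stats::setNames(as.character(families), species)[tree$tip.label]
  keep <- !duplicated(fam) & !is.na(fam)
  tr <- ape::keep.tip(tree, tree$tip.label[keep])
  tr$tip.label <- unname(fam[tr$tip.label])
  tr
}
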