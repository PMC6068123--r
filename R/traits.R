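#' The ten food-use categories of the diet scoring scheme
#' @return character vector of length 10.
#' @export
food_types <- function() {
  c("invertebrates", "vertebrates_endotherm", "vertebrates_ectotherm",
    "fish", "vertebrates_unknown", "carrion", "fruit", "nectar",
    "seeds", "other_plant")
}

#' Synthetic nutritional dissimilarity between food types
#'
#' A documented placeholder: pairwise dissimilarities over the ten food-use
#' categories built from a coarse grouping into animal prey, carrion, and
#' plant material (0 on the diagonal, small within a nutritional group, large
#' across groups). The empirically derived nutritional matrix used in the
#' original analyses is not reproduced here; supply your own matrix to
#' [diet_breadth()] whenever results should rest on measured nutrient
#' content. Any diet-breadth value therefore depends on this configuration
#' by design.
#'
#' @return a symmetric 10 x 10 matrix with zero diagonal, entries in [0, 1].
#' @export
default_food_dissimilarity <- function() {
  types <- food_types()
  group <- c(invertebrates = "animal", vertebrates_endotherm = "animal",
             vertebrates_ectotherm = "animal", fish = "animal",
             vertebrates_unknown = "animal", carrion = "carrion",
             fruit = "plant", nectar = "plant", seeds = "plant",
             other_plant = "plant")
  D <- matrix(0, 10, 10, dimnames = list(types, types))
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    D[i, j] <- if (group[types[i]] == group[types[j]]) 0.3 else 1
  }
  # carrion is nutritionally closer to animal prey than to plants
  D["carrion", group == "animal"] <- 0.5
  D[group == "animal", "carrion"] <- 0.5
  D
}

#' Diet breadth as Rao's quadratic entropy
#'
#' Q = sum_ij d_ij p_i p_j, where p are the food-use frequencies normalized
#' to sum 1 and d is a dissimilarity matrix over food types. Frequencies are
#' coded 1 (almost exclusively used), 0.5 (often used), 0.1 (rarely used),
#' 0 (not used); the index is invariant to rescaling of the frequency vector.
#'
#' @param frequencies numeric vector (one species) or matrix/data.frame
#'   (rows = species) of food-use frequencies, 10 columns in the order of
#'   [food_types()].
#' @param dissimilarity square symmetric matrix with zero diagonal and
#'   entries in [0, 1]; defaults to [default_food_dissimilarity()].
#' @return scalar or vector of Rao Q values; `NA` where all frequencies are
#'   zero (niche undefined).
#' @export
diet_breadth <- function(frequencies, dissimilarity = default_food_dissimilarity()) {
  D <- as.matrix(dissimilarity)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12) ||
      any(diag(D) != 0) || any(D < 0) || any(D > 1)) {
    stop("dissimilarity must be square, symmetric, zero-diagonal, in [0,1]")
  }
  one <- function(p) {
    s <- sum(p)
    if (s <= 0) return(NA_real_)
    p <- p / s
    as.numeric(p %*% D %*% p)
  }
  if (is.null(dim(frequencies))) return(one(as.numeric(frequencies)))
  apply(as.matrix(frequencies), 1L, one)
}

#' Vegetation-index variability summaries
#'
#' From a years x within-year-periods matrix of EVI values: inter-annual
#' variation = coefficient of variation of the yearly means (sample sd /
#' mean), and seasonality = the annual amplitude (within-year max - min)
#' averaged across years.
#'
#' @param evi numeric matrix, rows = years (>= 2), columns = periods within
#'   year (>= 2), non-negative values.
#' @return named numeric vector `c(interannual, seasonal)`; `interannual` is
#'   `NA` when the grand mean is zero.
#' @export
evi_variability <- function(evi) {
  evi <- as.matrix(evi)
  if (nrow(evi) < 2L || ncol(evi) < 2L) stop("need >= 2 years and >= 2 periods")
  if (any(evi < 0)) stop("EVI values must be non-negative")
  ym <- rowMeans(evi)
  gm <- mean(ym)
  cv <- if (gm > 0) stats::sd(ym) / gm else NA_real_
  amp <- mean(apply(evi, 1L, function(r) max(r) - min(r)))
  c(interannual = cv, seasonal = amp)
}

#' Relative brain size (allometric residuals)
#'
#' Residuals of log brain volume on log body mass from a phylogenetic GLS
#' regression under Brownian-motion covariance: the proxy for brain
#' enlargement beyond allometry used throughout. An optional Pagel's lambda
#' multiplies the off-diagonal covariance.
#'
#' @param table data frame with species, brain and body columns.
#' @param tree a `phylo` covering the species.
#' @param species,brain,body column names (defaults `species`, `brain_mm3`,
#'   `body_g`).
#' @param lambda optional phylogenetic-signal multiplier on off-diagonal
#'   covariance entries (default 1, pure Brownian motion).
#' @return named numeric vector of residuals, one per usable species; species
#'   absent from the tree are excluded with a warning. The underlying
#'   [pgls_fit] is attached as attribute `"fit"`.
#' @export
relative_brain_size <- function(table, tree, species = "species",
                                brain = "brain_mm3", body = "body_g",
                                lambda = 1) {
  sp <- normalize_labels(as.character(table[[species]]))
  ok <- !is.na(table[[brain]]) & !is.na(table[[body]])
  on_tree <- sp %in% tree$tip.label
  if (any(ok & !on_tree)) {
    warning("species missing from tree, excluded: ",
            paste(sp[ok & !on_tree], collapse = ", "))
  }
  use <- ok & on_tree
  sp <- sp[use]
  if (any(table[[brain]][use] <= 0) || any(table[[body]][use] <= 0)) {
    stop("brain and body must be strictly positive")
  }
  V <- vcv_phylo(tree)[sp, sp]
  if (lambda != 1) {
    dg <- diag(V)
    V <- V * lambda
    diag(V) <- dg
  }
  y <- log(table[[brain]][use])
  X <- cbind(`(Intercept)` = 1, log_body = log(table[[body]][use]))
  fit <- pgls_fit(y, X, V)
  res <- stats::setNames(fit$residuals, sp)
  attr(res, "fit") <- fit
  res
}

#' Derived trait columns
#'
#' Adds: `dev_period` (incubation + fledging, days), `log_brain`,
#' `log_body`, and `body_category` ("large" when log body mass is strictly
#' above the median of complete cases, "small" otherwise -- ties count as
#' small). Z-scoring is left to each fitted model, which standardizes within
#' its own complete cases.
#'
#' @param table trait data frame.
#' @param brain,body,incubation,fledging column names.
#' @return the table with the derived columns appended.
#' @export
derive_columns <- function(table, brain = "brain_mm3", body = "body_g",
                           incubation = "incubation_d", fledging = "fledging_d") {
  if (all(c(incubation, fledging) %in% names(table))) {
    inc <- table[[incubation]]; fle <- table[[fledging]]
    if (any(inc < 0 | fle < 0, na.rm = TRUE)) {
      stop("negative incubation or fledging durations")
    }
    table$dev_period <- inc + fle
  }
  if (brain %in% names(table)) table$log_brain <- log(table[[brain]])
  if (body %in% names(table)) {
    lb <- log(table[[body]])
    table$log_body <- lb
    med <- stats::median(lb, na.rm = TRUE)
    table$body_category <- ifelse(lb > med, "large", "small")
  }
  table
}

#' Read / write a species trait table
#'
#' Plain CSV with empty fields for missing values. The expected column
#' dictionary: `species` (tree tip label), `family`, `brain_mm3` (endocast
#' volume), `body_g` (body mass), `insularity` (1 = oceanic-island endemic),
#' `migratory` (1 = migrant), `dev_mode` ("precocial"/"altricial"),
#' `incubation_d`, `fledging_d`, ten `diet_*` frequency columns coded in
#' {0, 0.1, 0.5, 1}, `evi_interannual`, `evi_seasonal`, `latitude`,
#' `n_specimens`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' @rdname read_trait_table
#' @param table data frame to write.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
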