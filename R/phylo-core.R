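#' @importFrom ape read.tree read.nexus write.tree write.nexus mrca
#'   node.depth.edgelength getMRCA prop.part drop.tip is.ultrametric
NULL

# Tip labels are matched exactly after trimming surrounding whitespace and
# normalizing internal runs of whitespace to underscores.
normalize_labels <- function(x) gsub("[[:space:]]+", "_", trimws(x))

#' Validate a phylogenetic tree
#'
#' Checks the invariants assumed everywhere downstream: a single root,
#' non-negative branch lengths, unique tip labels. Polytomies are allowed.
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly, with normalized tip labels.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree$tip.label <- normalize_labels(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  # exactly one root: one node that never appears as a child
  kids <- tree$edge[, 2L]
  parents <- unique(tree$edge[, 1L])
  roots <- setdiff(parents, kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

#' Read phylogenetic trees from Newick or Nexus
#'
#' @param path file path.
#' @param format "auto" (sniff a leading `#NEXUS`), "newick" or "nexus".
#' @return a list of validated `phylo` trees (always a list, even for one).
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", head1, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("parse error in '", path, "': ", conditionMessage(e))
  )
  if (is.null(trees)) stop("parse error in '", path, "': no trees found")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    tr <- validate_tree(tr)
    tr
  })
  trees
}

#' Write trees to Newick or Nexus
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output file.
#' @param format "newick" or "nexus".
#' @param digits significant digits for branch lengths (default 6).
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus"), digits = 6) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  if (format == "nexus") {
    ape::write.nexus(trees, file = path, translate = TRUE)
  } else {
    ape::write.tree(trees, file = path, digits = digits)
  }
  invisible(path)
}

#' Deterministic internal-node identifiers
#'
#' Internal nodes receive ids `nd1, nd2, ...` in postorder-traversal order, so
#' node-level results are reproducible across runs and across functions. Tips
#' keep their labels.
#'
#' @param tree a `phylo` object.
#' @return named character vector mapping every node number (as character) to
#'   its id: tip labels for tips, `nd#` for internal nodes.
#' @export
node_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  internal <- unique(po$edge[, 1L])
  ids <- character(ntip + tree$Nnode)
  ids[seq_len(ntip)] <- tree$tip.label
  ids[internal] <- paste0("nd", seq_along(internal))
  names(ids) <- as.character(seq_along(ids))
  ids
}

# depths[i] = path length from root to node i (ape numbering)
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the path length from the root to the most recent common
#' ancestor of nodes i and j: the Brownian-motion covariance structure that
#' enters every phylogenetic model in the package, optionally extended to
#' internal (ancestral) nodes.
#'
#' @param tree a `phylo` object.
#' @param taxa optional character vector of tip labels and/or internal node
#'   ids (`nd#`, see [node_ids()]) selecting and ordering rows.
#' @param include_internal if `TRUE`, the matrix covers internal nodes too.
#' @return symmetric positive semi-definite matrix with dimnames.
#' @export
vcv_phylo <- function(tree, taxa = NULL, include_internal = FALSE) {
  tree <- validate_tree(tree)
  depths <- node_depths(tree)
  ids <- node_ids(tree)
  ntip <- length(tree$tip.label)
  m <- ape::mrca(tree, full = include_internal)
  V <- matrix(depths[m], nrow = nrow(m))
  keep <- if (include_internal) seq_along(ids) else seq_len(ntip)
  dimnames(V) <- list(ids[keep], ids[keep])
  if (!is.null(taxa)) {
    taxa <- normalize_labels(taxa)
    miss <- setdiff(taxa, rownames(V))
    if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
    V <- V[taxa, taxa, drop = FALSE]
  }
  V
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the path connecting tips `a` and `b`.
#'
#' @param tree a `phylo` object.
#' @param a,b tip labels.
#' @return non-negative scalar; 0 when `a == b`.
#' @export
patristic_distance <- function(tree, a, b) {
  a <- normalize_labels(a); b <- normalize_labels(b)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip: ", a)
  if (is.na(ib)) stop("unknown tip: ", b)
  if (ia == ib) return(0)
  depths <- node_depths(tree)
  anc <- ape::getMRCA(tree, c(ia, ib))
  depths[ia] + depths[ib] - 2 * depths[anc]
}

#' All pairwise patristic distances between tips
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix of path-length distances, tips as dimnames.
#' @export
patristic_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# canonical string key per clade (set of subtended tip labels)
clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  internal <- unique(po$edge[, 1L])
  vapply(internal, function(nd) paste(sort(below[[nd]]), collapse = "|"), "")
}

#' Maximum clade credibility tree
#'
#' Scores each tree in a set by the sum of log clade frequencies (clade
#' support computed across the whole set) and returns the highest-scoring
#' member; ties resolve to the first tree encountered. The log-sum form
#' avoids underflow of the clade-frequency product on large trees.
#'
#' @param trees a list of `phylo` objects (or `multiPhylo`) with identical
#'   tip sets.
#' @return the selected `phylo`, with attribute `"log_clade_score"`.
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, validate_tree)
  if (!length(trees)) stop("empty tree set")
  tipsets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(unique(vapply(tipsets, paste, "", collapse = "|"))) != 1L) {
    stop("trees have differing tip sets")
  }
  keys <- lapply(trees, clade_keys)
  freq <- table(unlist(keys)) / length(trees)
  scores <- vapply(keys, function(k) sum(log(freq[k])), 0)
  best <- which.max(scores)  # ties -> first
  out <- trees[[best]]
  attr(out, "log_clade_score") <- scores[best]
  out
}
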