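#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()], followed by a cleanup of the
#' small negative branch lengths NJ can produce: each negative edge is set
#' to zero and its deficit is transferred to the sibling edge (pairwise path
#' lengths through the parent are preserved).
#'
#' @param dist Symmetric zero-diagonal distance matrix (or `dist`) over at
#'   least 3 samples.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3L) abort("neighbor-joining needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  tree <- ape::nj(as.dist(d))
  clamp_negative_edges(tree)
}

# Zero out negative branch lengths, moving each deficit onto the sibling
# edge under the same parent node so parent-to-tip path sums are unchanged.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Resamples loci (columns) with replacement `B` times, rebuilds the
#' p-distance NJ tree on each replicate, and scores each internal
#' bipartition of the reference tree by the fraction of replicates
#' containing it. Supports are attached as node labels.
#'
#' @param gm A [genotype_matrix()] (or `consensus_matrix`).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param tree Optional reference tree; defaults to the NJ tree of the full
#'   data.
#' @return List: `tree` (reference tree with `node.label` set to support
#'   fractions), `support` (numeric per internal node, `NA` for the root).
#' @export
bootstrap_support <- function(gm, B = 1000L, seed = 1L, tree = NULL) {
  if (is.null(tree)) tree <- nj_tree(p_distance(gm))
  if (B == 0L) {
    return(list(tree = tree, support = numeric(0)))
  }
  set.seed(derive_seed(seed, "bootstrap"))
  m <- nrow(gm$loci)
  if (m < 1L) abort("bootstrap needs at least one locus")
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(m, m, replace = TRUE)
    sub <- list(
      geno = gm$geno[, idx, drop = FALSE],
      samples = gm$samples %||% gm$varieties
    )
    reps[[b]] <- nj_tree(p_distance_boot(sub$geno, sub$samples))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  support <- counts / B
  tree$node.label <- formatC(support, format = "f", digits = 3)
  list(tree = tree, support = support)
}

# p-distance tolerant of zero-overlap pairs (bootstrap replicates may lose
# all common loci for a pair; fall back to maximal distance 1).
p_distance_boot <- function(g, labels) {
  obs <- !is.na(g)
  storage.mode(obs) <- "double"
  common <- obs %*% t(obs)
  matches <- matrix(0, nrow(g), nrow(g))
  for (v in 0:2) {
    ind <- (!is.na(g) & g == v)
    storage.mode(ind) <- "double"
    matches <- matches + ind %*% t(ind)
  }
  d <- ifelse(common > 0, (common - matches) / common, 1)
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Write a tree in Newick format
#' @param tree An [ape::phylo] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Do groups form monophyletic clades on a tree?
#'
#' @param tree An [ape::phylo] tree whose tips are samples.
#' @param varieties Sample-to-cultivar map.
#' @return Named logical, one entry per cultivar.
#' @export
clades_monophyletic <- function(tree, varieties) {
  varieties <- variety_assignment(varieties)
  vapply(split(varieties$sample, varieties$variety), function(tips) {
    ape::is.monophyletic(tree, tips)
  }, logical(1))
}
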