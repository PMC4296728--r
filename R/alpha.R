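#' Observed richness
#'
#' Number of taxa with abundance strictly greater than zero.
#'
#' @param x non-negative numeric vector of per-taxon counts or abundances.
#' @return Integer count of observed taxa.
#' @export
richness <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  sum(x > 0)
}

#' Shannon diversity index
#'
#' `-sum(p * log(p))` over positive proportions, in nats by default.
#'
#' @param p proportions summing to 1.
#' @param base logarithm base; `exp(1)` (nats) by default, `2` for bits.
#' @return Shannon index.
#' @export
shannon <- function(p, base = exp(1)) {
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1` the number of
#' singletons and `F2` the number of doubletons. The bias-corrected form is
#' finite even when no doubletons are observed.
#'
#' @param counts non-negative integer counts per taxon.
#' @return Estimated richness (`>= richness(counts)`).
#' @export
chao1 <- function(counts) {
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("chao1 requires integer counts, not proportions")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Inverse Simpson index
#'
#' `1 / sum(p^2)`; equals the number of taxa under a uniform composition.
#'
#' @inheritParams shannon
#' @return Inverse Simpson diversity.
#' @export
inverse_simpson <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  1 / sum(p^2)
}

#' Faith's phylogenetic diversity (whole-tree variant)
#'
#' Sum of the branch lengths of the minimal subtree spanning the root and
#' all present taxa, including the path connecting them to the root.
#'
#' @param present character vector of present taxon (leaf) names.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @return Total branch length of the spanning subtree; 0 for no taxa.
#' @export
faith_pd <- function(present, tree) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  if (!length(present)) return(0)
  ntip <- length(tree$tip.label)
  # mark every node whose subtree holds a present leaf; an edge belongs to
  # the spanning subtree iff its child node is marked
  marked <- logical(ntip + tree$Nnode)
  marked[match(present, tree$tip.label)] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    e <- ord$edge[k, ]
    if (marked[e[2]]) marked[e[1]] <- TRUE
  }
  sum(tree$edge.length[marked[tree$edge[, 2]]])
}

#' Per-sample alpha diversity table
#'
#' Computes observed richness, Shannon (nats), bias-corrected Chao1,
#' inverse Simpson, and (when a tree is supplied) Faith's whole-tree
#' phylogenetic diversity for every sample. Estimators run at the finest
#' (OTU) level of the table as provided.
#'
#' @param table counts-mode [taxon_table()].
#' @param tree optional rooted `ape::phylo` covering the table's taxa.
#' @param base logarithm base for Shannon.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL, base = exp(1)) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$mode != "counts")
    stop("alpha diversity (Chao1) requires a counts-mode table")
  vals <- table$values
  props <- sweep(vals, 1, rowSums(vals), "/")
  out <- data.frame(
    sample_id = table$sample_ids,
    richness = apply(vals, 1, richness),
    shannon = apply(props, 1, shannon, base = base),
    chao1 = apply(vals, 1, chao1),
    inverse_simpson = apply(props, 1, inverse_simpson),
    stringsAsFactors = FALSE)
  if (!is.null(tree))
    out$faith_pd <- apply(vals, 1, function(v)
      faith_pd(table$taxon_ids[v > 0], tree))
  rownames(out) <- NULL
  out
}
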