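#' Kullback-Leibler divergence between two compositions
#'
#' `sum over k with p_k > 0 of p_k * log(p_k / q_k)`, with the convention
#' `0 * log(0/q) = 0`. When some `p_k > 0` has `q_k = 0` the divergence is
#' infinite and `Inf` is returned.
#'
#' @param p,q non-negative vectors of equal length summing to 1.
#' @param base logarithm base (natural log by default).
#' @return Non-negative real, possibly `Inf`.
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  if (length(p) != length(q)) stop("compositions differ in length")
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * log(p[i] / q[i])) / log(base)
}

#' Jensen-Shannon divergence between two compositions
#'
#' Symmetrised, bounded divergence: the average of the K-L divergences of
#' each composition to their midpoint `(p + q) / 2`. Always finite, zero iff
#' the compositions are identical, and at most `log(2)` in the chosen base.
#'
#' @inheritParams kl_divergence
#' @return JSD in `[0, log(2)/log(base)]`.
#' @export
js_divergence <- function(p, q, base = exp(1)) {
  if (length(p) != length(q)) stop("compositions differ in length")
  m <- (p + q) / 2
  (kl_divergence(p, m, base) + kl_divergence(q, m, base)) / 2
}

# row entropies with 0 log 0 = 0, natural log
.row_entropy <- function(x) {
  lx <- ifelse(x > 0, log(x), 0)
  -rowSums(x * lx)
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' Computes all pairwise JSD values between the samples of a relative-mode
#' table. Internally uses the entropy identity
#' `JSD(P,Q) = H(M) - (H(P) + H(Q)) / 2` with `M` the midpoint, which is
#' algebraically equal to the K-L-based definition but vectorises over
#' samples.
#'
#' @param table relative-mode [taxon_table()] (convert with
#'   [to_relative()] first).
#' @param base logarithm base.
#' @return A symmetric `n x n` matrix of class `"divergence_matrix"` with a
#'   zero diagonal, sample ids as dimnames, and the table's taxonomic level
#'   (if tagged) in attribute `"level"`.
#' @export
divergence_matrix <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$mode != "relative")
    stop("divergence requires a relative-mode table; call to_relative() first")
  x <- table$values
  if (any(rowSums(x) == 0))
    stop("sample(s) with all-zero composition")
  n <- nrow(x)
  h <- .row_entropy(x)
  d <- matrix(0, n, n, dimnames = list(table$sample_ids, table$sample_ids))
  for (i in seq_len(max(n - 1, 0))) {
    j <- (i + 1):n
    m <- sweep(x[j, , drop = FALSE], 2, x[i, ], "+") / 2
    hm <- .row_entropy(m)
    v <- hm - (h[i] + h[j]) / 2
    v <- pmin(pmax(v, 0), log(2)) / log(base)
    d[i, j] <- v
    d[j, i] <- v
  }
  structure(d, class = c("divergence_matrix", "matrix"),
            level = table$level)
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("divergence_matrix: %d samples%s\n", nrow(x),
              if (!is.null(attr(x, "level")))
                paste0(" (", attr(x, "level"), " level)") else ""))
  cat(sprintf("  JSD range [%.4g, %.4g] nats\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Write a divergence matrix as square TSV
#'
#' @param d a [divergence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_divergence_matrix <- function(d, path) {
  utils::write.table(format(unclass(d), digits = 15), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Hierarchical community clusters from a divergence matrix
#'
#' Agglomerative clustering of samples on the JSD matrix, cut to exactly
#' `K` clusters labelled `A`, `B`, ... in dendrogram order. Average linkage
#' on raw JSD is the default; `method = "ward"` applies Ward's criterion to
#' `sqrt(JSD)`, which is a metric while JSD itself is not.
#'
#' @param d a [divergence_matrix()] (or symmetric matrix).
#' @param K number of clusters, `1 <= K <= n`.
#' @param method `"average"` or `"ward"`.
#' @return Object of class `"cluster_assignment"`: list with `assignment`
#'   (named character vector of cluster labels), `hclust`, `K`, `method`.
#' @export
hierarchical_clusters <- function(d, K = 4, method = c("average", "ward")) {
  method <- match.arg(method)
  n <- nrow(d)
  if (K < 1 || K > n) stop("K must lie in [1, n]")
  hc <- if (method == "average")
    stats::hclust(stats::as.dist(d), method = "average")
  else
    stats::hclust(stats::as.dist(sqrt(d)), method = "ward.D2")
  cl <- stats::cutree(hc, k = K)
  labels <- stats::setNames(LETTERS[cl], names(cl))
  structure(list(assignment = labels, hclust = hc, K = as.integer(K),
                 method = method, level = attr(d, "level")),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters (%s linkage)\n",
              length(x$assignment), x$K, x$method))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Export a dendrogram as newick
#'
#' @param clusters a [hierarchical_clusters()] result.
#' @param path output newick path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}
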