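#' Generalized branch length distance between two lineage trees
#'
#' A dissimilarity in `[0, 2]` combining node-set overlap with normalized
#' branch-length differences. After scaling each tree's branch lengths to
#' sum to 1:
#'
#' * `P = 1 - |L_a ∩ L_b| / |L_a ∪ L_b|` over the sampled-node label sets
#'   (germline roots are matched to each other and excluded from the
#'   sets; inferred nodes never enter label matching but do contribute to
#'   path weights);
#' * `W` = mean over shared labels `v` of `|d_a(v) - d_b(v)|`, where
#'   `d(v)` is the normalized path weight from the germline to `v`; over
#'   an empty shared set `W = 0` (the overlap term already saturates).
#'
#' `gbld` is symmetric, zero on identical trees, and invariant under
#' uniform branch-length scaling and consistent relabeling.
#'
#' @param tree_a,tree_b germline-rooted `lineage_tree` objects.
#' @param allow_mixed compare trees processed with different
#'   internal-node-removal modes (default `FALSE`: mixing modes changes
#'   the apparent evolutionary trajectory, so it is refused).
#' @return numeric distance in `[0, 2]`.
#' @export
gbld <- function(tree_a, tree_b, allow_mixed = FALSE) {
  ma <- tree_a$info$removal_mode; mb <- tree_b$info$removal_mode
  if (!allow_mixed && !is.null(ma) && !is.null(mb) && !identical(ma, mb))
    stop("trees were processed with different internal-node-removal modes",
         " ('", ma, "' vs '", mb, "'); set allow_mixed = TRUE to override")
  da <- gbld_depths(tree_a)
  db <- gbld_depths(tree_b)
  la <- names(da); lb <- names(db)
  shared <- intersect(la, lb)
  P <- 1 - length(shared) / length(union(la, lb))
  W <- if (length(shared)) mean(abs(da[shared] - db[shared])) else 0
  P + W
}

# normalized germline->node path weights over sampled labels (no germline)
gbld_depths <- function(tree) {
  if (tree$nodes$kind[match(tree$root_id, tree$nodes$node_id)] != "germline")
    stop("gbld requires germline-rooted trees")
  tot <- sum(tree$edges$weight)
  w <- if (tot > 0) tree$edges$weight / tot else tree$edges$weight
  t2 <- tree; t2$edges$weight <- w
  d <- node_depths(t2, weighted = TRUE)
  samp <- tree$nodes$node_id[tree$nodes$kind == "sampled"]
  d[samp]
}

#' Construction-method robustness of a clonotype's lineage tree
#'
#' Builds the lineage tree with each requested method (after a common
#' internal-node-removal mode, so the trees are comparable), computes all
#' pairwise GBLD values, and summarises robustness as the mean
#' off-diagonal GBLD (0 = perfectly stable topology across methods).
#'
#' @param clonotype a `clonotype`.
#' @param methods character vector of at least 2 construction methods
#'   (see [build_lineage()]).
#' @param metric distance metric for the distance-based methods.
#' @param removal_mode internal-node-removal mode applied to every tree
#'   (default `"link_to_parent"`, which leaves no inferred nodes).
#' @param ... passed to [build_lineage()].
#' @return list with `gbld_matrix` (method x method), `robustness` (mean
#'   off-diagonal GBLD) and `trees`.
#' @export
robustness_report <- function(clonotype, methods = c("default", "mst", "nj"),
                              metric = "hamming",
                              removal_mode = "link_to_parent", ...) {
  if (length(methods) < 2) stop("need at least 2 construction methods")
  trees <- lapply(methods, function(m) {
    tr <- build_lineage(clonotype, method = m, metric = metric, ...)
    remove_internal_nodes(tr, removal_mode)
  })
  names(trees) <- make.unique(methods)
  k <- length(trees)
  G <- matrix(0, k, k, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    G[i, j] <- G[j, i] <- gbld(trees[[i]], trees[[j]])
  }
  list(gbld_matrix = G,
       robustness = mean(G[upper.tri(G)]),
       trees = trees)
}

#' Cluster and embed trees by their topology metrics
#'
#' Z-scores the metric columns (constant or all-`NA` columns dropped),
#' runs average-linkage hierarchical clustering on Euclidean distances,
#' cuts at `k` clusters, and returns 2-D principal-component coordinates.
#' Both steps are deterministic given the metric matrix.
#'
#' @param metrics data frame from [metrics_matrix()] (first column
#'   `tree_id`).
#' @param k number of clusters (must not exceed the number of trees).
#' @return list with `clusters` (data frame `tree_id`, `cluster`),
#'   `embedding` (data frame `tree_id`, `PC1`, `PC2`), `hclust` and the
#'   retained `columns`.
#' @export
compare_across <- function(metrics, k = 2) {
  ids <- metrics$tree_id
  if (k > length(ids)) stop("k exceeds the number of trees")
  X <- as.matrix(metrics[, setdiff(names(metrics), "tree_id"), drop = FALSE])
  keep <- apply(X, 2, function(v) {
    v <- v[is.finite(v)]
    length(v) == nrow(X) && stats::sd(v) > 0
  })
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("no informative (non-constant) metric columns")
  Z <- scale(X)
  hc <- stats::hclust(stats::dist(Z, method = "euclidean"),
                      method = "average")
  cl <- stats::cutree(hc, k = k)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  emb <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(emb) == 1) emb <- cbind(emb, PC2 = 0)
  colnames(emb) <- c("PC1", "PC2")
  list(clusters = data.frame(tree_id = ids, cluster = unname(cl),
                             stringsAsFactors = FALSE),
       embedding = data.frame(tree_id = ids, PC1 = emb[, 1], PC2 = emb[, 2],
                              stringsAsFactors = FALSE),
       hclust = hc,
       columns = colnames(X))
}

#' Edge agreement between two trees on the same sequences
#'
#' For two trees over identical sampled label sets, reports the shared
#' directed parent-child pairs, the Jaccard index of the directed edge
#' sets, and the per-node parent agreement: the fraction of non-root
#' sampled nodes that have the same parent in both trees. Inferred nodes
#' must have been removed first (their labels are tree-specific).
#'
#' @param tree_a,tree_b `lineage_tree` objects with identical sampled
#'   label sets.
#' @return list with `shared_edges` (data frame), `edge_jaccard`,
#'   `parent_agreement` and `n_compared`.
#' @export
compare_identical_sequences <- function(tree_a, tree_b) {
  sa <- sort(tree_a$nodes$node_id[tree_a$nodes$kind == "sampled"])
  sb <- sort(tree_b$nodes$node_id[tree_b$nodes$kind == "sampled"])
  if (!identical(sa, sb))
    stop("sampled label sets differ; use gbld() for such trees")
  ea <- paste(tree_a$edges$parent, tree_a$edges$child, sep = "->")
  eb <- paste(tree_b$edges$parent, tree_b$edges$child, sep = "->")
  shared <- intersect(ea, eb)
  pa <- lt_parent_map(tree_a)
  pb <- lt_parent_map(tree_b)
  comparable <- intersect(names(pa), names(pb))
  agree <- if (length(comparable))
    mean(pa[comparable] == pb[comparable]) else NA_real_
  list(shared_edges = do.call(rbind, lapply(strsplit(shared, "->", fixed = TRUE),
         function(x) data.frame(parent = x[1], child = x[2],
                                stringsAsFactors = FALSE))),
       edge_jaccard = length(shared) / length(union(ea, eb)),
       parent_agreement = agree,
       n_compared = length(comparable))
}
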