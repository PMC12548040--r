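#' Topology descriptors of a lineage tree
#'
#' Computes general graph statistics and imbalance metrics from the
#' germline: node/leaf/internal counts, maximum and mean depth in both
#' edge counts and cumulative edge weight, out-degrees, and the Sackin
#' index (sum of leaf depths in edge counts; high values indicate
#' imbalance and suggest selective pressure). Spectral summaries from
#' [spectral_density()] are appended when the tree has at least two nodes.
#'
#' @param tree a `lineage_tree`.
#' @param spectral include Laplacian spectral summaries (default `TRUE`).
#' @return a one-row data frame of metrics.
#' @export
compute_tree_metrics <- function(tree, spectral = TRUE) {
  n <- nrow(tree$nodes)
  outdeg <- table(factor(tree$edges$parent, levels = tree$nodes$node_id))
  leaves <- setdiff(names(outdeg)[outdeg == 0], tree$root_id)
  de <- node_depths(tree, weighted = FALSE)
  dw <- node_depths(tree, weighted = TRUE)
  res <- data.frame(
    n_nodes = n,
    n_leaves = length(leaves),
    n_internal = n - length(leaves) - 1L,
    max_depth_edges = max(de),
    mean_depth_edges = mean(de),
    max_depth_weighted = max(dw),
    mean_depth_weighted = mean(dw),
    root_outdegree = as.integer(outdeg[[tree$root_id]]),
    mean_outdegree = mean(outdeg[outdeg > 0]),
    sackin = sum(de[leaves]),
    stringsAsFactors = FALSE)
  # size-normalized shape summaries, so trees of different sizes compare
  # on branching pattern rather than node count
  res$sackin_norm <- if (length(leaves)) res$sackin / length(leaves)
                     else NA_real_
  res$depth_ratio <- if (res$max_depth_edges > 0)
    res$mean_depth_edges / res$max_depth_edges else NA_real_
  if (spectral) {
    sp <- if (n >= 2) spectral_density(tree) else NULL
    res$lambda_star <- if (is.null(sp)) NA_real_ else sp$principal_eigenvalue
    res$spectral_asymmetry <- if (is.null(sp)) NA_real_ else sp$asymmetry
    res$spectral_peakedness <- if (is.null(sp)) NA_real_ else sp$peakedness
  }
  res
}

#' Laplacian spectral density of a lineage tree
#'
#' Builds the modified graph Laplacian `M = Diag(rowSums(P)) - P`, where
#' `P` holds the patristic (path) distances between *all* pairs of nodes
#' (root and inferred nodes included), and eigendecomposes it. The density
#' is a Gaussian kernel density estimate over the natural-log-transformed
#' positive eigenvalues with Silverman's rule-of-thumb bandwidth.
#' Summaries: the principal eigenvalue (largest raw eigenvalue, tracking
#' lineage richness), the asymmetry (sample skewness of the
#' ln-eigenvalues, deep vs shallow branching) and the peakedness (sample
#' excess kurtosis of the ln-eigenvalues, imbalance). Skewness and
#' kurtosis are computed on the ln-eigenvalue sample, not the KDE grid, so
#' they do not depend on grid resolution.
#'
#' @param tree a `lineage_tree` with at least 2 nodes. Zero-weight edges
#'   are nudged to `1e-9` so patristic distances stay positive.
#' @return object of class `spectral_density`: list with `eigenvalues`
#'   (descending), `principal_eigenvalue`, `asymmetry`, `peakedness`,
#'   `density_grid` (data frame `x`, `fx`; `NULL` when fewer than two
#'   positive eigenvalues exist) and `bandwidth_rule`.
#' @export
spectral_density <- function(tree) {
  if (nrow(tree$nodes) < 2)
    stop("spectral density undefined for a single-node tree")
  w <- pmax(tree$edges$weight, 1e-9)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edges$parent, to = tree$edges$child, weight = w),
    directed = FALSE,
    vertices = data.frame(name = tree$nodes$node_id))
  P <- igraph::distances(g, weights = igraph::E(g)$weight)
  M <- diag(rowSums(P)) - P
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  pos <- ev[ev > 1e-8]
  lpos <- log(pos)
  dens <- NULL
  if (length(lpos) >= 2 && stats::sd(lpos) > 0) {
    d <- stats::density(lpos, bw = "nrd0")
    dens <- data.frame(x = d$x, fx = d$y)
  }
  structure(list(
    eigenvalues = ev,
    principal_eigenvalue = ev[1],
    asymmetry = sample_skewness(lpos),
    peakedness = sample_excess_kurtosis(lpos),
    density_grid = dens,
    bandwidth_rule = "silverman"), class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf(paste0("<spectral_density> %d eigenvalues, lambda* = %.4g, ",
                     "asymmetry = %.4g, peakedness = %.4g\n"),
              length(x$eigenvalues), x$principal_eigenvalue,
              x$asymmetry, x$peakedness))
  invisible(x)
}

sample_skewness <- function(x) {
  if (length(x) < 2) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  if (length(x) < 2) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Metric matrix over a forest of lineage trees
#'
#' One row per tree in a fixed column order, suitable for CSV export and
#' downstream clustering ([compare_across()]). Metrics that are undefined
#' for a tree (e.g. spectral summaries of a germline-only tree) are `NA`.
#'
#' @param forest named list of `lineage_tree` objects.
#' @param spectral include spectral summaries (default `TRUE`).
#' @return data frame with a `tree_id` column followed by the metric
#'   columns.
#' @export
metrics_matrix <- function(forest, spectral = TRUE) {
  if (!length(forest)) stop("empty forest")
  if (is.null(names(forest)))
    names(forest) <- paste0("tree_", seq_along(forest))
  rows <- lapply(names(forest), function(id) {
    cbind(data.frame(tree_id = id, stringsAsFactors = FALSE),
          compute_tree_metrics(forest[[id]], spectral = spectral))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
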