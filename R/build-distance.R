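# shared scaffolding for distance-based builders --------------------------

# node metadata for a label set, pulling sequences / cell counts from the
# clonotype when one is supplied; labels[1] is always the germline
build_node_info <- function(labels, clonotype = NULL) {
  kinds <- stats::setNames(c("germline", rep("sampled", length(labels) - 1)),
                           labels)
  seqs <- stats::setNames(rep(NA_character_, length(labels)), labels)
  counts <- stats::setNames(rep(0, length(labels)), labels)
  if (!is.null(clonotype)) {
    seqs["germline"] <- clonotype$germline_nt
    hit <- intersect(labels, clonotype$variants$variant_id)
    m <- match(hit, clonotype$variants$variant_id)
    seqs[hit] <- clonotype$variants$sequence_nt[m]
    counts[hit] <- clonotype$variants$cell_count[m]
  }
  list(kinds = kinds, seqs = seqs, counts = counts)
}

#' Build a lineage tree by iterative minimum-distance attachment
#'
#' The default construction: start from the germline node and repeatedly
#' find the globally smallest distance `D[u, v]` between any node `u`
#' already in the tree and any node `v` outside it, then attach `v` as a
#' child of `u` with edge weight `D[u, v]`.
#'
#' When several pairs tie at the minimum, the `tie_break` criterion first
#' restricts the candidate parents `u`: `"breadth"` keeps parents with the
#' most current descendants, `"depth"` the fewest; `"mutational_load_min"` /
#' `"mutational_load_max"` the smallest / largest summed path weight from
#' the germline; `"expansion_max"` / `"expansion_min"` the largest /
#' smallest cell count. Any remaining tie is broken lexicographically by
#' child then parent id, so runs are reproducible; `tie_break = "random"`
#' instead draws uniformly among the tied pairs under `seed`.
#'
#' @param distances symmetric distance matrix whose first label is the
#'   germline (see [compute_distances()]).
#' @param clonotype optional `clonotype` supplying sequences and cell
#'   counts for the nodes.
#' @param tie_break one of `"none"`, `"breadth"`, `"depth"`,
#'   `"mutational_load_min"`, `"mutational_load_max"`, `"expansion_max"`,
#'   `"expansion_min"`, `"random"`.
#' @param seed integer seed, required when `tie_break = "random"`.
#' @return a `lineage_tree` on exactly the input nodes (no inferred nodes).
#' @export
build_default <- function(distances, clonotype = NULL,
                          tie_break = c("none", "breadth", "depth",
                                        "mutational_load_min",
                                        "mutational_load_max",
                                        "expansion_max", "expansion_min",
                                        "random"),
                          seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (tie_break == "random") {
    if (is.null(seed)) stop("tie_break = 'random' requires a seed")
    return(withr::with_seed(seed,
      build_default_impl(distances, clonotype, tie_break)))
  }
  build_default_impl(distances, clonotype, tie_break)
}

build_default_impl <- function(distances, clonotype, tie_break) {
  labels <- rownames(distances)
  root <- labels[1]
  ni <- build_node_info(labels, clonotype)
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  weight <- stats::setNames(rep(NA_real_, length(labels)), labels)
  depthw <- stats::setNames(rep(0, length(labels)), labels)
  ndesc <- stats::setNames(rep(0L, length(labels)), labels)
  in_tree <- root
  outside <- setdiff(labels, root)
  while (length(outside)) {
    sub <- distances[in_tree, outside, drop = FALSE]
    m <- min(sub)
    hit <- which(sub <= m + 1e-12, arr.ind = TRUE)
    us <- in_tree[hit[, 1]]; vs <- outside[hit[, 2]]
    if (length(us) > 1 && tie_break != "none" && tie_break != "random") {
      crit <- switch(tie_break,
        breadth = ndesc[us],
        depth = -ndesc[us],
        mutational_load_min = -depthw[us],
        mutational_load_max = depthw[us],
        expansion_max = ni$counts[us],
        expansion_min = -ni$counts[us])
      keep <- which(crit >= max(crit) - 1e-12)
      us <- us[keep]; vs <- vs[keep]
    }
    if (length(us) > 1) {
      if (tie_break == "random") {
        k <- sample.int(length(us), 1)
      } else {
        k <- order(vs, us)[1]
      }
      us <- us[k]; vs <- vs[k]
    }
    u <- us[1]; v <- vs[1]
    parent[v] <- u
    weight[v] <- distances[u, v]
    depthw[v] <- depthw[u] + distances[u, v]
    a <- u
    while (!is.na(a)) { ndesc[a] <- ndesc[a] + 1L; a <- parent[a] }
    in_tree <- c(in_tree, v)
    outside <- setdiff(outside, v)
  }
  apply_clonotype_counts(
    lt_from_parents(labels, parent, weight, root, ni$kinds, ni$seqs,
                    ni$counts, info = list(method = "default",
                                           tie_break = tie_break)),
    clonotype)
}

#' Build a germline-rooted minimum spanning tree
#'
#' Computes a minimum-total-weight spanning tree of the complete distance
#' graph over germline + variants and orients its edges away from the
#' germline.
#'
#' @inheritParams build_default
#' @return a `lineage_tree` with total edge weight equal to the global
#'   minimum over all spanning trees.
#' @export
build_mst <- function(distances, clonotype = NULL) {
  labels <- rownames(distances)
  root <- labels[1]
  ni <- build_node_info(labels, clonotype)
  if (length(labels) == 1) {
    return(lt_from_parents(labels, stats::setNames(character(0), character(0)),
                           numeric(0), root, ni$kinds, ni$seqs, ni$counts,
                           info = list(method = "mst")))
  }
  g <- igraph::graph_from_adjacency_matrix(distances, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g, weights = igraph::E(g)$weight)
  ed <- igraph::as_data_frame(t, what = "edges")
  # orient away from the germline
  adj <- split(c(ed$to, ed$from), c(ed$from, ed$to))
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  weight <- stats::setNames(rep(NA_real_, length(labels)), labels)
  frontier <- root; seen <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in setdiff(adj[[u]], seen)) {
        parent[v] <- u
        weight[v] <- distances[u, v]
        nxt <- c(nxt, v); seen <- c(seen, v)
      }
    }
    frontier <- nxt
  }
  apply_clonotype_counts(
    lt_from_parents(labels, parent, weight, root, ni$kinds, ni$seqs,
                    ni$counts, info = list(method = "mst")),
    clonotype)
}
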