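#' Build a lineage tree by neighbor joining
#'
#' Standard agglomerative neighbor joining over germline + variants,
#' producing inferred internal nodes (`inferred_1`, `inferred_2`, ...),
#' then re-rooted at the germline leaf: the germline becomes the root and
#' its pendant edge the root edge. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sibling branch, so edge weights
#' stay valid for downstream metrics. On additive distance matrices NJ
#' recovers the generating topology and branch lengths exactly.
#'
#' With fewer than four taxa (germline + at most two variants) the
#' agglomeration is degenerate and the variants are attached directly to
#' the germline (star fallback).
#'
#' @inheritParams build_default
#' @return a `lineage_tree`; internal nodes have kind `"inferred"`.
#' @export
build_nj <- function(distances, clonotype = NULL) {
  labels <- rownames(distances)
  root <- labels[1]
  n <- length(labels)
  ni <- build_node_info(labels, clonotype)
  if (n <= 3) {  # degenerate: star on the germline
    parent <- stats::setNames(rep(root, n - 1), labels[-1])
    weight <- stats::setNames(distances[root, labels[-1]], labels[-1])
    return(apply_clonotype_counts(
      lt_from_parents(labels, parent, weight, root, ni$kinds, ni$seqs,
                      ni$counts, info = list(method = "nj",
                                             fallback = "star")),
      clonotype))
  }
  D <- distances
  active <- labels
  edges <- list()
  k <- 0L
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest label pair
    ord <- order(active[hits[, 1]], active[hits[, 2]])
    i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
    a <- active[i]; b <- active[j]
    d <- Dm[i, j]
    la <- d / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lb <- d - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    k <- k + 1L
    u <- paste0("inferred_", k)
    edges[[length(edges) + 1L]] <- list(u, a, la)
    edges[[length(edges) + 1L]] <- list(u, b, lb)
    rest <- setdiff(active, c(a, b))
    du <- (D[a, rest] + D[b, rest] - d) / 2
    du[du < 0] <- 0
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, rest] <- du; D[rest, u] <- du
    active <- c(rest, u)
  }
  # final join of the last three nodes onto one internal node
  a <- active[1]; b <- active[2]; cc <- active[3]
  k <- k + 1L
  u <- paste0("inferred_", k)
  la <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
  lb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
  lc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
  for (x in list(list(a, la), list(b, lb), list(cc, lc))) {
    edges[[length(edges) + 1L]] <- list(u, x[[1]], max(0, x[[2]]))
  }
  apply_clonotype_counts(
    nj_edges_to_tree(edges, labels, root, ni, info = list(method = "nj")),
    clonotype)
}

# orient an undirected edge list away from the germline leaf
nj_edges_to_tree <- function(edges, sampled_labels, root, ni, info) {
  ea <- vapply(edges, function(e) e[[1]], character(1))
  eb <- vapply(edges, function(e) e[[2]], character(1))
  ew <- vapply(edges, function(e) e[[3]], numeric(1))
  ids <- unique(c(sampled_labels, ea, eb))
  adj <- split(data.frame(to = c(eb, ea), w = c(ew, ew),
                          stringsAsFactors = FALSE),
               c(ea, eb))
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  weight <- stats::setNames(rep(NA_real_, length(ids)), ids)
  frontier <- root; seen <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb$to[r]
        if (!v %in% seen) {
          parent[v] <- u; weight[v] <- nb$w[r]
          nxt <- c(nxt, v); seen <- c(seen, v)
        }
      }
    }
    frontier <- nxt
  }
  inferred <- setdiff(ids, sampled_labels)
  kinds <- c(ni$kinds, stats::setNames(rep("inferred", length(inferred)),
                                       inferred))
  seqs <- c(ni$seqs, stats::setNames(rep(NA_character_, length(inferred)),
                                     inferred))
  counts <- c(ni$counts, stats::setNames(rep(0, length(inferred)), inferred))
  lt_from_parents(ids, parent, weight, root, kinds, seqs, counts, info = info)
}
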