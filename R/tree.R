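#' Construct a germline-rooted lineage tree
#'
#' A `lineage_tree` is a rooted, edge-weighted, multifurcation-capable
#' directed graph whose root is the unmutated germline of a clonotype.
#' Sampled nodes carry the observed sequences; algorithms such as neighbor
#' joining may additionally introduce `inferred` ancestors.
#'
#' @param nodes data frame with columns `node_id` (character, unique),
#'   `kind` (one of `"germline"`, `"sampled"`, `"inferred"`),
#'   `sequence_nt`, `sequence_aa` (character, `NA` allowed for inferred
#'   nodes) and `cell_count` (non-negative numeric; 0 for germline and
#'   inferred nodes).
#' @param edges data frame with columns `parent`, `child` (node ids) and
#'   `weight` (non-negative numeric). Edges point away from the root.
#' @param root_id id of the germline node.
#' @param fractions named list (by node id) of named lists (by label
#'   column) of named numeric fraction vectors, each summing to 1.
#' @param annotations named list of per-node free-form annotation lists.
#' @param info free-form list of tree-level metadata (construction method,
#'   internal-node-removal mode, ...).
#' @param validate run structural validation (default `TRUE`).
#' @return an object of class `lineage_tree`.
#' @export
lineage_tree <- function(nodes, edges, root_id, fractions = list(),
                         annotations = list(), info = list(),
                         validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  for (col in c("sequence_nt", "sequence_aa")) {
    if (is.null(nodes[[col]])) nodes[[col]] <- NA_character_
  }
  if (is.null(nodes$cell_count)) nodes$cell_count <- 0
  nodes <- nodes[, c("node_id", "kind", "sequence_nt", "sequence_aa",
                     "cell_count")]
  if (nrow(edges) == 0) {
    edges <- data.frame(parent = character(), child = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = as.character(edges$parent),
                        child = as.character(edges$child),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
  }
  tree <- structure(
    list(nodes = nodes, edges = edges, root_id = root_id,
         fractions = fractions, annotations = annotations, info = info),
    class = "lineage_tree")
  if (validate) validate_lineage_tree(tree)
  tree
}

#' Validate the structural invariants of a lineage tree
#'
#' Checks rootedness (every non-root node has exactly one parent), acyclicity
#' and connectivity, non-negative edge weights, and that the root is the
#' germline.
#'
#' @param tree a `lineage_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_lineage_tree <- function(tree) {
  nodes <- tree$nodes; edges <- tree$edges
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids in lineage tree")
  if (!tree$root_id %in% nodes$node_id)
    stop("root_id not among nodes")
  if (nodes$kind[nodes$node_id == tree$root_id] != "germline")
    stop("root node must have kind 'germline'")
  if (!all(nodes$kind %in% c("germline", "sampled", "inferred")))
    stop("invalid node kind")
  if (nrow(edges) != nrow(nodes) - 1L)
    stop("a rooted tree on n nodes must have n-1 edges")
  if (nrow(edges) > 0) {
    if (!all(edges$parent %in% nodes$node_id) ||
        !all(edges$child %in% nodes$node_id))
      stop("edge endpoint not among nodes")
    if (anyDuplicated(edges$child))
      stop("a node has more than one parent")
    if (tree$root_id %in% edges$child)
      stop("root must not have a parent")
    if (any(edges$weight < 0))
      stop("negative edge weight")
  }
  # connectivity: walk from root
  kids <- split(edges$child, edges$parent)
  seen <- character(0); frontier <- tree$root_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (length(seen) != nrow(nodes))
    stop("tree is not connected from the root")
  inf <- nodes$kind == "inferred"
  if (any(nodes$cell_count[inf] != 0))
    stop("inferred nodes must have cell_count 0")
  invisible(tree)
}

#' @export
print.lineage_tree <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf("<lineage_tree> %d nodes (%s), root '%s'\n",
              nrow(x$nodes),
              paste(sprintf("%s %s", kinds, names(kinds)), collapse = ", "),
              x$root_id))
  if (length(x$info)) {
    cat("  info:", paste(names(x$info), unlist(lapply(x$info, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

# child -> parent lookup (named character vector)
lt_parent_map <- function(tree) {
  stats::setNames(tree$edges$parent, tree$edges$child)
}

# parent -> children (list)
lt_children <- function(tree) {
  split(tree$edges$child, factor(tree$edges$parent,
                                 levels = tree$nodes$node_id))
}

# nodes in root-first (pre)order
lt_preorder <- function(tree) {
  kids <- split(tree$edges$child, tree$edges$parent)
  out <- character(nrow(tree$nodes)); out[1] <- tree$root_id
  i <- 1L; n <- 1L
  while (i <= n) {
    ch <- kids[[out[i]]]
    if (!is.null(ch)) { out[(n + 1L):(n + length(ch))] <- ch; n <- n + length(ch) }
    i <- i + 1L
  }
  out
}

#' Node depths from the germline
#'
#' @param tree a `lineage_tree`.
#' @param weighted if `TRUE` depth is the summed edge weight on the path
#'   from the germline (patristic distance to the root); otherwise the edge
#'   count.
#' @return named numeric vector over all nodes (root depth 0).
#' @export
node_depths <- function(tree, weighted = FALSE) {
  pm <- lt_parent_map(tree)
  w <- stats::setNames(tree$edges$weight, tree$edges$child)
  depth <- stats::setNames(numeric(nrow(tree$nodes)), tree$nodes$node_id)
  for (id in lt_preorder(tree)) {
    if (id == tree$root_id) next
    depth[id] <- depth[pm[id]] + if (weighted) w[id] else 1
  }
  depth
}

# number of descendants (excluding self) per node
lt_n_descendants <- function(tree) {
  pm <- lt_parent_map(tree)
  nd <- stats::setNames(integer(nrow(tree$nodes)), tree$nodes$node_id)
  for (id in rev(lt_preorder(tree))) {
    if (id == tree$root_id) next
    p <- pm[[id]]
    nd[p] <- nd[p] + nd[id] + 1L
  }
  nd
}

#' Convert a lineage tree to an igraph object
#'
#' Node kind, sequences, cell counts and edge weights become igraph
#' attributes, so the full tree survives GraphML export.
#'
#' @param tree a `lineage_tree`.
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(tree) {
  nd <- tree$nodes
  nd$name <- nd$node_id
  g <- igraph::graph_from_data_frame(
    d = tree$edges[, c("parent", "child", "weight")],
    directed = TRUE,
    vertices = nd[, c("name", "kind", "sequence_nt", "sequence_aa",
                      "cell_count")])
  igraph::graph_attr(g, "root_id") <- tree$root_id
  g
}

# igraph -> lineage_tree (attributes as written by as_igraph)
igraph_to_lineage_tree <- function(g, info = list()) {
  va <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(node_id = va$name, kind = va$kind,
                      sequence_nt = va$sequence_nt,
                      sequence_aa = va$sequence_aa,
                      cell_count = va$cell_count,
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = ed$from, child = ed$to, weight = ed$weight,
                      stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, igraph::graph_attr(g, "root_id"), info = info)
}

#' Total branch length of a tree
#' @param tree a `lineage_tree`.
#' @return sum of edge weights.
#' @export
total_branch_length <- function(tree) sum(tree$edges$weight)

# build a lineage_tree from a parent vector representation
# ids: all node ids; parent: named vector child->parent; weight: child->weight
lt_from_parents <- function(ids, parent, weight, root_id, kinds, seqs,
                            cell_counts, info = list()) {
  ch <- setdiff(ids, root_id)
  edges <- data.frame(parent = unname(parent[ch]), child = ch,
                      weight = unname(weight[ch]), stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = ids, kind = kinds[ids],
                      sequence_nt = seqs[ids],
                      sequence_aa = NA_character_,
                      cell_count = cell_counts[ids],
                      stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, root_id, info = info)
}
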