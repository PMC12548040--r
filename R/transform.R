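#' Remove inferred internal nodes from a lineage tree
#'
#' Converts bifurcating phylogenies (e.g. neighbor-joining output) into
#' multifurcating lineage networks of sampled sequences. Three modes:
#'
#' * `"zero_length_only"` — an inferred node with a zero-length edge
#'   (within tolerance `1e-9`) to a sampled terminal node is merged with
#'   that terminal: the terminal takes the inferred node's place and
#'   inherits its children. This preserves mutational ordering and may
#'   leave inferred nodes with no zero-length sampled terminal untouched.
#'   When two sampled terminals tie at zero length, the one with the
#'   larger cell count is merged (reported via `message()`).
#' * `"replace_by_closest_descendant"` — every inferred node is replaced
#'   by its nearest sampled descendant (smallest path weight; ties broken
#'   by larger cell count, then lexicographic id), processed bottom-up so
#'   the result contains no inferred nodes. Favors depth.
#' * `"link_to_parent"` — every inferred node is deleted and each sampled
#'   node is re-attached to its closest sampled (or germline) ancestor
#'   with edge weight equal to the connecting path weight, so the path
#'   weight from the germline to every sampled node is preserved. Favors
#'   breadth.
#'
#' The mode applied is stamped into `tree$info$removal_mode`; downstream
#' tree comparisons refuse to mix modes unless explicitly allowed, since
#' node removal changes the apparent evolutionary trajectory.
#'
#' @param tree a `lineage_tree`.
#' @param mode one of `"zero_length_only"`,
#'   `"replace_by_closest_descendant"`, `"link_to_parent"`.
#' @param tolerance branch lengths at or below this count as zero
#'   (default `1e-9`).
#' @return the transformed `lineage_tree`; the sampled-node set is always
#'   preserved exactly.
#' @export
remove_internal_nodes <- function(tree,
                                  mode = c("zero_length_only",
                                           "replace_by_closest_descendant",
                                           "link_to_parent"),
                                  tolerance = 1e-9) {
  mode <- match.arg(mode)
  out <- switch(mode,
    zero_length_only = rin_zero_length(tree, tolerance),
    replace_by_closest_descendant = rin_closest_descendant(tree),
    link_to_parent = rin_link_to_parent(tree))
  out$info$removal_mode <- mode
  validate_lineage_tree(out)
  out
}

# child ids of `id` in `tree`
node_children <- function(tree, id) tree$edges$child[tree$edges$parent == id]

is_inferred <- function(tree, id) {
  tree$nodes$kind[match(id, tree$nodes$node_id)] == "inferred"
}

# replace node `old` by node `new`: `new` inherits old's parent edge and
# children edges; `new`'s former position is vacated (its incoming edge
# dropped). Caller guarantees `new` is a leaf child of `old`.
lt_splice <- function(tree, old, new) {
  drop <- which(tree$edges$child == new & tree$edges$parent == old)
  tree$edges <- tree$edges[-drop, , drop = FALSE]
  tree$edges$parent[tree$edges$parent == old] <- new
  tree$edges$child[tree$edges$child == old] <- new
  tree$nodes <- tree$nodes[tree$nodes$node_id != old, , drop = FALSE]
  tree
}

rin_zero_length <- function(tree, tolerance) {
  repeat {
    cand <- NULL
    for (id in tree$nodes$node_id[tree$nodes$kind == "inferred"]) {
      ch <- node_children(tree, id)
      w <- tree$edges$weight[match(ch, tree$edges$child)]
      term <- vapply(ch, function(c) length(node_children(tree, c)) == 0,
                     logical(1))
      samp <- tree$nodes$kind[match(ch, tree$nodes$node_id)] == "sampled"
      hit <- ch[term & samp & w <= tolerance]
      if (length(hit)) {
        if (length(hit) > 1) {
          cc <- tree$nodes$cell_count[match(hit, tree$nodes$node_id)]
          hit <- hit[order(-cc, hit)]
          message("inferred node '", id, "' has ", length(hit),
                  " zero-length sampled terminals; merging '", hit[1], "'")
        }
        cand <- c(id, hit[1])
        break
      }
    }
    if (is.null(cand)) break
    tree <- lt_splice(tree, cand[1], cand[2])
  }
  tree
}

rin_closest_descendant <- function(tree) {
  depth <- node_depths(tree)
  inferred <- tree$nodes$node_id[tree$nodes$kind == "inferred"]
  for (id in inferred[order(-depth[inferred])]) {  # deepest first
    ch <- node_children(tree, id)
    if (!length(ch)) {  # dangling inferred leaf: drop it
      tree$edges <- tree$edges[tree$edges$child != id, , drop = FALSE]
      tree$nodes <- tree$nodes[tree$nodes$node_id != id, , drop = FALSE]
      next
    }
    # bottom-up processing: all descendants are sampled, so the nearest
    # one by path weight is a direct child
    w <- tree$edges$weight[match(ch, tree$edges$child)]
    cc <- tree$nodes$cell_count[match(ch, tree$nodes$node_id)]
    s <- ch[order(w, -cc, ch)][1]
    tree <- lt_splice(tree, id, s)
  }
  tree
}

rin_link_to_parent <- function(tree) {
  pm <- lt_parent_map(tree)
  wts <- stats::setNames(tree$edges$weight, tree$edges$child)
  keep <- tree$nodes$node_id[tree$nodes$kind != "inferred"]
  parent <- stats::setNames(rep(NA_character_, length(keep)), keep)
  weight <- stats::setNames(rep(NA_real_, length(keep)), keep)
  for (id in setdiff(keep, tree$root_id)) {
    a <- pm[[id]]; w <- wts[[id]]
    while (is_inferred(tree, a)) { w <- w + wts[[a]]; a <- pm[[a]] }
    parent[id] <- a; weight[id] <- w
  }
  nodes <- tree$nodes[tree$nodes$node_id %in% keep, , drop = FALSE]
  edges <- data.frame(parent = unname(parent[setdiff(keep, tree$root_id)]),
                      child = setdiff(keep, tree$root_id),
                      weight = unname(weight[setdiff(keep, tree$root_id)]),
                      stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, tree$root_id, fractions = tree$fractions,
               annotations = tree$annotations, info = tree$info)
}

#' Integrate bulk sequencing reads into a clonotype or lineage tree
#'
#' Bulk records whose sequence matches an existing variant increase that
#' variant's cell count by their `duplicate_count`; new sequences become
#' new variants (clonotype input) or attach as new leaves below the
#' minimum-distance existing node (tree input, mirroring the default
#' construction's attachment step) without altering any existing edge.
#'
#' @param x a `clonotype` or `lineage_tree`.
#' @param bulk_records data frame of records with `source = "bulk"`.
#' @param clonotype_match optional `clonotype` used to decide which bulk
#'   records belong to the lineage when `x` is a tree; when `NULL`
#'   together with `strategy = "none"` all records are taken.
#' @param strategy `"clone_id"` (match on `clone_id`), `"vjl"` (same
#'   V/J/junction-length and junction identity at least
#'   `junction_threshold` against a member record) or `"none"`.
#' @param junction_threshold identity threshold for `"vjl"` (default 0.85).
#' @param metric distance metric for tree attachment.
#' @return list with the updated object (`clonotype` or `tree`) and a
#'   data frame `unassigned` of non-matching records.
#' @export
integrate_bulk <- function(x, bulk_records, clonotype_match = NULL,
                           strategy = c("clone_id", "vjl", "none"),
                           junction_threshold = 0.85,
                           metric = c("hamming", "levenshtein")) {
  strategy <- match.arg(strategy)
  metric <- match.arg(metric)
  ref <- if (inherits(x, "clonotype")) x else clonotype_match
  matches <- vapply(seq_len(nrow(bulk_records)), function(i) {
    bulk_matches_clonotype(bulk_records[i, ], ref, strategy,
                           junction_threshold)
  }, logical(1))
  unassigned <- bulk_records[!matches, , drop = FALSE]
  hit <- bulk_records[matches, , drop = FALSE]
  if (inherits(x, "clonotype")) {
    for (i in seq_len(nrow(hit))) {
      j <- match(hit$sequence_nt[i], x$variants$sequence_nt)
      if (!is.na(j)) {
        x$variants$cell_count[j] <- x$variants$cell_count[j] +
          hit$duplicate_count[i]
      } else {
        vid <- paste0("variant_", nrow(x$variants) + 1L)
        x$variants <- rbind(x$variants, data.frame(
          variant_id = vid, sequence_nt = hit$sequence_nt[i],
          sequence_aa = translate_nt(hit$sequence_nt[i]),
          cell_count = hit$duplicate_count[i], stringsAsFactors = FALSE))
        x$cell_ids[[vid]] <- character(0)
        x$fractions[[vid]] <- list(source = c(bulk = 1))
      }
    }
    return(list(clonotype = x, unassigned = unassigned))
  }
  # lineage_tree: attach without touching existing edges
  for (i in seq_len(nrow(hit))) {
    s <- hit$sequence_nt[i]
    j <- match(s, x$nodes$sequence_nt)
    if (!is.na(j)) {
      x$nodes$cell_count[j] <- x$nodes$cell_count[j] + hit$duplicate_count[i]
      next
    }
    with_seq <- x$nodes[!is.na(x$nodes$sequence_nt), , drop = FALSE]
    d <- vapply(with_seq$sequence_nt, function(t) {
      if (metric == "hamming" && nchar(t) == nchar(s))
        hamming_distance(t, s)
      else levenshtein_distance(t, s)
    }, numeric(1))
    ord <- order(d, with_seq$node_id)
    u <- with_seq$node_id[ord[1]]
    nid <- hit$sequence_id[i]
    x$nodes <- rbind(x$nodes, data.frame(
      node_id = nid, kind = "sampled", sequence_nt = s,
      sequence_aa = translate_nt(s), cell_count = hit$duplicate_count[i],
      stringsAsFactors = FALSE))
    x$edges <- rbind(x$edges, data.frame(
      parent = u, child = nid, weight = d[ord[1]], stringsAsFactors = FALSE))
    x$annotations[[nid]] <- list(source = "bulk")
  }
  validate_lineage_tree(x)
  list(tree = x, unassigned = unassigned)
}

bulk_matches_clonotype <- function(rec, ref, strategy, t) {
  if (strategy == "none" || is.null(ref)) return(TRUE)
  if (strategy == "clone_id") return(rec$clone_id == ref$clonotype_id)
  mem <- ref$records
  for (i in seq_len(nrow(mem))) {
    if (rec$v_call == mem$v_call[i] && rec$j_call == mem$j_call[i] &&
        nchar(rec$junction_nt) == nchar(mem$junction_nt[i]) &&
        nchar(rec$junction_nt) > 0) {
      a <- strsplit(rec$junction_nt, "")[[1]]
      b <- strsplit(mem$junction_nt[i], "")[[1]]
      if (mean(a == b) >= t) return(TRUE)
    }
  }
  FALSE
}

#' Annotate tree nodes with per-cell label fractions
#'
#' Joins a per-cell metadata table to the tree through the cell ids stored
#' on each sampled node and fills `tree$fractions[[node]][[label_column]]`
#' with the per-label fractions over the node's cells (summing to 1).
#' Nodes without cells (germline, inferred) get empty fractions.
#'
#' @param tree a `lineage_tree` built from a clonotype (nodes carry
#'   `cell_ids` annotations).
#' @param cell_table data frame with a `cell_id` column and the label
#'   column.
#' @param label_column name of the label column (e.g. isotype).
#' @return the annotated `lineage_tree`.
#' @export
annotate_nodes <- function(tree, cell_table, label_column) {
  if (!label_column %in% names(cell_table))
    stop("label column '", label_column, "' not found")
  for (id in tree$nodes$node_id) {
    cells <- tree$annotations[[id]]$cell_ids
    if (is.null(cells) || !length(cells)) next
    lab <- cell_table[[label_column]][match(cells, cell_table$cell_id)]
    lab <- lab[!is.na(lab) & lab != ""]
    if (!length(lab)) next
    tb <- table(lab)
    tree$fractions[[id]][[label_column]] <-
      stats::setNames(as.numeric(tb) / length(lab), names(tb))
  }
  tree
}
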