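#' Read an AIRR Rearrangement TSV into sequence records
#'
#' Parses the community-standard tab-separated Rearrangement format. Rows
#' missing a resolvable `sequence_id` or `sequence` are skipped; the skip
#' count is reported via `message()`. Columns beyond the recognised set are
#' ignored (carry them through `column_map` if they hold data under a
#' nonstandard header).
#'
#' @param path path to a TSV file with a header row.
#' @param column_map optional named character vector mapping canonical
#'   record fields (names) to the file's column headers (values), e.g.
#'   `c(sequence_nt = "nt_seq")`. Canonical fields: `sequence_id`,
#'   `cell_id`, `sequence_nt`, `sequence_aa`, `v_call`, `j_call`,
#'   `junction_nt`, `c_call`, `duplicate_count`, `clone_id`,
#'   `germline_alignment_nt`.
#' @return data frame of sequence records, one per retained row, with the
#'   canonical columns above plus `source` (`"single_cell"` when `cell_id`
#'   is non-empty, `"bulk"` otherwise).
#' @export
read_airr <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("AIRR file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  # default AIRR-standard headers for each canonical field
  defaults <- c(sequence_id = "sequence_id", cell_id = "cell_id",
                sequence_nt = "sequence", sequence_aa = "sequence_aa",
                v_call = "v_call", j_call = "j_call",
                junction_nt = "junction", c_call = "c_call",
                duplicate_count = "duplicate_count", clone_id = "clone_id",
                germline_alignment_nt = "germline_alignment")
  if (!is.null(column_map)) defaults[names(column_map)] <- column_map
  get_col <- function(field) {
    h <- defaults[[field]]
    if (h %in% names(raw)) raw[[h]] else rep("", nrow(raw))
  }
  rec <- data.frame(
    sequence_id = get_col("sequence_id"),
    cell_id = get_col("cell_id"),
    sequence_nt = toupper(get_col("sequence_nt")),
    sequence_aa = get_col("sequence_aa"),
    v_call = get_col("v_call"),
    j_call = get_col("j_call"),
    junction_nt = toupper(get_col("junction_nt")),
    c_call = get_col("c_call"),
    duplicate_count = suppressWarnings(as.integer(get_col("duplicate_count"))),
    clone_id = get_col("clone_id"),
    germline_alignment_nt = toupper(get_col("germline_alignment_nt")),
    stringsAsFactors = FALSE)
  if (all(rec$sequence_id == "") && all(rec$sequence_nt == "") && nrow(raw) > 0)
    stop("no resolvable 'sequence_id'/'sequence' columns in ", path)
  rec$duplicate_count[is.na(rec$duplicate_count)] <- 1L
  keep <- rec$sequence_id != "" & rec$sequence_nt != ""
  if (any(!keep))
    message(sum(!keep), " row(s) skipped (missing sequence_id or sequence)")
  rec <- rec[keep, , drop = FALSE]
  rec$source <- ifelse(rec$cell_id != "", "single_cell", "bulk")
  rownames(rec) <- NULL
  rec
}

#' Write sequence records to an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: canonical record fields are written under the
#' standard AIRR headers.
#'
#' @param records data frame as returned by [read_airr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  out <- data.frame(
    sequence_id = records$sequence_id,
    cell_id = records$cell_id,
    sequence = records$sequence_nt,
    sequence_aa = records$sequence_aa,
    v_call = records$v_call,
    j_call = records$j_call,
    junction = records$junction_nt,
    c_call = records$c_call,
    duplicate_count = records$duplicate_count,
    clone_id = records$clone_id,
    germline_alignment = records$germline_alignment_nt,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read/write FASTA sequence sets
#'
#' Thin wrappers around seqinr keeping sequences as plain named character
#' strings (upper case).
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  sq <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(sq, `[[`, character(1), 1L)), names(sq))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

# --- Newick -----------------------------------------------------------------

#' Import a phylogeny in Newick format as a germline-rooted lineage tree
#'
#' Accepts multifurcations, named internal nodes and branch lengths. The
#' node named `germline_label` becomes the root; if it is a leaf the tree is
#' re-rooted on it and its pendant edge becomes the root edge. Unnamed
#' internal nodes are labelled `inferred_1`, `inferred_2`, ... and get kind
#' `"inferred"`; named nodes are treated as sampled sequences.
#'
#' @param path path to a Newick file (or a Newick string containing `";"`).
#' @param germline_label name of the germline node in the file.
#' @return a `lineage_tree`.
#' @export
read_newick <- function(path, germline_label) {
  phy <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
         else ape::read.tree(path)
  if (is.null(phy)) stop("malformed Newick input")
  phylo_to_lineage(phy, germline_label)
}

# convert an ape phylo (rooted or not) into a germline-rooted lineage_tree.
# Branch lengths default to 0 when the Newick carries none.
phylo_to_lineage <- function(phy, germline_label, sequences = NULL,
                             info = list()) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- character(ntip + nnode)
  labels[seq_len(ntip)] <- phy$tip.label
  inner <- if (!is.null(phy$node.label)) phy$node.label else rep("", nnode)
  k <- 0L
  for (i in seq_len(nnode)) {
    if (is.na(inner[i]) || inner[i] == "") {
      k <- k + 1L
      inner[i] <- paste0("inferred_", k)
    }
  }
  labels[ntip + seq_len(nnode)] <- inner
  if (anyDuplicated(labels)) stop("duplicate node labels in Newick input")
  if (!germline_label %in% labels)
    stop("germline label '", germline_label, "' not found in tree")
  len <- if (!is.null(phy$edge.length)) phy$edge.length
         else rep(0, nrow(phy$edge))
  # undirected adjacency, then orient away from the germline
  adj <- vector("list", length(labels))
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, len[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, len[e]))
  }
  root <- match(germline_label, labels)
  parent <- rep(NA_integer_, length(labels))
  weight <- rep(NA_real_, length(labels))
  frontier <- root; seen <- rep(FALSE, length(labels)); seen[root] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (!seen[v]) {
          seen[v] <- TRUE; parent[v] <- u; weight[v] <- nb[r, 2]
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  kind <- ifelse(grepl("^inferred_", labels), "inferred", "sampled")
  kind[root] <- "germline"
  seqs <- rep(NA_character_, length(labels))
  if (!is.null(sequences)) {
    hit <- labels %in% names(sequences)
    seqs[hit] <- unname(sequences[labels[hit]])
  }
  ids <- labels
  names(parent) <- ids; names(weight) <- ids
  lt_from_parents(
    ids = ids,
    parent = stats::setNames(ids[parent], ids),
    weight = weight,
    root_id = germline_label,
    kinds = stats::setNames(kind, ids),
    seqs = stats::setNames(seqs, ids),
    cell_counts = stats::setNames(rep(0, length(ids)), ids),
    info = info)
}

#' Export a lineage tree as a Newick string or file
#'
#' The germline root is written as the (named) outermost node. Multifurcating
#' nodes are written as-is; branch lengths are the edge weights.
#'
#' @param tree a `lineage_tree`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  kids <- split(tree$edges$child, tree$edges$parent)
  wts <- stats::setNames(tree$edges$weight, tree$edges$child)
  fmt <- function(id) {
    ch <- kids[[id]]
    lab <- id
    if (is.null(ch)) lab
    else paste0("(", paste(vapply(ch, function(c) {
      paste0(fmt(c), ":", format(wts[[c]], digits = 12))
    }, character(1)), collapse = ","), ")", lab)
  }
  nwk <- paste0(fmt(tree$root_id), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

# --- GraphML ----------------------------------------------------------------

#' Write / read a lineage tree in GraphML format
#'
#' All node attributes (kind, sequences, cell count) and edge weights are
#' emitted; `read_graphml` restores the `lineage_tree`.
#'
#' @param tree a `lineage_tree`.
#' @param path file path.
#' @return `write_graphml` returns `path` invisibly; `read_graphml` a
#'   `lineage_tree`.
#' @export
write_graphml <- function(tree, path) {
  g <- as_igraph(tree)
  # GraphML has no NA; encode missing sequences as empty strings
  for (at in c("sequence_nt", "sequence_aa")) {
    v <- igraph::vertex_attr(g, at)
    v[is.na(v)] <- ""
    g <- igraph::set_vertex_attr(g, at, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  for (at in c("sequence_nt", "sequence_aa")) {
    v <- igraph::vertex_attr(g, at)
    v[!is.na(v) & v == ""] <- NA_character_
    g <- igraph::set_vertex_attr(g, at, value = v)
  }
  igraph_to_lineage_tree(g)
}
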