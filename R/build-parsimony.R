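# --- shared alignment / topology machinery ---------------------------------

# nucleotide -> bitmask encoding (A=1, C=2, G=4, T=8; N and gap match all)
NT_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)

check_alignment <- function(alignment, germline_label) {
  if (is.null(names(alignment))) stop("alignment must be a named vector")
  if (!germline_label %in% names(alignment))
    stop("germline '", germline_label, "' missing from alignment")
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment sequences must have equal length")
  invisible(alignment)
}

# sites x taxa bitmask matrix
encode_alignment <- function(alignment) {
  m <- vapply(alignment, function(s) {
    b <- NT_BITS[strsplit(toupper(s), "")[[1]]]
    if (anyNA(b)) stop("non-ACGTN- character in alignment")
    unname(b)
  }, integer(nchar(alignment[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- names(alignment)
  m
}

# unique/NJ starting topology as an unrooted ape phylo
start_topology <- function(alignment, germline_label) {
  nm <- c(germline_label, setdiff(names(alignment), germline_label))
  if (length(nm) == 2)
    return(ape::read.tree(text = paste0("(", nm[1], ",", nm[2], ");")))
  if (length(nm) == 3)
    return(ape::read.tree(text = paste0("(", paste(nm, collapse = ","), ");")))
  D <- compute_distances(stats::setNames(alignment[nm], nm),
                         metric = "hamming")
  nj <- build_nj(D)
  # write the NJ tree re-rooted at an internal node so ape sees the
  # standard unrooted binary shape (trifurcating root)
  ape::read.tree(text = unrooted_newick(nj))
}

# Newick of a lineage tree as an unrooted topology: rooted at an inferred
# internal node when one exists, so leaves (incl. the germline) are tips
unrooted_newick <- function(tree) {
  inf <- tree$nodes$node_id[tree$nodes$kind == "inferred"]
  if (!length(inf)) return(write_newick(tree))
  start <- inf[length(inf)]  # final NJ join: degree-3 center
  adj <- split(data.frame(to = c(tree$edges$child, tree$edges$parent),
                          w = c(tree$edges$weight, tree$edges$weight),
                          stringsAsFactors = FALSE),
               c(tree$edges$parent, tree$edges$child))
  fmt <- function(id, from) {
    nb <- adj[[id]]
    lab <- if (id %in% inf) "" else id
    if (is.null(nb)) return(lab)
    nb <- nb[nb$to != from | is.na(from), , drop = FALSE]
    if (!nrow(nb)) return(lab)
    paste0("(", paste(vapply(seq_len(nrow(nb)), function(r) {
      paste0(fmt(nb$to[r], id), ":", format(nb$w[r], digits = 12))
    }, character(1)), collapse = ","), ")", lab)
  }
  paste0(fmt(start, NA_character_), ";")
}

# collapse inferred nodes with a single child into their outgoing edge
lt_suppress_unifurcations <- function(tree) {
  repeat {
    kids <- table(tree$edges$parent)
    uni <- names(kids)[kids == 1]
    uni <- uni[uni %in% tree$nodes$node_id[tree$nodes$kind == "inferred"]]
    uni <- setdiff(uni, tree$root_id)
    if (!length(uni)) break
    u <- uni[1]
    ein <- which(tree$edges$child == u)
    eout <- which(tree$edges$parent == u)
    tree$edges$parent[eout] <- tree$edges$parent[ein]
    tree$edges$weight[eout] <- tree$edges$weight[eout] + tree$edges$weight[ein]
    tree$edges <- tree$edges[-ein, , drop = FALSE]
    tree$nodes <- tree$nodes[tree$nodes$node_id != u, , drop = FALSE]
  }
  validate_lineage_tree(tree)
  tree
}

# germline-rooted lineage tree from an (unrooted) topology
lineage_from_topology <- function(phy, germline_label, alignment,
                                  info = list()) {
  lt <- phylo_to_lineage(phy, germline_label, sequences = alignment,
                         info = info)
  lt_suppress_unifurcations(lt)
}

# --- Fitch small parsimony --------------------------------------------------

#' Fitch parsimony score of a topology
#'
#' Minimum number of substitutions required to explain an equal-length
#' nucleotide alignment on a tree, by the Fitch set algorithm (uniform
#' cost). The score does not depend on the root position.
#'
#' @param phy an `ape` phylo whose tip labels name alignment rows.
#' @param alignment named character vector of equal-length sequences.
#' @return integer parsimony score.
#' @export
fitch_score <- function(phy, alignment) {
  enc <- encode_alignment(alignment)
  rt <- if (ape::is.rooted(phy) && ape::is.binary(phy)) phy
        else ape::root(phy, outgroup = phy$tip.label[1], resolve.root = TRUE)
  rt <- stats::reorder(rt, "postorder")
  ntip <- length(rt$tip.label)
  S <- nrow(enc)
  sets <- matrix(0L, S, ntip + rt$Nnode)
  sets[, seq_len(ntip)] <- enc[, rt$tip.label, drop = FALSE]
  score <- 0L
  for (nd in unique(rt$edge[, 1])) {
    ch <- rt$edge[rt$edge[, 1] == nd, 2]
    cur <- sets[, ch[1]]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(cur, sets[, c2])
      un <- bitwOr(cur, sets[, c2])
      empty <- inter == 0L
      score <- score + sum(empty)
      cur <- ifelse(empty, un, inter)
    }
    sets[, nd] <- cur
  }
  score
}

# lowest set bit -> base letter
bit_to_base <- function(bits) {
  b <- bitwAnd(bits, -bits)  # lowest set bit
  c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")[as.character(b)]
}

# Fitch traceback on a germline-rooted lineage tree: assigns sequences to
# inferred nodes and per-edge substitution counts; returns the tree
fitch_annotate <- function(tree, alignment) {
  enc <- encode_alignment(alignment)
  S <- nrow(enc)
  ids <- lt_preorder(tree)
  kids <- split(tree$edges$child, tree$edges$parent)
  sets <- matrix(0L, S, length(ids), dimnames = list(NULL, ids))
  for (id in rev(ids)) {
    if (id %in% names(alignment)) {
      sets[, id] <- enc[, id]
    } else {
      ch <- kids[[id]]
      cur <- sets[, ch[1]]
      for (c2 in ch[-1]) {
        inter <- bitwAnd(cur, sets[, c2])
        un <- bitwOr(cur, sets[, c2])
        cur <- ifelse(inter == 0L, un, inter)
      }
      sets[, id] <- cur
    }
  }
  state <- matrix(0L, S, length(ids), dimnames = list(NULL, ids))
  pm <- lt_parent_map(tree)
  for (id in ids) {
    if (id == tree$root_id) {
      s <- sets[, id]
      state[, id] <- bitwAnd(s, -s)  # deterministic: lowest bit
      next
    }
    ps <- state[, pm[[id]]]
    keep <- bitwAnd(sets[, id], ps) != 0L
    s <- sets[, id]
    state[, id] <- ifelse(keep, ps, bitwAnd(s, -s))
  }
  # per-edge substitution counts and inferred sequences
  for (e in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[e]; c <- tree$edges$child[e]
    tree$edges$weight[e] <- sum(state[, p] != state[, c])
  }
  inferred <- tree$nodes$node_id[tree$nodes$kind == "inferred"]
  for (id in inferred) {
    i <- tree$nodes$node_id == id
    tree$nodes$sequence_nt[i] <-
      paste(bit_to_base(state[, id]), collapse = "")
  }
  tree
}

#' Build a maximum parsimony lineage tree
#'
#' Minimises the Fitch small-parsimony score over topologies by
#' nearest-neighbor-interchange (NNI) hill climbing from a neighbor-joining
#' start tree, or by exhaustive enumeration of all unrooted topologies
#' (`search = "exhaustive"`, allowed up to 7 leaves and guaranteed
#' optimal). The best topology is rooted at the germline; each edge weight
#' is the number of substitutions implied by a deterministic Fitch
#' traceback (parent state retained on ties), and inferred internal nodes
#' receive the traceback sequences.
#'
#' @param alignment named character vector of equal-length nucleotide
#'   sequences including the germline.
#' @param germline_label name of the germline sequence (default
#'   `"germline"`).
#' @param search `"nni"` (default) or `"exhaustive"`.
#' @param clonotype optional `clonotype` supplying cell counts.
#' @return list with elements `tree` (a `lineage_tree`) and `score`
#'   (integer parsimony score).
#' @export
build_parsimony <- function(alignment, germline_label = "germline",
                            search = c("nni", "exhaustive"),
                            clonotype = NULL) {
  search <- match.arg(search)
  check_alignment(alignment, germline_label)
  n <- length(alignment)
  if (n <= 3 || search == "nni") {
    phy <- start_topology(alignment, germline_label)
    best <- phy
    best_score <- fitch_score(best, alignment)
    if (n >= 4) {
      repeat {
        nb <- phangorn::nni(best)
        scores <- vapply(nb, fitch_score, numeric(1), alignment = alignment)
        if (min(scores) < best_score) {
          best <- nb[[which.min(scores)]]
          best_score <- min(scores)
        } else break
      }
    }
  } else {
    if (n > 7) stop("exhaustive search limited to 7 leaves")
    all_t <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = names(alignment))
    scores <- vapply(all_t, fitch_score, numeric(1), alignment = alignment)
    best <- all_t[[which.min(scores)]]
    best_score <- min(scores)
  }
  tree <- lineage_from_topology(best, germline_label, alignment,
                                info = list(method = "mp", search = search))
  tree <- fitch_annotate(tree, alignment)
  tree <- apply_clonotype_counts(tree, clonotype)
  list(tree = tree, score = as.integer(best_score))
}

# fill sampled-node cell counts, cell ids and metadata fractions from a
# clonotype (variant ids as node labels)
apply_clonotype_counts <- function(tree, clonotype) {
  if (is.null(clonotype)) return(tree)
  m <- match(tree$nodes$node_id, clonotype$variants$variant_id)
  hit <- which(!is.na(m))
  tree$nodes$cell_count[hit] <- clonotype$variants$cell_count[m[hit]]
  for (i in hit) {
    id <- tree$nodes$node_id[i]
    tree$annotations[[id]]$cell_ids <- clonotype$cell_ids[[id]]
    fr <- clonotype$fractions[[id]]
    if (!is.null(fr) && length(fr)) tree$fractions[[id]] <- fr
  }
  tree$info$clonotype_id <- clonotype$clonotype_id
  tree
}
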