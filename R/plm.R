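# fixed amino-acid alphabet order for likelihood matrices
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# probability floor: PLM exports sometimes contain exact zeros
PLM_FLOOR <- 1e-12

#' Per-sequence pseudolikelihood from a per-residue likelihood matrix
#'
#' The mean (not the sum, so values are comparable across sequence
#' lengths) natural-log probability of the observed residue at each
#' position: `mean_i ln P[i, seq[i]]`, with probabilities floored at
#' `1e-12`.
#'
#' @param sequence_aa amino-acid string over the 20-letter alphabet.
#' @param matrix positions x alphabet probability matrix; column names
#'   must be the amino-acid alphabet.
#' @return negative (or zero) numeric pseudolikelihood.
#' @export
pseudolikelihood <- function(sequence_aa, matrix) {
  res <- strsplit(sequence_aa, "")[[1]]
  if (length(res) != nrow(matrix))
    stop("sequence length (", length(res), ") != matrix rows (",
         nrow(matrix), ")")
  j <- match(res, colnames(matrix))
  if (anyNA(j)) stop("residue(s) outside the matrix alphabet: ",
                     paste(unique(res[is.na(j)]), collapse = ", "))
  p <- matrix[cbind(seq_along(res), j)]
  mean(log(pmax(p, PLM_FLOOR)))
}

#' Load per-residue likelihood matrices and attach them to tree nodes
#'
#' Accepts either a directory of per-node CSV files (`<node_id>.csv`,
#' header = the 20 amino-acid letters, one row per position) or one
#' long-format CSV with `node_id` and `position` columns followed by the
#' alphabet columns. Rows not summing to 1 within `1e-3` are renormalized
#' with a warning; grosser violations are an error. Matrices whose row
#' count does not match the node's amino-acid sequence length are
#' reported.
#'
#' @param path directory or CSV file path.
#' @param tree optional `lineage_tree` used to validate node ids and
#'   sequence lengths.
#' @return named list (by node id) with elements `matrix` and
#'   `pseudolikelihood` (computed when the tree supplies the node's
#'   amino-acid sequence).
#' @export
load_likelihoods <- function(path, tree = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    mats <- lapply(files, function(f) {
      validate_likelihood_matrix(as.matrix(utils::read.csv(f)), f)
    })
    names(mats) <- sub("\\.csv$", "", basename(files))
  } else {
    long <- utils::read.csv(path)
    if (!all(c("node_id", "position") %in% names(long)))
      stop("long-format likelihood CSV needs node_id and position columns")
    mats <- lapply(split(long, long$node_id), function(d) {
      d <- d[order(d$position), , drop = FALSE]
      validate_likelihood_matrix(
        as.matrix(d[, setdiff(names(d), c("node_id", "position"))]), path)
    })
  }
  out <- lapply(names(mats), function(id) {
    pll <- NA_real_
    if (!is.null(tree)) {
      i <- match(id, tree$nodes$node_id)
      if (is.na(i)) {
        message("likelihood matrix '", id, "' matches no tree node")
      } else {
        aa <- tree$nodes$sequence_aa[i]
        if (!is.na(aa)) {
          if (nchar(aa) != nrow(mats[[id]]))
            message("node '", id, "': matrix rows (", nrow(mats[[id]]),
                    ") != sequence length (", nchar(aa), ")")
          else pll <- pseudolikelihood(aa, mats[[id]])
        }
      }
    }
    list(matrix = mats[[id]], pseudolikelihood = pll)
  })
  names(out) <- names(mats)
  out
}

validate_likelihood_matrix <- function(m, origin) {
  if (!identical(sort(colnames(m)), sort(AA_ALPHABET)))
    stop("likelihood matrix header must be the 20 amino-acid letters (",
         origin, ")")
  m <- m[, AA_ALPHABET, drop = FALSE]
  rownames(m) <- NULL
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off > 1e-3))
    stop("likelihood rows deviate from sum 1 by more than 1e-3 (", origin, ")")
  if (any(off > 1e-6)) {
    warning("renormalizing likelihood rows deviating from sum 1 (", origin,
            ")")
    m <- m / rs
  }
  m
}

#' Per-substitution likelihood profile along a tree edge
#'
#' Classifies each aligned position of a parent/child pair as mutated or
#' conserved and reports, per position, the parent model's probability of
#' the parent residue, the parent model's probability of the child
#' residue, the child model's probability of the child residue, and the
#' rank of the child residue within the parent's row (1 = most likely).
#' Positions with a gap in either sequence are excluded from both classes
#' and counted separately (PLM rows do not cover gaps). Scoring under
#' both the parent's and the child's model is reported because either
#' reading is defensible; interpretation is left to the user.
#'
#' @param tree a `lineage_tree` with amino-acid sequences on the edge's
#'   nodes.
#' @param likelihoods output of [load_likelihoods()] (or
#'   [standin_scorer()]).
#' @param parent_id,child_id node ids of the edge.
#' @return list with `positions` (per-position data frame) and
#'   `summary` (mean probabilities per class plus counts).
#' @export
edge_substitution_profile <- function(tree, likelihoods, parent_id,
                                      child_id) {
  pa <- tree$nodes$sequence_aa[match(parent_id, tree$nodes$node_id)]
  ca <- tree$nodes$sequence_aa[match(child_id, tree$nodes$node_id)]
  if (is.na(pa) || is.na(ca)) stop("both nodes need amino-acid sequences")
  if (nchar(pa) != nchar(ca))
    stop("parent and child sequences must be aligned (equal length)")
  pm <- likelihoods[[parent_id]]$matrix
  cm <- likelihoods[[child_id]]$matrix
  if (is.null(pm) || is.null(cm))
    stop("both nodes need likelihood matrices")
  pr <- strsplit(pa, "")[[1]]
  cr <- strsplit(ca, "")[[1]]
  gap <- pr == "-" | cr == "-"
  idx <- which(!gap)
  rows <- lapply(idx, function(i) {
    rank_child <- rank(-pm[i, ], ties.method = "min")[[cr[i]]]
    data.frame(position = i,
               parent_residue = pr[i], child_residue = cr[i],
               class = if (pr[i] == cr[i]) "conserved" else "mutated",
               p_parent_parent = unname(pm[i, pr[i]]),
               p_parent_child = unname(pm[i, cr[i]]),
               p_child_child = unname(cm[i, cr[i]]),
               child_rank_in_parent = rank_child,
               stringsAsFactors = FALSE)
  })
  pos <- do.call(rbind, rows)
  agg <- function(cls, col) {
    v <- pos[[col]][pos$class == cls]
    if (length(v)) mean(v) else NA_real_
  }
  list(positions = pos,
       summary = data.frame(
         n_mutated = sum(pos$class == "mutated"),
         n_conserved = sum(pos$class == "conserved"),
         n_gap = sum(gap),
         mean_p_parent_child_mutated = agg("mutated", "p_parent_child"),
         mean_p_child_child_mutated = agg("mutated", "p_child_child"),
         mean_p_parent_parent_conserved = agg("conserved", "p_parent_parent"),
         stringsAsFactors = FALSE))
}

#' Correlate pseudolikelihood with evolutionary distance from the germline
#'
#' For every tree in a forest, the Spearman and Pearson correlations of
#' node pseudolikelihood against weighted distance to the germline, over
#' sampled nodes with likelihood matrices; trees with fewer than 3 such
#' nodes or with zero variance in either variable get `NA` with a reason.
#' A pooled correlation across all trees is appended as row
#' `"pooled"`.
#'
#' @param forest named list of `lineage_tree` objects.
#' @param likelihoods named list (by tree id) of [load_likelihoods()]
#'   outputs; for a single tree, the output itself.
#' @return data frame with columns `tree_id`, `n`, `spearman`, `pearson`,
#'   `reason`.
#' @export
likelihood_vs_evolution <- function(forest, likelihoods) {
  if (inherits(forest, "lineage_tree")) {
    forest <- list(tree_1 = forest)
    likelihoods <- list(tree_1 = likelihoods)
  }
  if (is.null(names(forest)))
    names(forest) <- paste0("tree_", seq_along(forest))
  pool_d <- numeric(0); pool_p <- numeric(0)
  rows <- lapply(names(forest), function(id) {
    tree <- forest[[id]]
    lk <- likelihoods[[id]]
    d <- node_depths(tree, weighted = TRUE)
    samp <- tree$nodes$node_id[tree$nodes$kind == "sampled"]
    samp <- samp[samp %in% names(lk)]
    pll <- vapply(samp, function(nid) lk[[nid]]$pseudolikelihood, numeric(1))
    keep <- is.finite(pll)
    x <- d[samp][keep]; y <- pll[keep]
    pool_d <<- c(pool_d, x); pool_p <<- c(pool_p, y)
    cor_row(id, x, y)
  })
  out <- do.call(rbind, c(rows, list(cor_row("pooled", pool_d, pool_p))))
  rownames(out) <- NULL
  out
}

cor_row <- function(id, x, y) {
  if (length(x) < 3)
    return(data.frame(tree_id = id, n = length(x), spearman = NA_real_,
                      pearson = NA_real_, reason = "fewer than 3 points",
                      stringsAsFactors = FALSE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(tree_id = id, n = length(x), spearman = NA_real_,
                      pearson = NA_real_, reason = "zero variance",
                      stringsAsFactors = FALSE))
  data.frame(tree_id = id, n = length(x),
             spearman = stats::cor(x, y, method = "spearman"),
             pearson = stats::cor(x, y, method = "pearson"),
             reason = "", stringsAsFactors = FALSE)
}

#' Column-frequency stand-in scorer
#'
#' A deterministic substitute for an external protein language model,
#' used as a test substrate: per-position probabilities are the
#' additive-smoothed (pseudo-count 1) column frequencies of the lineage's
#' amino-acid alignment, and every node receives the same matrix. Rows
#' sum to 1 by construction.
#'
#' @param alignment named character vector of aligned amino-acid
#'   sequences (one per node).
#' @return named list (by node id) with `matrix` and `pseudolikelihood`,
#'   in the same shape as [load_likelihoods()].
#' @export
standin_scorer <- function(alignment) {
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment sequences must have equal length")
  L <- nchar(alignment[[1]])
  chars <- vapply(alignment, function(s) strsplit(s, "")[[1]],
                  character(L))
  if (is.null(dim(chars))) chars <- matrix(chars, nrow = 1)
  m <- t(apply(chars, 1, function(col) {
    counts <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    (as.numeric(counts) + 1) / (sum(counts) + 20)
  }))
  colnames(m) <- AA_ALPHABET
  out <- lapply(names(alignment), function(id) {
    seq_nogap <- alignment[[id]]
    pll <- if (grepl("-", seq_nogap, fixed = TRUE)) NA_real_
           else pseudolikelihood(seq_nogap, m)
    list(matrix = m, pseudolikelihood = pll)
  })
  names(out) <- names(alignment)
  out
}
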