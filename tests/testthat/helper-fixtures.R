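# Shared in-code fixtures and independent oracles.

# random germline-rooted lineage tree: node i attaches to a uniform
# earlier node with a positive random weight
random_tree <- function(n, seed, id_prefix = "v") {
  withr::with_seed(seed, {
    ids <- c("germline", paste0(id_prefix, seq_len(n - 1)))
    parent <- c(NA, vapply(seq_len(n - 1), function(i) {
      ids[sample.int(i, 1)]
    }, character(1)))
    weight <- c(NA, stats::runif(n - 1, 0.5, 3))
    nodes <- data.frame(node_id = ids,
                        kind = c("germline", rep("sampled", n - 1)),
                        sequence_nt = NA_character_,
                        sequence_aa = NA_character_,
                        cell_count = c(0, sample(1:5, n - 1, replace = TRUE)),
                        stringsAsFactors = FALSE)
    edges <- data.frame(parent = parent[-1], child = ids[-1],
                        weight = weight[-1], stringsAsFactors = FALSE)
    lineage_tree(nodes, edges, "germline")
  })
}

# symmetric random distance matrix with all-distinct off-diagonal entries
random_distance_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    labels <- c("germline", paste0("v", seq_len(n - 1)))
    D <- matrix(0, n, n, dimnames = list(labels, labels))
    vals <- sample(seq_len(n * n), n * (n - 1) / 2) + stats::runif(1)
    k <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      k <- k + 1
      D[i, j] <- D[j, i] <- vals[k]
    }
    D
  })
}

# chain germline -> ids[1] -> ids[2] -> ...
chain_tree <- function(ids, weights = rep(1, length(ids))) {
  nodes <- data.frame(node_id = c("germline", ids),
                      kind = c("germline", rep("sampled", length(ids))),
                      sequence_nt = NA_character_,
                      sequence_aa = NA_character_,
                      cell_count = c(0, rep(1, length(ids))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = c("germline", ids[-length(ids)]),
                      child = ids, weight = weights,
                      stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, "germline")
}

# star: all n variants directly under the germline
star_tree <- function(n, w = 1) {
  ids <- paste0("v", seq_len(n))
  nodes <- data.frame(node_id = c("germline", ids),
                      kind = c("germline", rep("sampled", n)),
                      sequence_nt = NA_character_,
                      sequence_aa = NA_character_,
                      cell_count = c(0, rep(1, n)), stringsAsFactors = FALSE)
  edges <- data.frame(parent = "germline", child = ids, weight = w,
                      stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, "germline")
}

# amino-acid helpers: stop codons mapped onto a standard residue so the
# 20-letter PLM alphabet covers every position
fix_stops <- function(aa) gsub("\\*", "G", aa)
translate_no_stop <- function(nt) fix_stops(bcrforest:::translate_nt(nt))

# --- independent oracles ----------------------------------------------------

# decode a Pruefer sequence into the edge list of a labelled tree on 1..n
prufer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (x in pr) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (x in pr) {
    leaf <- which(degree == 1L)[1]
    k <- k + 1L
    edges[k, ] <- c(leaf, x)
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# minimum spanning-tree weight by exhaustive enumeration over all n^(n-2)
# labelled trees (Cayley's formula)
min_spanning_weight_bruteforce <- function(D) {
  n <- nrow(D)
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(as.integer(seqs[r, ]), n)
    w <- sum(D[ed])
    if (w < best) best <- w
  }
  best
}

# patristic distance matrix of a lineage tree computed from first
# principles (path enumeration to the root, no graph library)
patristic_oracle <- function(tree) {
  ids <- tree$nodes$node_id
  pm <- setNames(tree$edges$parent, tree$edges$child)
  wt <- setNames(tree$edges$weight, tree$edges$child)
  path_up <- function(id) {
    d <- c(setNames(0, id))
    while (id %in% names(pm)) {
      d <- c(d, setNames(unname(d[length(d)]) + wt[[id]], pm[[id]]))
      id <- pm[[id]]
    }
    d
  }
  paths <- lapply(setNames(ids, ids), path_up)
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) {
    if (a == b) next
    anc <- intersect(names(paths[[a]]), names(paths[[b]]))
    P[a, b] <- min(paths[[a]][anc] + paths[[b]][anc])
  }
  P
}

# alignment fixture: germline plus mutated copies at chosen positions
mutate_at <- function(seq, pos, base) {
  s <- strsplit(seq, "")[[1]]
  s[pos] <- base
  paste(s, collapse = "")
}

# simulated alignment of n_taxa random sequences for parsimony/ML checks
sim_alignment <- function(seed, n_taxa = 6, length = 60, mu = 0.05) {
  sim <- simulate_lineage(simulation_config(
    seed = seed, germline_length = 3 * ceiling(length / 3),
    branching_rate = 2, mutation_rate = mu, generations = 3,
    sampling_fraction = 1))
  cl <- sim$clonotype
  if (is.null(cl) || nrow(cl$variants) < n_taxa - 1) return(NULL)
  aln <- c(germline = cl$germline_nt,
           setNames(cl$variants$sequence_nt, cl$variants$variant_id))
  aln[seq_len(n_taxa)]
}
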