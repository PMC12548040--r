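#' Configuration for the somatic-hypermutation lineage simulator
#'
#' The defaults describe a desk-scale clonal expansion: a 300 nt germline,
#' a Poisson branching process with mean 1.5 offspring per node over 4
#' generations, a per-site per-generation substitution probability of
#' 0.01 (so about 3 mutations per edge), 80% sampling, geometric cell
#' counts with mean 3, and one-way isotype switching IgM -> IgG -> IgA
#' with probability 0.3 per generation.
#'
#' @param seed mandatory integer seed; a single pseudorandom stream is
#'   used for the whole run, so runs are byte-reproducible.
#' @param germline_length germline length in nt (codon multiple).
#' @param branching_rate mean offspring per node per generation
#'   (Poisson).
#' @param mutation_rate per-site per-generation substitution probability;
#'   each edge carries `Binomial(L, mutation_rate)` distinct substituted
#'   positions.
#' @param generations number of generations.
#' @param sampling_fraction probability that a generated B cell variant
#'   is observed (the germline is always retained as reference, never as
#'   an observed cell).
#' @param cell_count_mean mean of the geometric cell-count law.
#' @param isotype_switch_prob per-generation probability of switching one
#'   step along IgM -> IgG -> IgA.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed, germline_length = 300,
                              branching_rate = 1.5, mutation_rate = 0.01,
                              generations = 4, sampling_fraction = 0.8,
                              cell_count_mean = 3,
                              isotype_switch_prob = 0.3) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            germline_length > 0, germline_length %% 3 == 0,
            branching_rate >= 0,
            mutation_rate > 0, mutation_rate < 1,
            generations >= 0,
            sampling_fraction > 0, sampling_fraction <= 1,
            cell_count_mean >= 1,
            isotype_switch_prob >= 0, isotype_switch_prob <= 1)
  structure(list(seed = as.integer(seed), germline_length = germline_length,
                 branching_rate = branching_rate,
                 mutation_rate = mutation_rate, generations = generations,
                 sampling_fraction = sampling_fraction,
                 cell_count_mean = cell_count_mean,
                 isotype_switch_prob = isotype_switch_prob),
            class = "simulation_config")
}

ISOTYPE_ORDER <- c("IgM", "IgG", "IgA")

#' Simulate a clonal lineage with known ground truth
#'
#' Draws a uniform random germline, runs the branching/mutation process
#' of [simulation_config()], samples observed nodes, and emits AIRR-style
#' sequence records (one row per cell, `germline_alignment` set to the
#' germline) together with the full simulation truth. A central 30 nt
#' codon-aligned window is annotated as the junction (CDR3 stand-in).
#'
#' @param config a `simulation_config`.
#' @param out_dir optional directory; when given, writes `airr.tsv`,
#'   `sequences.fasta` (observed variants + germline) and `truth.json`.
#' @return list with `records` (data frame in [read_airr()] layout),
#'   `truth` (node table, per-edge mutated positions, germline, junction
#'   interval, config) and `clonotype` (the assembled `clonotype` over
#'   the observed variants, junction interval attached).
#' @export
simulate_lineage <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- withr::with_seed(config$seed, simulate_lineage_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_airr(sim$records, file.path(out_dir, "airr.tsv"))
    obs <- sim$truth$nodes[sim$truth$nodes$observed, , drop = FALSE]
    write_fasta(c(stats::setNames(obs$sequence, obs$node_id),
                  germline = sim$truth$germline),
                file.path(out_dir, "sequences.fasta"))
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  sim
}

simulate_lineage_impl <- function(config) {
  L <- config$germline_length
  bases <- c("A", "C", "G", "T")
  germline <- paste(sample(bases, L, replace = TRUE), collapse = "")
  if (config$branching_rate == 0 && config$generations > 0)
    warning("branching_rate 0: germline-only lineage")
  nodes <- data.frame(node_id = "germline", parent = NA_character_,
                      generation = 0L, isotype = "IgM",
                      sequence = germline, observed = FALSE,
                      cell_count = 0, stringsAsFactors = FALSE)
  mutations <- list()  # node_id -> integer positions mutated on its edge
  k <- 0L
  current <- "germline"
  for (g in seq_len(config$generations)) {
    nxt <- character(0)
    for (p in current) {
      pi <- match(p, nodes$node_id)
      n_child <- stats::rpois(1, config$branching_rate)
      for (cc in seq_len(n_child)) {
        k <- k + 1L
        id <- paste0("node_", k)
        s <- strsplit(nodes$sequence[pi], "")[[1]]
        nmut <- stats::rbinom(1, L, config$mutation_rate)
        pos <- if (nmut > 0) sort(sample.int(L, nmut)) else integer(0)
        for (m in pos) s[m] <- sample(setdiff(bases, s[m]), 1)
        iso <- nodes$isotype[pi]
        io <- match(iso, ISOTYPE_ORDER)
        if (io < length(ISOTYPE_ORDER) &&
            stats::runif(1) < config$isotype_switch_prob)
          iso <- ISOTYPE_ORDER[io + 1L]
        nodes <- rbind(nodes, data.frame(
          node_id = id, parent = p, generation = g, isotype = iso,
          sequence = paste(s, collapse = ""), observed = FALSE,
          cell_count = 0, stringsAsFactors = FALSE))
        mutations[[id]] <- pos
        nxt <- c(nxt, id)
      }
    }
    current <- nxt
    if (!length(current)) break
  }
  nonroot <- nodes$node_id != "germline"
  nodes$observed[nonroot] <-
    stats::runif(sum(nonroot)) < config$sampling_fraction
  n_obs <- sum(nodes$observed)
  nodes$cell_count[nodes$observed] <-
    stats::rgeom(n_obs, prob = 1 / config$cell_count_mean) + 1L
  # junction: central codon-aligned 30 nt window (0-based half-open)
  jstart <- max(0L, 3L * ((L %/% 2L) %/% 3L) - 15L)
  jstart <- 3L * (jstart %/% 3L)
  jend <- min(L, jstart + 30L)
  truth <- list(config = unclass(config), germline = germline,
                nodes = nodes, mutations = mutations,
                junction_interval = c(jstart, jend))
  obs <- nodes[nodes$observed, , drop = FALSE]
  rec_rows <- lapply(seq_len(nrow(obs)), function(i) {
    ncell <- obs$cell_count[i]
    data.frame(
      sequence_id = paste0(obs$node_id[i], "_seq", seq_len(ncell)),
      cell_id = paste0(obs$node_id[i], "_cell", seq_len(ncell)),
      sequence_nt = obs$sequence[i],
      sequence_aa = "",
      v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
      junction_nt = substr(obs$sequence[i], jstart + 1L, jend),
      c_call = obs$isotype[i],
      duplicate_count = 1L,
      clone_id = "clonotype_1",
      germline_alignment_nt = germline,
      source = "single_cell",
      stringsAsFactors = FALSE)
  })
  records <- if (length(rec_rows)) do.call(rbind, rec_rows) else
    data.frame(sequence_id = character(), cell_id = character(),
               sequence_nt = character(), sequence_aa = character(),
               v_call = character(), j_call = character(),
               junction_nt = character(), c_call = character(),
               duplicate_count = integer(), clone_id = character(),
               germline_alignment_nt = character(), source = character(),
               stringsAsFactors = FALSE)
  clono <- if (nrow(records)) {
    cl <- group_clonotypes(records, strategy = "clone_id")$clonotypes[[1]]
    cl$junction_interval <- c(jstart, jend)
    cl
  } else NULL
  list(records = records, truth = truth, clonotype = clono)
}

#' Map tree variant labels back to simulation truth nodes
#'
#' Variants are matched to truth nodes by sequence identity; variants
#' whose sequence occurs at several truth nodes (possible but rare under
#' high mutation rates) are dropped from the mapping.
#'
#' @param sim output of [simulate_lineage()].
#' @return named character vector variant_id -> truth node id.
#' @export
variant_truth_map <- function(sim) {
  obs <- sim$truth$nodes[sim$truth$nodes$observed, , drop = FALSE]
  dup <- obs$sequence[duplicated(obs$sequence)]
  obs <- obs[!obs$sequence %in% dup, , drop = FALSE]
  v <- sim$clonotype$variants
  m <- match(v$sequence_nt, obs$sequence)
  stats::setNames(obs$node_id[m], v$variant_id)[!is.na(m)]
}

#' Fraction of true parents recovered by a reconstructed tree
#'
#' For every mapped variant, the true parent is its closest observed
#' ancestor in the simulation truth (the germline when none is
#' observed); the reconstruction is credited when the tree parent maps
#' to that node.
#'
#' @param sim output of [simulate_lineage()].
#' @param tree a `lineage_tree` built over the simulation's clonotype.
#' @return fraction in `[0, 1]` (`NA` when no variant could be scored).
#' @export
parent_recovery <- function(sim, tree) {
  vmap <- variant_truth_map(sim)
  truth <- sim$truth$nodes
  pm <- lt_parent_map(tree)
  true_parent <- function(node_id) {
    p <- truth$parent[match(node_id, truth$node_id)]
    while (!is.na(p) && p != "germline" &&
           !truth$observed[match(p, truth$node_id)]) {
      p <- truth$parent[match(p, truth$node_id)]
    }
    if (is.na(p)) "germline" else p
  }
  scored <- 0L; correct <- 0L
  for (v in names(vmap)) {
    if (!v %in% names(pm)) next
    tp <- true_parent(vmap[[v]])
    pred <- pm[[v]]
    pred_truth <- if (pred == tree$root_id) "germline" else vmap[pred]
    if (is.null(pred_truth) || is.na(pred_truth)) next
    scored <- scored + 1L
    if (identical(unname(pred_truth), tp)) correct <- correct + 1L
  }
  if (!scored) return(NA_real_)
  correct / scored
}

#' Simulate predicted structures for a lineage
#'
#' The germline structure is an ideal helix-like CA trace (one residue
#' per codon). Each observed node inherits the germline trace and
#' displaces one CA per inherited mutated codon by
#' `displacement_per_mutation` Angstrom in a seeded random direction;
#' pLDDT values are seeded uniform draws in `[60, 95]`. Structures are
#' labelled synthetic stand-ins for predictor output throughout.
#'
#' @param truth truth component of [simulate_lineage()].
#' @param displacement_per_mutation displacement magnitude in Angstrom.
#' @param seed integer seed (default: the simulation seed plus 1).
#' @param chain chain id (default `"H"`), role `"antibody"`.
#' @param out_dir optional directory to write one PDB per model.
#' @return named list of `structure_model`s (`germline` plus observed
#'   node ids).
#' @export
simulate_structures <- function(truth, displacement_per_mutation = 1,
                                seed = NULL, chain = "H", out_dir = NULL) {
  if (is.null(seed)) seed <- truth$config$seed + 1L
  models <- withr::with_seed(seed,
    simulate_structures_impl(truth, displacement_per_mutation, chain))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(models))
      write_pdb_ca(models[[id]], file.path(out_dir, paste0(id, ".pdb")))
  }
  models
}

simulate_structures_impl <- function(truth, disp, chain) {
  L <- nchar(truth$germline)
  n_res <- L %/% 3L
  i <- seq_len(n_res)
  base_xyz <- cbind(x = 2.3 * cos(i * 100 * pi / 180),
                    y = 2.3 * sin(i * 100 * pi / 180),
                    z = 1.5 * i)
  aa_of <- function(nt) {
    aa <- strsplit(translate_nt(nt), "")[[1]]
    aa[aa == "*"] <- "G"  # keep residues structurally representable
    aa
  }
  # displacement vectors are drawn once per mutation event and inherited,
  # so structural divergence accumulates along the lineage exactly as
  # mutations do
  cum_disp <- list(germline = matrix(0, n_res, 3))
  for (id in truth$nodes$node_id[-1]) {
    p <- truth$nodes$parent[match(id, truth$nodes$node_id)]
    cum <- cum_disp[[p]]
    for (r in unique((truth$mutations[[id]] - 1L) %/% 3L + 1L)) {
      u <- stats::rnorm(3)
      cum[r, ] <- cum[r, ] + disp * u / sqrt(sum(u^2))
    }
    cum_disp[[id]] <- cum
  }
  ids <- c("germline",
           truth$nodes$node_id[truth$nodes$observed])
  models <- lapply(ids, function(id) {
    xyz <- base_xyz + cum_disp[[id]]
    aa <- aa_of(truth$nodes$sequence[match(id, truth$nodes$node_id)])
    atoms <- data.frame(
      chain = chain, resno = i, insert = "",
      resid = bio3d::aa123(aa), aa = aa,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      plddt = round(stats::runif(n_res, 60, 95), 2),
      role = "antibody", stringsAsFactors = FALSE)
    structure(list(node_id = id, atoms = atoms), class = "structure_model")
  })
  names(models) <- ids
  models
}
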