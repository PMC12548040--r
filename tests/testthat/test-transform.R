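# small NJ-like fixture: germline -> I1 -> {A (0), I2}, I2 -> {B, C}
fixture_tree <- function(wA = 0) {
  nodes <- data.frame(
    node_id = c("germline", "I1", "A", "I2", "B", "C"),
    kind = c("germline", "inferred", "sampled", "inferred", "sampled",
             "sampled"),
    sequence_nt = NA_character_, sequence_aa = NA_character_,
    cell_count = c(0, 0, 3, 0, 1, 2), stringsAsFactors = FALSE)
  edges <- data.frame(
    parent = c("germline", "I1", "I1", "I2", "I2"),
    child = c("I1", "A", "I2", "B", "C"),
    weight = c(1, wA, 2, 0.5, 1.5), stringsAsFactors = FALSE)
  lineage_tree(nodes, edges, "germline")
}

test_that("trees without inferred nodes pass through all removal modes", {
  tr <- random_tree(6, 3)
  for (mode in c("zero_length_only", "replace_by_closest_descendant",
                 "link_to_parent")) {
    out <- remove_internal_nodes(tr, mode)
    expect_setequal(out$nodes$node_id, tr$nodes$node_id)
    expect_equal(out$edges[order(out$edges$child), c("parent", "weight")],
                 tr$edges[order(tr$edges$child), c("parent", "weight")],
                 ignore_attr = TRUE)
  }
})

test_that("zero_length_only merges a zero-length sampled terminal upward", {
  tr <- fixture_tree(wA = 0)
  out <- remove_internal_nodes(tr, "zero_length_only")
  # A takes I1's place and inherits its child I2
  expect_false("I1" %in% out$nodes$node_id)
  expect_true("I2" %in% out$nodes$node_id)  # no zero-length terminal below
  pm <- setNames(out$edges$parent, out$edges$child)
  expect_equal(unname(pm["A"]), "germline")
  expect_equal(unname(pm["I2"]), "A")
  w <- setNames(out$edges$weight, out$edges$child)
  expect_equal(unname(w["I2"]), 2)
  # idempotence
  again <- remove_internal_nodes(out, "zero_length_only")
  expect_equal(again$edges, out$edges)
})

test_that("replace_by_closest_descendant removes every inferred node", {
  tr <- fixture_tree(wA = 0)
  out <- remove_internal_nodes(tr, "replace_by_closest_descendant")
  expect_true(all(out$nodes$kind != "inferred"))
  expect_setequal(out$nodes$node_id[out$nodes$kind == "sampled"],
                  c("A", "B", "C"))
  pm <- setNames(out$edges$parent, out$edges$child)
  # B is I2's closest descendant (0.5 < 1.5); A replaces I1 (weight 0)
  expect_equal(unname(pm["A"]), "germline")
  expect_equal(unname(pm["B"]), "A")
  expect_equal(unname(pm["C"]), "B")
})

test_that("link_to_parent flattens onto sampled ancestors preserving paths", {
  # hand-traced caterpillar NJ shape: both deep leaves end up under the
  # germline with their full path weights
  tr <- fixture_tree(wA = 1)
  before <- node_depths(tr, weighted = TRUE)
  out <- remove_internal_nodes(tr, "link_to_parent")
  expect_true(all(out$nodes$kind != "inferred"))
  pm <- setNames(out$edges$parent, out$edges$child)
  expect_equal(unname(pm[c("A", "B", "C")]),
               c("germline", "germline", "germline"))
  after <- node_depths(out, weighted = TRUE)
  expect_equal(after[c("A", "B", "C")], before[c("A", "B", "C")])
})

test_that("removal modes preserve the sampled node set on NJ trees", {
  for (seed in 1:20) {
    D <- random_distance_matrix(7, seed)
    nj <- build_nj(D)
    sampled <- sort(nj$nodes$node_id[nj$nodes$kind != "inferred"])
    for (mode in c("zero_length_only", "replace_by_closest_descendant",
                   "link_to_parent")) {
      out <- remove_internal_nodes(nj, mode)
      expect_equal(sort(out$nodes$node_id[out$nodes$kind != "inferred"]),
                   sampled)
    }
    # zero_length_only idempotent
    z1 <- remove_internal_nodes(nj, "zero_length_only")
    z2 <- remove_internal_nodes(z1, "zero_length_only")
    expect_equal(z2$edges, z1$edges)
    # link_to_parent preserves germline path weights of sampled nodes
    lp <- remove_internal_nodes(nj, "link_to_parent")
    d0 <- node_depths(nj, weighted = TRUE)
    d1 <- node_depths(lp, weighted = TRUE)
    expect_equal(d1[sampled], d0[sampled], tolerance = 1e-9)
  }
})

test_that("bulk integration collapses duplicates and attaches new leaves", {
  tr <- fixture_tree(wA = 1)
  tr$nodes$sequence_nt <- c("AAAA", NA, "AAAT", NA, "ATAT", "TTAT")
  bulk <- data.frame(
    sequence_id = c("b1", "b2"), cell_id = "",
    sequence_nt = c("AAAT", "AAGA"), sequence_aa = "",
    v_call = "IGHV1", j_call = "IGHJ4", junction_nt = "",
    c_call = "", duplicate_count = c(4L, 2L), clone_id = "cl1",
    germline_alignment_nt = "", source = "bulk", stringsAsFactors = FALSE)
  before_edges <- tr$edges
  out <- integrate_bulk(tr, bulk, strategy = "none")
  # identical sequence: cell count grows, no new node
  expect_equal(out$tree$nodes$cell_count[out$tree$nodes$node_id == "A"],
               3 + 4)
  # new sequence AAGA: distance 1 from germline AAAA, >1 elsewhere
  pm <- setNames(out$tree$edges$parent, out$tree$edges$child)
  expect_equal(unname(pm["b2"]), "germline")
  expect_equal(out$tree$edges$weight[out$tree$edges$child == "b2"], 1)
  # existing edges untouched
  expect_equal(out$tree$edges[seq_len(nrow(before_edges)), ], before_edges,
               ignore_attr = TRUE)
})

test_that("simulated bulk reads are assigned to their true clonotype", {
  sim <- simulate_lineage(simulation_config(seed = 2, generations = 3,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  obs <- sim$truth$nodes[sim$truth$nodes$observed, ][1:5, ]
  bulk <- data.frame(
    sequence_id = paste0("bulk", 1:5), cell_id = "",
    sequence_nt = obs$sequence, sequence_aa = "",
    v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
    junction_nt = substr(obs$sequence, sim$clonotype$junction_interval[1] + 1,
                         sim$clonotype$junction_interval[2]),
    c_call = "", duplicate_count = 1L, clone_id = "clonotype_1",
    germline_alignment_nt = "", source = "bulk", stringsAsFactors = FALSE)
  out <- integrate_bulk(sim$clonotype, bulk, strategy = "vjl")
  expect_equal(nrow(out$unassigned), 0)
  # a non-matching junction length is reported unassigned
  bad <- bulk[1, ]; bad$junction_nt <- "TT"
  out2 <- integrate_bulk(sim$clonotype, bad, strategy = "vjl")
  expect_equal(nrow(out2$unassigned), 1)
})

test_that("annotate_nodes computes per-node label fractions", {
  rec <- data.frame(
    sequence_id = paste0("s", 1:3), cell_id = paste0("c", 1:3),
    sequence_nt = "AAAA", sequence_aa = "", v_call = "V", j_call = "J",
    junction_nt = "", c_call = c("IgG", "IgG", "IgM"),
    duplicate_count = 1L, clone_id = "cl1", germline_alignment_nt = "AAAA",
    source = "single_cell", stringsAsFactors = FALSE)
  cl <- group_clonotypes(rec, strategy = "clone_id")$clonotypes[[1]]
  tr <- build_lineage(cl, method = "default")
  cells <- data.frame(cell_id = paste0("c", 1:3),
                      phenotype = c("memory", "plasma", "plasma"),
                      stringsAsFactors = FALSE)
  tr <- annotate_nodes(tr, cells, "phenotype")
  fr <- tr$fractions$variant_1$phenotype
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["plasma"]), 2 / 3)
  expect_null(tr$fractions$germline$phenotype)
  expect_error(annotate_nodes(tr, cells, "missing_col"), "not found")
})

test_that("simulator isotype fractions are recovered through annotation", {
  sim <- simulate_lineage(simulation_config(seed = 6, generations = 3,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  cl <- sim$clonotype
  tr <- build_lineage(cl, method = "default")
  cells <- data.frame(cell_id = sim$records$cell_id,
                      isotype = sim$records$c_call, stringsAsFactors = FALSE)
  tr <- annotate_nodes(tr, cells, "isotype")
  vmap <- variant_truth_map(sim)
  for (v in names(vmap)) {
    iso <- sim$truth$nodes$isotype[sim$truth$nodes$node_id == vmap[[v]]]
    fr <- tr$fractions[[v]]$isotype
    expect_equal(unname(fr[iso]), 1)
  }
})
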