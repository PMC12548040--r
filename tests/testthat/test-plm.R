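AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

uniform_matrix <- function(L) {
  m <- matrix(1 / 20, L, 20, dimnames = list(NULL, AA))
  m
}

test_that("pseudolikelihood closed forms hold", {
  expect_equal(pseudolikelihood("ACDY", uniform_matrix(4)), log(1 / 20))
  # one-hot rows matching the sequence: pseudolikelihood ~ 0
  seqaa <- "KLHW"
  m <- matrix(1e-12 / 19, 4, 20, dimnames = list(NULL, AA))
  for (i in 1:4) m[i, substr(seqaa, i, i)] <- 1 - 1e-12
  expect_equal(pseudolikelihood(seqaa, m), 0, tolerance = 1e-10)
  # single position, P(A) = 0.5
  m1 <- uniform_matrix(1); m1[1, ] <- 0.5 / 19.5; m1[1, "A"] <- 0.5
  expect_equal(pseudolikelihood("A", m1), log(0.5), tolerance = 1e-12)
})

test_that("pseudolikelihood is a mean: invariant under row duplication", {
  set.seed(3)
  m <- matrix(rexp(20 * 6), 6, 20, dimnames = list(NULL, AA))
  m <- m / rowSums(m)
  seqaa <- paste(AA[sample(20, 6, replace = TRUE)], collapse = "")
  p1 <- pseudolikelihood(seqaa, m)
  p2 <- pseudolikelihood(paste0(seqaa, seqaa), rbind(m, m))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_lte(p1, 0)
  # loop oracle on a 100-mer
  m2 <- matrix(rexp(20 * 100), 100, 20, dimnames = list(NULL, AA))
  m2 <- m2 / rowSums(m2)
  s2 <- paste(AA[sample(20, 100, replace = TRUE)], collapse = "")
  acc <- 0
  for (i in 1:100) acc <- acc + log(max(m2[i, substr(s2, i, i)], 1e-12))
  expect_equal(pseudolikelihood(s2, m2), acc / 100, tolerance = 1e-12)
  expect_error(pseudolikelihood("AB", uniform_matrix(2)), "alphabet")
})

test_that("likelihood CSVs load, validate and renormalize", {
  dir <- file.path(tempdir(), "plmdir")
  dir.create(dir, showWarnings = FALSE)
  m <- uniform_matrix(3)
  write.csv(m, file.path(dir, "variant_1.csv"), row.names = FALSE)
  bad <- m; bad[1, ] <- bad[1, ] * (1 + 5e-4)  # mild violation: renormalize
  write.csv(bad, file.path(dir, "variant_2.csv"), row.names = FALSE)
  expect_warning(lk <- load_likelihoods(dir), "renormalizing")
  expect_equal(rowSums(lk$variant_2$matrix), rep(1, 3), tolerance = 1e-9)
  worse <- m; worse[2, ] <- worse[2, ] * 1.01
  write.csv(worse, file.path(dir, "variant_3.csv"), row.names = FALSE)
  expect_error(suppressWarnings(load_likelihoods(dir)), "1e-3")
  file.remove(file.path(dir, "variant_3.csv"))
  # long format round-trips to the same matrices
  long <- do.call(rbind, lapply(c("variant_1", "variant_2"), function(id) {
    cbind(data.frame(node_id = id, position = 1:3), as.data.frame(m))
  }))
  lf <- file.path(tempdir(), "plm_long.csv")
  write.csv(long, lf, row.names = FALSE)
  lk2 <- load_likelihoods(lf)
  expect_equal(lk2$variant_1$matrix, lk$variant_1$matrix, tolerance = 1e-12)
})

test_that("stand-in scorer applies additive smoothing exactly", {
  lk <- standin_scorer(c(n1 = "AC"))
  expect_equal(unname(lk$n1$matrix[1, "A"]), 2 / 21)
  expect_equal(unname(lk$n1$matrix[1, "C"]), 1 / 21)
  # 20 sequences, column all A
  aln <- setNames(rep("A", 20), paste0("n", 1:20))
  lk20 <- standin_scorer(aln)
  expect_equal(unname(lk20$n1$matrix[1, "A"]), 21 / 40)
  # rows always sum to 1
  sim_aln <- c(a = "ACDY", b = "ACDW", c = "GCDY")
  lks <- standin_scorer(sim_aln)
  expect_equal(rowSums(lks$a$matrix), rep(1, 4), tolerance = 1e-12)
})

test_that("edge profiles classify every non-gap position exactly once", {
  tr <- chain_tree(c("p", "c"), c(1, 1))
  tr$nodes$sequence_aa <- c(NA, "ACDY", "ACDW")
  lk <- standin_scorer(c(p = "ACDY", c = "ACDW"))
  prof <- edge_substitution_profile(tr, lk, "p", "c")
  expect_equal(prof$summary$n_mutated + prof$summary$n_conserved, 4)
  expect_equal(prof$summary$n_mutated, 1)
  # identical sequences: nothing mutated
  tr2 <- tr; tr2$nodes$sequence_aa <- c(NA, "ACDY", "ACDY")
  prof2 <- edge_substitution_profile(tr2, standin_scorer(
    c(p = "ACDY", c = "ACDY")), "p", "c")
  expect_equal(prof2$summary$n_mutated, 0)
  expect_equal(prof2$summary$n_conserved, 4)
})

test_that("a child residue that is the parent's argmax gets rank 1", {
  tr <- chain_tree(c("p", "c"), c(1, 1))
  tr$nodes$sequence_aa <- c(NA, "AA", "AC")
  m <- uniform_matrix(2)
  m[2, ] <- 0.01; m[2, "C"] <- 1 - 0.19 * 0.01 - 0.01 * 18  # C dominates
  m[2, ] <- m[2, ] / sum(m[2, ])
  lk <- list(p = list(matrix = m), c = list(matrix = uniform_matrix(2)))
  prof <- edge_substitution_profile(tr, lk, "p", "c")
  mut <- prof$positions[prof$positions$class == "mutated", ]
  expect_equal(mut$child_rank_in_parent, 1)
})

test_that("profile values match a per-position loop oracle", {
  sim <- simulate_lineage(simulation_config(seed = 6, generations = 2,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  cl <- sim$clonotype
  tr <- build_lineage(cl, "default")
  aa <- setNames(cl$variants$sequence_aa, cl$variants$variant_id)
  aa <- c(germline = translate_no_stop(cl$germline_nt), vapply(aa, fix_stops,
                                                               character(1)))
  for (i in seq_along(aa)) {
    idx <- match(names(aa)[i], tr$nodes$node_id)
    tr$nodes$sequence_aa[idx] <- aa[[i]]
  }
  lk <- standin_scorer(aa)
  e <- tr$edges[1, ]
  prof <- edge_substitution_profile(tr, lk, e$parent, e$child)
  pseq <- strsplit(aa[[e$parent]], "")[[1]]
  cseq <- strsplit(aa[[e$child]], "")[[1]]
  expect_equal(prof$summary$n_mutated, sum(pseq != cseq))
  pm <- lk[[e$parent]]$matrix
  for (r in sample(nrow(prof$positions), 5)) {
    row <- prof$positions[r, ]
    expect_equal(row$p_parent_child, unname(pm[row$position, row$child_residue]))
  }
})

test_that("likelihood-depth correlations match a rank-based oracle", {
  tr <- chain_tree(paste0("v", 1:6), weights = 1:6)
  d <- node_depths(tr, weighted = TRUE)[paste0("v", 1:6)]
  pll <- c(-1, -1.5, -1.2, -2, -2.5, -3)
  lk <- lapply(pll, function(p) list(pseudolikelihood = p))
  names(lk) <- paste0("v", 1:6)
  out <- likelihood_vs_evolution(tr, lk)
  row <- out[out$tree_id == "tree_1", ]
  # rank oracle
  oracle <- cor(rank(d), rank(pll))
  expect_equal(row$spearman, oracle, tolerance = 1e-12)
  expect_equal(row$n, 6)

  # perfectly linear decline: pearson exactly -1
  lk2 <- lapply(-d, function(p) list(pseudolikelihood = p))
  names(lk2) <- names(d)
  out2 <- likelihood_vs_evolution(tr, lk2)
  expect_equal(out2$pearson[1], -1, tolerance = 1e-12)

  # constant pseudolikelihoods: zero variance, reason reported
  lk3 <- lapply(d, function(p) list(pseudolikelihood = -2))
  names(lk3) <- names(d)
  out3 <- likelihood_vs_evolution(tr, lk3)
  expect_true(is.na(out3$spearman[1]))
  expect_equal(out3$reason[1], "zero variance")

  # fewer than 3 points: omitted, not an error
  tr2 <- chain_tree(c("a", "b"))
  out4 <- likelihood_vs_evolution(tr2, list(a = list(pseudolikelihood = -1),
                                            b = list(pseudolikelihood = -2)))
  expect_equal(out4$reason[1], "fewer than 3 points")
})

test_that("Spearman matches the rank oracle on a simulated 30-node tree", {
  tr <- random_tree(31, 8)
  d <- node_depths(tr, weighted = TRUE)
  ids <- tr$nodes$node_id[tr$nodes$kind == "sampled"]
  pll <- withr::with_seed(9, -d[ids] * 0.1 + rnorm(length(ids), 0, 0.2))
  lk <- lapply(pll, function(p) list(pseudolikelihood = unname(p)))
  names(lk) <- ids
  out <- likelihood_vs_evolution(tr, lk)
  expect_equal(out$spearman[1], cor(rank(d[ids]), rank(pll)),
               tolerance = 1e-12)
})
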