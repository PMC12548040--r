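# rigid motion: rotation about z by `theta` plus translation
rigid <- function(X, theta = pi / 2, shift = c(0, 0, 5)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(X %*% t(R), 2, shift, `+`)
}

test_that("PDB reading extracts CA traces, pLDDT and roles", {
  pdb <- file.path(tempdir(), "mini.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.10           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00 90.10           C",
    "ATOM      3  CA  GLY A   2       2.000   1.000   0.000  1.00 85.00           C",
    "ATOM      4  CA  LYS A   3       3.000   2.000   1.000  1.00 70.20           C",
    "END"), pdb)
  m <- read_pdb(pdb, chain_roles = c(A = "antibody"))
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$aa, c("A", "G", "K"))
  expect_equal(mean(m$atoms$plddt), mean(c(90.1, 85.0, 70.2)))
  expect_equal(unique(m$atoms$role), "antibody")
  expect_equal(m$atoms$x, c(1, 2, 3))
  # no CA atoms -> format error
  pdb2 <- file.path(tempdir(), "noca.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.10           N",
    "END"), pdb2)
  expect_error(read_pdb(pdb2), "no CA")
})

test_that("synthetic structures round-trip through the PDB writer/reader", {
  sim <- simulate_lineage(simulation_config(seed = 2, generations = 2,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  models <- simulate_structures(sim$truth, displacement_per_mutation = 1)
  dir <- file.path(tempdir(), "pdbs")
  dir.create(dir, showWarnings = FALSE)
  id <- names(models)[2]
  write_pdb_ca(models[[id]], file.path(dir, "m.pdb"))
  back <- read_pdb(file.path(dir, "m.pdb"), node_id = id)
  expect_equal(back$atoms$x, models[[id]]$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$plddt, models[[id]]$atoms$plddt, tolerance = 1e-2)
  expect_equal(back$atoms$aa, models[[id]]$atoms$aa)
})

test_that("RMSD vanishes under rigid motions and is symmetric", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(X, X), 0, tolerance = 1e-9)
  expect_equal(superpose_rmsd(X, rigid(X)), 0, tolerance = 1e-6)
  Y <- X + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(superpose_rmsd(X, Y), superpose_rmsd(Y, X),
               tolerance = 1e-9)
  expect_equal(superpose_rmsd(rigid(X, 1, c(3, -2, 1)), Y),
               superpose_rmsd(X, Y), tolerance = 1e-6)
  expect_error(superpose_rmsd(X[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("RMSD agrees with an independent superposition implementation", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(3 * 12), 12, 3)
    Y <- X + matrix(rnorm(3 * 12, sd = 0.5), 12, 3)
    mine <- superpose_rmsd(X, Y)
    fitted <- matrix(suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(Y)),
                     mobile = as.numeric(t(X)))), ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((fitted - Y)^2)))
    expect_equal(mine, oracle, tolerance = 1e-9)
  }
  # 4 points, one displaced: exact agreement with the oracle
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  Y <- X; Y[4, ] <- Y[4, ] + c(0, 0, 2)
  fitted <- matrix(suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Y)),
                   mobile = as.numeric(t(X)))), ncol = 3, byrow = TRUE)
  expect_equal(superpose_rmsd(X, Y), sqrt(mean(rowSums((fitted - Y)^2))),
               tolerance = 1e-9)
})

test_that("hydrophobicity and charge follow the stated conventions", {
  expect_equal(unname(biophysics("A")["hydrophobicity"]), 1.8)
  expect_equal(unname(biophysics("GKDE")["net_charge"]), -1)
  expect_equal(unname(biophysics("KR")["net_charge"]), 2)
  expect_equal(unname(biophysics("KHRH")["net_charge"]), 2)  # His = 0
  expect_error(biophysics(""), "empty")
})

test_that("interface detection matches an all-pairs distance oracle", {
  mk_complex <- function(ab, ag) {
    atoms <- rbind(
      data.frame(chain = "H", resno = seq_len(nrow(ab)), insert = "",
                 resid = "ALA", aa = "A", x = ab[, 1], y = ab[, 2],
                 z = ab[, 3], plddt = 80, role = "antibody"),
      data.frame(chain = "A", resno = seq_len(nrow(ag)), insert = "",
                 resid = "GLY", aa = "G", x = ag[, 1], y = ag[, 2],
                 z = ag[, 3], plddt = 70, role = "antigen"))
    structure(list(node_id = "cx", atoms = atoms),
              class = "structure_model")
  }
  # chains 100 A apart: empty interface
  far <- mk_complex(matrix(0, 4, 3), matrix(100, 4, 3))
  out <- interface_residues(far)
  expect_equal(out$summary$n_antibody, 0)
  # one pair at 4.9 A, everything else far
  ab <- matrix(c(0, 0, 0, 50, 50, 50, 60, 60, 60), 3, 3, byrow = TRUE)
  ag <- matrix(c(4.9, 0, 0, -50, -50, -50), 2, 3, byrow = TRUE)
  near <- mk_complex(ab, ag)
  out2 <- interface_residues(near, cutoff_angstrom = 5)
  expect_equal(out2$summary$n_antibody, 1)
  expect_equal(out2$summary$n_antigen, 1)
  # random complexes against a brute-force double loop
  for (seed in 1:5) {
    set.seed(seed)
    ab <- matrix(rnorm(3 * 8, sd = 4), 8, 3)
    ag <- matrix(rnorm(3 * 6, sd = 4) + 3, 6, 3)
    cx <- mk_complex(ab, ag)
    out3 <- interface_residues(cx, cutoff_angstrom = 5)
    hit_ab <- rep(FALSE, 8); hit_ag <- rep(FALSE, 6)
    for (i in 1:8) for (j in 1:6) {
      if (sqrt(sum((ab[i, ] - ag[j, ])^2)) <= 5) {
        hit_ab[i] <- TRUE; hit_ag[j] <- TRUE
      }
    }
    expect_equal(out3$summary$n_antibody, sum(hit_ab))
    expect_equal(out3$summary$n_antigen, sum(hit_ag))
  }
  expect_error(interface_residues(
    structure(list(node_id = "x",
                   atoms = far$atoms[far$atoms$role == "antibody", ]),
              class = "structure_model")), "antigen")
})

test_that("lineage structure reports track displacement with mutations", {
  sim <- simulate_lineage(simulation_config(seed = 4, generations = 3,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  tr <- build_lineage(sim$clonotype, "default")
  # structures keyed by variant id via the truth map
  vmap <- variant_truth_map(sim)
  models <- simulate_structures(sim$truth, displacement_per_mutation = 1.5)
  structures <- list(germline = models$germline)
  for (v in names(vmap)) structures[[v]] <- models[[vmap[[v]]]]
  rep <- lineage_structure_report(tr, structures)
  expect_equal(rep$nodes$rmsd_to_germline[rep$nodes$node_id == "germline"], 0)
  expect_true(all(rep$nodes$rmsd_to_germline >= 0))
  expect_setequal(rep$skipped,
                  setdiff(tr$nodes$node_id, names(structures)))
  # displacement grows with inherited mutations: positive rank correlation
  expect_true(is.na(rep$correlations$node_rmsd_vs_depth) ||
              rep$correlations$node_rmsd_vs_depth > 0)

  # zero displacement: all structures identical, zero-variance guard
  models0 <- simulate_structures(sim$truth, displacement_per_mutation = 0)
  structures0 <- list(germline = models0$germline)
  for (v in names(vmap)) structures0[[v]] <- models0[[vmap[[v]]]]
  rep0 <- lineage_structure_report(tr, structures0)
  expect_equal(max(rep0$nodes$rmsd_to_germline), 0, tolerance = 1e-9)
  expect_true(is.na(rep0$correlations$edge_rmsd_vs_weight))
})

test_that("single-mutation displacement obeys the d/sqrt(N) bound", {
  sim <- simulate_lineage(simulation_config(seed = 2, generations = 1,
                                            branching_rate = 3,
                                            sampling_fraction = 1))
  d <- 2
  models <- simulate_structures(sim$truth, displacement_per_mutation = d)
  obs <- sim$truth$nodes[sim$truth$nodes$observed, ]
  for (i in seq_len(nrow(obs))) {
    n_codon <- length(unique((sim$truth$mutations[[obs$node_id[i]]] - 1)
                             %/% 3))
    r <- superpose_rmsd(models$germline, models[[obs$node_id[i]]])
    N <- nrow(models$germline$atoms)
    # superposed RMSD can never exceed the pre-fit displacement RMSD
    expect_lte(r, sqrt(n_codon * d^2 / N) + 1e-9)
  }
})

test_that("structure simulation is reproducible under a fixed seed", {
  sim <- simulate_lineage(simulation_config(seed = 3, generations = 2,
                                            branching_rate = 2,
                                            sampling_fraction = 1))
  a <- simulate_structures(sim$truth, 1)
  b <- simulate_structures(sim$truth, 1)
  expect_identical(a, b)
})
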