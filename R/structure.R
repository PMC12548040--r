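# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9,
                   A = 1.8, G = -0.4, T = -0.7, S = -0.8, W = -0.9,
                   Y = -1.3, P = -1.6, H = -3.2, E = -3.5, Q = -3.5,
                   D = -3.5, N = -3.5, K = -3.9, R = -4.5)

#' Read a predicted structure from a PDB file
#'
#' Extracts the alpha-carbon trace: one row per residue with chain,
#' residue number/insertion code, residue name, one-letter code,
#' coordinates, and the temperature-factor column as the per-residue
#' pLDDT confidence (the convention of structure predictors). Alternate
#' locations are resolved by highest occupancy, then file order.
#'
#' @param path PDB file with ATOM records.
#' @param chain_roles named character vector chain id -> role
#'   (`"antibody"`, `"antigen"`); unlisted chains get `"unassigned"`.
#' @param node_id identifier stored on the model (default: file base
#'   name).
#' @return object of class `structure_model`: list with `node_id` and
#'   `atoms` (data frame, one CA per residue in file order).
#' @export
read_pdb <- function(path, chain_roles = NULL, node_id = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("no CA ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  key <- paste(at$chain, at$resno, at$insert)
  at$o[is.na(at$o)] <- 1
  # alternate locations: highest occupancy, then first in file order
  pick <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(i) i[order(-at$o[i])][1]),
                 use.names = FALSE)
  at <- at[sort(pick), , drop = FALSE]
  roles <- rep("unassigned", nrow(at))
  if (!is.null(chain_roles)) {
    hit <- at$chain %in% names(chain_roles)
    roles[hit] <- unname(chain_roles[at$chain[hit]])
  }
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid,
    aa = bio3d::aa321(at$resid),
    x = at$x, y = at$y, z = at$z,
    plddt = at$b,
    role = roles,
    stringsAsFactors = FALSE)
  if (is.null(node_id)) node_id <- sub("\\.pdb$", "", basename(path))
  structure(list(node_id = node_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> '%s': %d residues, chains %s\n",
              x$node_id, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Write an alpha-carbon trace to a PDB file
#'
#' Companion writer to [read_pdb()] (used by the structure simulator):
#' one CA ATOM record per residue, pLDDT in the temperature-factor
#' column.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = rep("CA", nrow(a)), b = a$plddt,
                   o = rep(1, nrow(a)))
  invisible(path)
}

# CA coordinate matrix (N x 3) of a model, optionally one chain
ca_coords <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Optimal-superposition RMSD between two structures
#'
#' Least-squares rigid-body superposition (centroid shift plus the
#' optimal rotation from the Kabsch/SVD construction, reflections
#' disallowed) followed by the root-mean-square deviation over the mapped
#' alpha-carbons. With no `residue_map`, residues are paired positionally
#' 1:1 over the shared length of each common chain. RMSD is symmetric
#' and invariant under rigid motions of either input.
#'
#' @param model_a,model_b `structure_model` objects, or plain `N x 3`
#'   coordinate matrices.
#' @param residue_map optional two-column integer matrix of paired atom
#'   row indices (into `model_a$atoms` and `model_b$atoms`).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(model_a, model_b, residue_map = NULL) {
  if (is.matrix(model_a) && is.matrix(model_b)) {
    X <- model_a; Y <- model_b
  } else if (!is.null(residue_map)) {
    X <- ca_coords(model_a)[residue_map[, 1], , drop = FALSE]
    Y <- ca_coords(model_b)[residue_map[, 2], , drop = FALSE]
  } else {
    common <- intersect(unique(model_a$atoms$chain),
                        unique(model_b$atoms$chain))
    if (!length(common)) stop("models share no chain ids")
    X <- NULL; Y <- NULL
    for (ch in common) {
      xa <- ca_coords(model_a, ch); xb <- ca_coords(model_b, ch)
      n <- min(nrow(xa), nrow(xb))
      X <- rbind(X, xa[seq_len(n), , drop = FALSE])
      Y <- rbind(Y, xb[seq_len(n), , drop = FALSE])
    }
  }
  if (nrow(X) != nrow(Y)) stop("coordinate sets must have equal size")
  if (nrow(X) < 3) stop("superposition needs at least 3 paired atoms")
  kabsch_rmsd(X, Y)
}

# RMSD after optimal proper rotation of centered X onto centered Y
kabsch_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  A <- t(Xc) %*% Yc
  sv <- svd(A)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

#' Mean hydrophobicity and net charge of a protein sequence
#'
#' Mean Kyte-Doolittle hydropathy over standard residues (`X` and gaps
#' excluded from the average) and the integer net charge at neutral pH:
#' `(#K + #R) - (#D + #E)`, histidine counted as 0.
#'
#' @param sequence_aa amino-acid string.
#' @return named numeric vector `c(hydrophobicity, net_charge)`.
#' @export
biophysics <- function(sequence_aa) {
  res <- strsplit(sequence_aa, "")[[1]]
  if (!length(res)) stop("empty sequence")
  h <- KD_HYDROPATHY[res]
  c(hydrophobicity = mean(h, na.rm = TRUE),
    net_charge = sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")))
}

#' Antibody-antigen interface residues of a complex
#'
#' Finds antibody residues whose alpha-carbon lies within
#' `cutoff_angstrom` of any antigen alpha-carbon, and vice versa, and
#' summarises the interface (size per side, mean interface pLDDT, mean
#' hydrophobicity, net charge over interface residues).
#'
#' @param complex_model a `structure_model` with at least one chain
#'   assigned role `"antibody"` and one `"antigen"`.
#' @param cutoff_angstrom CA-CA contact cutoff (default 5.0 A, a common
#'   coarse contact definition).
#' @return list with `residues` (data frame of interface residues, both
#'   sides) and `summary`.
#' @export
interface_residues <- function(complex_model, cutoff_angstrom = 5.0) {
  a <- complex_model$atoms
  ab <- which(a$role == "antibody")
  ag <- which(a$role == "antigen")
  if (!length(ab)) stop("no chain with role 'antibody'")
  if (!length(ag)) stop("no chain with role 'antigen'")
  X <- as.matrix(a[ab, c("x", "y", "z")])
  Y <- as.matrix(a[ag, c("x", "y", "z")])
  D2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
  hit <- D2 <= cutoff_angstrom^2 + 1e-12
  iface <- rbind(
    a[ab[rowSums(hit) > 0], , drop = FALSE],
    a[ag[colSums(hit) > 0], , drop = FALSE])
  res_sum <- data.frame(
    n_antibody = sum(rowSums(hit) > 0),
    n_antigen = sum(colSums(hit) > 0),
    mean_plddt = if (nrow(iface)) mean(iface$plddt) else NA_real_,
    hydrophobicity = if (nrow(iface))
      unname(biophysics(paste(iface$aa, collapse = ""))["hydrophobicity"])
      else NA_real_,
    net_charge = if (nrow(iface))
      unname(biophysics(paste(iface$aa, collapse = ""))["net_charge"])
      else NA_real_,
    stringsAsFactors = FALSE)
  list(residues = iface, summary = res_sum)
}

#' Structural evolution report over a lineage tree
#'
#' Per node: superposition RMSD to the germline structure, mean pLDDT,
#' mean hydrophobicity and net charge; per edge with structures at both
#' ends: pairwise RMSD and the edge weight (mutation count); per tree:
#' Spearman correlation of edge RMSD against edge weight and of node
#' RMSD-to-germline against weighted germline distance. Nodes without a
#' structure are skipped and listed.
#'
#' @param tree a `lineage_tree`.
#' @param structures named list (by node id) of `structure_model`s; must
#'   include the germline (root) structure.
#' @return list with `nodes`, `edges`, `correlations` and `skipped`.
#' @export
lineage_structure_report <- function(tree, structures) {
  root <- tree$root_id
  if (is.null(structures[[root]])) stop("missing germline structure")
  have <- intersect(tree$nodes$node_id, names(structures))
  skipped <- setdiff(tree$nodes$node_id, have)
  dw <- node_depths(tree, weighted = TRUE)
  nodes <- do.call(rbind, lapply(have, function(id) {
    m <- structures[[id]]
    seq_aa <- paste(m$atoms$aa, collapse = "")
    bp <- biophysics(seq_aa)
    data.frame(node_id = id,
               rmsd_to_germline = if (id == root) 0 else
                 superpose_rmsd(structures[[root]], m),
               mean_plddt = mean(m$atoms$plddt),
               hydrophobicity = unname(bp["hydrophobicity"]),
               net_charge = unname(bp["net_charge"]),
               depth_weighted = unname(dw[id]),
               stringsAsFactors = FALSE)
  }))
  ed <- tree$edges[tree$edges$parent %in% have & tree$edges$child %in% have, ,
                   drop = FALSE]
  edges <- if (nrow(ed)) do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
    data.frame(parent = ed$parent[i], child = ed$child[i],
               weight = ed$weight[i],
               rmsd = superpose_rmsd(structures[[ed$parent[i]]],
                                     structures[[ed$child[i]]]),
               stringsAsFactors = FALSE)
  })) else data.frame(parent = character(), child = character(),
                      weight = numeric(), rmsd = numeric())
  safe_spear <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  nr <- nodes[nodes$node_id != root, , drop = FALSE]
  correlations <- data.frame(
    edge_rmsd_vs_weight = safe_spear(edges$weight, edges$rmsd),
    node_rmsd_vs_depth = safe_spear(nr$depth_weighted, nr$rmsd_to_germline),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, correlations = correlations,
       skipped = skipped)
}
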