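# --- substitution models ----------------------------------------------------

# transition probability matrix (order A, C, G, T) for branch length d
# (expected substitutions per site). K80 with kappa = 1 reduces to JC69.
transition_matrix <- function(d, model = "JC69", kappa = 2) {
  if (model == "JC69") kappa <- 1
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition (A<->G, C<->T)
  tv <- 0.25 - 0.25 * e1              # each transversion
  P <- matrix(tv, 4, 4)
  diag(P) <- same
  P[1, 3] <- P[3, 1] <- ts
  P[2, 4] <- P[4, 2] <- ts
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

# sites x 4 indicator likelihood for a sequence (N/gap -> all ones)
leaf_likelihood <- function(seq) {
  b <- NT_BITS[strsplit(toupper(seq), "")[[1]]]
  m <- cbind(A = bitwAnd(b, 1L) > 0, C = bitwAnd(b, 2L) > 0,
             G = bitwAnd(b, 4L) > 0, T = bitwAnd(b, 8L) > 0)
  storage.mode(m) <- "double"
  m
}

# log-likelihood of an alignment on a germline-rooted lineage tree by
# Felsenstein pruning; edge weights are branch lengths in expected
# substitutions per site; base frequencies fixed at 1/4.
tree_log_likelihood <- function(tree, alignment, model = "JC69", kappa = 2) {
  ids <- lt_preorder(tree)
  kids <- split(tree$edges$child, tree$edges$parent)
  wts <- stats::setNames(tree$edges$weight, tree$edges$child)
  S <- nchar(alignment[[1]])
  cond <- vector("list", length(ids)); names(cond) <- ids
  for (id in rev(ids)) {
    L <- if (id %in% names(alignment)) leaf_likelihood(alignment[[id]])
         else matrix(1, S, 4)
    for (ch in kids[[id]]) {
      P <- transition_matrix(wts[[ch]], model, kappa)
      L <- L * (cond[[ch]] %*% t(P))
    }
    cond[[id]] <- L
  }
  site <- rowSums(0.25 * cond[[tree$root_id]])
  sum(log(site))
}

# one coordinate-descent sweep over branch lengths; returns updated tree
optimize_branches <- function(tree, alignment, model, kappa,
                              tol = 1e-6, max_sweeps = 10) {
  ll <- tree_log_likelihood(tree, alignment, model, kappa)
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_len(nrow(tree$edges))) {
      f <- function(t) {
        tree$edges$weight[e] <- t
        -tree_log_likelihood(tree, alignment, model, kappa)
      }
      opt <- stats::optimize(f, interval = c(0, 10), tol = tol)
      # optimize() never evaluates the boundary; keep 0 when it is better
      cand <- if (f(0) <= opt$objective) 0 else opt$minimum
      tree$edges$weight[e] <- cand
    }
    ll_new <- tree_log_likelihood(tree, alignment, model, kappa)
    if (ll_new - ll < 1e-7) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(tree = tree, loglik = ll)
}

#' Build a maximum likelihood lineage tree
#'
#' Maximises the likelihood of an equal-length nucleotide alignment under
#' the JC69 or K80 substitution model (base frequencies 1/4, no rate
#' heterogeneity). The likelihood is computed by pruning over the
#' germline-rooted tree; branch lengths are optimised one at a time by
#' bounded one-dimensional search (tolerance `1e-6`), and the topology by
#' NNI hill climbing from a neighbor-joining start tree. Accepted NNI
#' moves never decrease the log-likelihood.
#'
#' @inheritParams build_parsimony
#' @param model `"JC69"` or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80 (default 2;
#'   `kappa = 1` reproduces JC69).
#' @param search `"nni"` (default) or `"none"` (optimise branch lengths on
#'   the start topology only).
#' @return list with elements `tree` (branch lengths in expected
#'   substitutions per site) and `loglik`.
#' @export
build_ml <- function(alignment, germline_label = "germline",
                     model = c("JC69", "K80"), kappa = 2,
                     search = c("nni", "none"), clonotype = NULL) {
  model <- match.arg(model)
  search <- match.arg(search)
  check_alignment(alignment, germline_label)
  n <- length(alignment)
  fit_topology <- function(phy) {
    lt <- lineage_from_topology(phy, germline_label, alignment,
                                info = list(method = "ml", model = model))
    lt$edges$weight <- pmax(lt$edges$weight / max(1, nchar(alignment[[1]])),
                            0.01)  # crude initial lengths
    optimize_branches(lt, alignment, model, kappa)
  }
  phy <- start_topology(alignment, germline_label)
  best_fit <- fit_topology(phy)
  if (search == "nni" && n >= 4) {
    best_phy <- phy
    repeat {
      nb <- phangorn::nni(best_phy)
      fits <- lapply(nb, fit_topology)
      lls <- vapply(fits, `[[`, numeric(1), "loglik")
      if (max(lls) > best_fit$loglik + 1e-8) {
        best_fit <- fits[[which.max(lls)]]
        best_phy <- nb[[which.max(lls)]]
      } else break
    }
  }
  tree <- apply_clonotype_counts(best_fit$tree, clonotype)
  list(tree = tree, loglik = best_fit$loglik)
}

#' Closed-form JC69 distance between two sequences
#'
#' The maximum likelihood branch length joining two sequences differing at
#' a fraction `p` of sites under JC69: `-(3/4) ln(1 - 4p/3)`.
#'
#' @param p proportion of differing sites (`p < 3/4`).
#' @return distance in expected substitutions per site.
#' @export
jc69_distance <- function(p) {
  if (any(p >= 0.75)) stop("JC69 distance undefined for p >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' Unified tree construction front end
#'
#' Dispatches to the construction algorithms from a single configuration,
#' mirroring the package's pipeline interface.
#'
#' @param clonotype a `clonotype`.
#' @param method `"default"`, `"mst"`, `"nj"`, `"mp"` or `"ml"`.
#' @param metric distance metric for the distance-based methods.
#' @param ... passed to the specific builder (e.g. `tie_break`, `seed`,
#'   `model`, `search`).
#' @return a `lineage_tree` (for `"mp"`/`"ml"` the tree component of the
#'   fit, with the score/log-likelihood stored in `tree$info`).
#' @export
build_lineage <- function(clonotype,
                          method = c("default", "mst", "nj", "mp", "ml"),
                          metric = c("hamming", "levenshtein"), ...) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (method %in% c("default", "mst", "nj")) {
    D <- compute_distances(clonotype, metric)
    return(switch(method,
      default = build_default(D, clonotype, ...),
      mst = build_mst(D, clonotype),
      nj = build_nj(D, clonotype)))
  }
  aln <- c(germline = clonotype$germline_nt,
           stats::setNames(clonotype$variants$sequence_nt,
                           clonotype$variants$variant_id))
  if (method == "mp") {
    fit <- build_parsimony(aln, "germline", clonotype = clonotype, ...)
    fit$tree$info$parsimony_score <- fit$score
    return(fit$tree)
  }
  fit <- build_ml(aln, "germline", clonotype = clonotype, ...)
  fit$tree$info$loglik <- fit$loglik
  fit$tree
}
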