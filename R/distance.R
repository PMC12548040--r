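#' Pairwise sequence distances for a clonotype
#'
#' Builds the symmetric distance matrix over the germline plus all variants
#' that the distance-based tree builders consume. The germline is always
#' the first row/column, labelled `"germline"`.
#'
#' `"hamming"` requires equal-length (pre-aligned) sequences and counts
#' mismatching positions; by default the ambiguity code `N` matches any
#' base (contributing 0), so sequencing uncertainty does not inflate
#' distances. `"levenshtein"` is the standard edit distance and accepts
#' sequences of any length.
#'
#' @param clonotype a `clonotype`, or a named character vector of sequences
#'   whose first element is the germline.
#' @param metric `"hamming"` or `"levenshtein"`.
#' @param n_matches_any should `N` match every base under hamming
#'   (default `TRUE`)?
#' @return a symmetric numeric matrix with zero diagonal; labels are
#'   `"germline"` followed by variant ids.
#' @export
compute_distances <- function(clonotype,
                              metric = c("hamming", "levenshtein"),
                              n_matches_any = TRUE) {
  metric <- match.arg(metric)
  if (inherits(clonotype, "clonotype")) {
    seqs <- c(germline = clonotype$germline_nt,
              stats::setNames(clonotype$variants$sequence_nt,
                              clonotype$variants$variant_id))
  } else {
    seqs <- clonotype
    if (is.null(names(seqs))) stop("sequences must be named")
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (metric == "levenshtein") {
    D[] <- utils::adist(seqs)
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("hamming distance requires equal-length (aligned) sequences")
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- hamming_chars(chars[[i]], chars[[j]],
                                          n_matches_any)
    }
  }
  storage.mode(D) <- "double"
  D
}

# hamming distance on split character vectors
hamming_chars <- function(a, b, n_matches_any = TRUE) {
  diff <- a != b
  if (n_matches_any) diff <- diff & a != "N" & b != "N"
  sum(diff)
}

#' Hamming distance between two sequences
#'
#' @param a,b equal-length character strings.
#' @param n_matches_any should `N` match any base (default `TRUE`)?
#' @return integer distance.
#' @export
hamming_distance <- function(a, b, n_matches_any = TRUE) {
  if (nchar(a) != nchar(b))
    stop("hamming distance requires equal-length sequences")
  hamming_chars(strsplit(a, "")[[1]], strsplit(b, "")[[1]], n_matches_any)
}

#' Levenshtein (edit) distance between two sequences
#' @param a,b character strings.
#' @return integer distance.
#' @export
levenshtein_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}
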