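#' Assemble clonotypes from sequence records
#'
#' A clonotype collects the B cells descending from one V(D)J recombination
#' event: a shared germline reference plus the set of unique sequence
#' variants observed across cells. Two grouping strategies are supported:
#'
#' * `"clone_id"` — trust a precomputed `clone_id` column; records with an
#'   empty `clone_id` land in the unassigned bin.
#' * `"vjl"` — records share a clonotype when they have identical `v_call`,
#'   `j_call` and junction length, and their nucleotide junctions agree at
#'   a fraction of positions of at least `junction_threshold`
#'   (alignment-free per-position identity; single-linkage within each
#'   V/J/length group).
#'
#' Within a clonotype, records with identical `sequence_nt` collapse into
#' one variant. A variant's `cell_count` is the number of distinct cells
#' (single-cell records) plus the summed `duplicate_count` of bulk records.
#' Per-variant metadata fractions (isotype by default) are computed over
#' the member cells.
#'
#' @param records data frame of sequence records ([read_airr()]).
#' @param strategy `"clone_id"` or `"vjl"`.
#' @param junction_threshold junction identity threshold for `"vjl"`
#'   (default 0.85, a common choice in repertoire analysis).
#' @param label_columns record columns to summarise into per-variant
#'   fractions (default `"c_call"`).
#' @param require_germline if `TRUE`, records with an empty
#'   `germline_alignment_nt` go to the unassigned bin.
#' @return list with elements `clonotypes` (list of `clonotype` objects)
#'   and `unassigned` (data frame of records not assigned to any clonotype).
#' @export
group_clonotypes <- function(records, strategy = c("clone_id", "vjl"),
                             junction_threshold = 0.85,
                             label_columns = "c_call",
                             require_germline = FALSE) {
  strategy <- match.arg(strategy)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  unassigned <- records[0, , drop = FALSE]
  if (require_germline) {
    miss <- records$germline_alignment_nt == ""
    unassigned <- rbind(unassigned, records[miss, , drop = FALSE])
    records <- records[!miss, , drop = FALSE]
  }
  if (strategy == "clone_id") {
    blank <- records$clone_id == ""
    unassigned <- rbind(unassigned, records[blank, , drop = FALSE])
    records <- records[!blank, , drop = FALSE]
    groups <- split(seq_len(nrow(records)), records$clone_id)
  } else {
    key <- paste(records$v_call, records$j_call, nchar(records$junction_nt),
                 sep = "|")
    groups <- list()
    for (idx in split(seq_len(nrow(records)), key)) {
      groups <- c(groups, split_by_junction_identity(
        records$junction_nt[idx], idx, junction_threshold))
    }
    names(groups) <- paste0("clonotype_", seq_along(groups))
  }
  cl <- lapply(names(groups), function(gid) {
    make_clonotype(gid, records[groups[[gid]], , drop = FALSE],
                   label_columns)
  })
  names(cl) <- vapply(cl, `[[`, character(1), "clonotype_id")
  list(clonotypes = cl, unassigned = unassigned)
}

# single-linkage clusters of equal-length junctions at identity >= t
split_by_junction_identity <- function(junctions, idx, t) {
  n <- length(junctions)
  if (n == 1) return(list(idx))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(junctions[i], "")[[1]]
    b <- strsplit(junctions[j], "")[[1]]
    if (length(a) == length(b) && length(a) > 0 &&
        mean(a == b) >= t) {
      comp[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(seq_len(n), roots), function(m) idx[m]))
}

# collapse a set of records into a clonotype object
make_clonotype <- function(clonotype_id, recs, label_columns = "c_call",
                           chain_scope = "heavy") {
  germ <- recs$germline_alignment_nt[recs$germline_alignment_nt != ""]
  germline_nt <- if (length(germ)) names(sort(table(germ),
                                              decreasing = TRUE))[1] else ""
  useq <- unique(recs$sequence_nt)  # first-appearance order
  variants <- data.frame(
    variant_id = paste0("variant_", seq_along(useq)),
    sequence_nt = useq,
    sequence_aa = vapply(useq, translate_nt, character(1)),
    cell_count = NA_real_,
    stringsAsFactors = FALSE)
  cell_ids <- vector("list", length(useq))
  fractions <- vector("list", length(useq))
  for (i in seq_along(useq)) {
    m <- recs[recs$sequence_nt == useq[i], , drop = FALSE]
    sc <- m[m$source == "single_cell", , drop = FALSE]
    bk <- m[m$source == "bulk", , drop = FALSE]
    cells <- unique(sc$cell_id)
    variants$cell_count[i] <- length(cells) + sum(bk$duplicate_count)
    cell_ids[[i]] <- cells
    fr <- list()
    for (lab in label_columns) {
      v <- m[[lab]][!duplicated(m$cell_id) | m$source == "bulk"]
      v <- v[v != ""]
      if (length(v)) fr[[lab]] <- table(v) / length(v)
    }
    fractions[[i]] <- lapply(fr, function(x) {
      stats::setNames(as.numeric(x), names(x))
    })
  }
  names(cell_ids) <- variants$variant_id
  names(fractions) <- variants$variant_id
  structure(list(clonotype_id = clonotype_id, germline_nt = germline_nt,
                 variants = variants, cell_ids = cell_ids,
                 fractions = fractions, chain_scope = chain_scope,
                 records = recs),
            class = "clonotype")
}

#' @export
print.clonotype <- function(x, ...) {
  cat(sprintf("<clonotype> '%s': %d variant(s), %g cell(s), germline %s nt\n",
              x$clonotype_id, nrow(x$variants), sum(x$variants$cell_count),
              nchar(x$germline_nt)))
  invisible(x)
}

#' Restrict a clonotype to sequence regions
#'
#' Replaces every variant sequence (and the germline) by the concatenation
#' of the requested regions. Coordinates are 0-based, half-open. Variants
#' that become identical after restriction are merged, with cell counts
#' summed and cell ids pooled. The named region `"junction"` resolves to
#' the junction interval annotated on the clonotype (e.g. by the bundled
#' simulator) and corresponds to a CDR3-only analysis.
#'
#' @param clonotype a `clonotype`.
#' @param region_spec either a list of `c(start, end)` integer pairs
#'   (0-based, half-open) or the string `"junction"`.
#' @return a restricted `clonotype`.
#' @export
restrict_region <- function(clonotype, region_spec) {
  if (identical(region_spec, "junction")) {
    iv <- clonotype$junction_interval
    if (is.null(iv)) stop("clonotype carries no junction interval annotation")
    region_spec <- list(iv)
  }
  len <- nchar(clonotype$germline_nt)
  for (iv in region_spec) {
    if (iv[1] < 0 || iv[2] > len || iv[1] > iv[2])
      stop("region interval [", iv[1], ", ", iv[2],
           ") out of bounds for length ", len)
  }
  cut <- function(s) {
    paste(vapply(region_spec,
                 function(iv) substr(s, iv[1] + 1L, iv[2]), character(1)),
          collapse = "")
  }
  out <- clonotype
  out$germline_nt <- cut(clonotype$germline_nt)
  newseq <- vapply(clonotype$variants$sequence_nt, cut, character(1),
                   USE.NAMES = FALSE)
  # merge variants that collapsed onto the same restricted sequence
  grp <- match(newseq, unique(newseq))
  useq <- unique(newseq)
  variants <- data.frame(
    variant_id = paste0("variant_", seq_along(useq)),
    sequence_nt = useq,
    sequence_aa = vapply(useq, translate_nt, character(1)),
    cell_count = as.numeric(tapply(clonotype$variants$cell_count, grp, sum)),
    stringsAsFactors = FALSE)
  cell_ids <- lapply(seq_along(useq), function(i) {
    unique(unlist(clonotype$cell_ids[grp == i], use.names = FALSE))
  })
  names(cell_ids) <- variants$variant_id
  out$variants <- variants
  out$cell_ids <- cell_ids
  out$fractions <- stats::setNames(vector("list", length(useq)),
                                   variants$variant_id)
  out$chain_scope <- "region-restricted"
  out$junction_interval <- NULL
  out
}

# translate a nucleotide string; NA when length is not a codon multiple
translate_nt <- function(s) {
  if (is.na(s) || s == "" || nchar(s) %% 3 != 0) return(NA_character_)
  paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = "")
}
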