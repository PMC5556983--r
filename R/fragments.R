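#' Pearson correlation of two expression profiles
#'
#' Correlation of log2(FPKM + 1)-transformed abundance profiles over all
#' twelve time points; the transform keeps every time point usable (no NA
#' holes from the fold-change floor) while working on the log scale on which
#' regulation patterns are compared.
#'
#' @param x,y Numeric abundance profiles of equal length (FPKM).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
profile_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  lx <- log2(x + 1); ly <- log2(y + 1)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0)
    stop("constant profile: correlation undefined")
  stats::cor(lx, ly)
}

#' Scaffold-margin test for putative gene fragments
#'
#' A gene counts as putatively fragmented when it lies within `margin`
#' nucleotides of a scaffold end (boundary inclusive): fragments of one true
#' gene split across an assembly gap sit at scaffold margins.
#'
#' @param rec One gene-model row (`start`, `end`, `scaffold_length`), or a
#'   gene-model `data.frame` (vectorized).
#' @param margin Margin distance in nt.
#' @return Logical.
#' @export
is_margin_gene <- function(rec, margin = 500) {
  pmin(rec$start - 1, rec$scaffold_length - rec$end) <= margin
}

#' Complementary-truncation domain compatibility
#'
#' Two candidate fragments are domain-compatible when they share a domain id
#' and carry complementary truncations — one hit truncated at the C-terminus
#' (the 5' fragment) and the other at the N-terminus (the 3' fragment).
#'
#' @param hits_a,hits_b Domain-hit `data.frame`s (`domain_id`, `truncation`)
#'   for the two loci.
#' @return Logical.
#' @export
domains_compatible <- function(hits_a, hits_b) {
  if (is.null(hits_a) || is.null(hits_b) || !nrow(hits_a) || !nrow(hits_b))
    return(FALSE)
  shared <- intersect(hits_a$domain_id, hits_b$domain_id)
  for (d in shared) {
    ta <- hits_a$truncation[hits_a$domain_id == d]
    tb <- hits_b$truncation[hits_b$domain_id == d]
    if (("C" %in% ta && "N" %in% tb) || ("N" %in% ta && "C" %in% tb))
      return(TRUE)
  }
  FALSE
}

#' Detect fragment pairs in a fragmented assembly
#'
#' Three-step detection of gene-model pairs that are halves of one true gene:
#' (1) highly correlated expression profiles (Pearson r of log2(FPKM+1)
#' profiles strictly above `r_threshold`), (2) both genes within `margin` nt
#' of a scaffold end, (3) complementary C-/N-terminally truncated hits to a
#' shared domain. Candidates are matched one-to-one greedily by descending
#' correlation (ties by lexicographic id pair). Per pair, the retained member
#' is the 5' fragment: the one carrying the start codon; if that does not
#' decide, the one whose shared-domain hit is N-terminally intact (truncation
#' `C`); if still tied, the lexicographically smaller id.
#'
#' @param mat FPKM time-course matrix.
#' @param models Gene-model `data.frame` (see [read_gene_models()]).
#' @param annotations Annotation `data.frame` (see [read_annotations()]).
#' @param r_threshold Correlation threshold (exclusive).
#' @param margin Scaffold-margin distance in nt.
#' @param candidates Optional character vector restricting the search to a
#'   candidate locus list (e.g. one enzymatic step's forward hits).
#' @return Object of class `merge_map`: `data.frame` with columns `locus_a`,
#'   `locus_b`, `retained`, `dropped`, `r`.
#' @export
detect_fragment_pairs <- function(mat, models, annotations,
                                  r_threshold = 0.9, margin = 500,
                                  candidates = NULL) {
  mat <- validate_tc_matrix(mat)
  missing <- setdiff(rownames(mat), models$locus_id)
  if (is.null(candidates) && length(missing))
    stop("gene models missing for matrix loci: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  ids <- intersect(rownames(mat), models$locus_id)
  if (!is.null(candidates)) ids <- intersect(ids, candidates)
  models <- models[match(ids, models$locus_id), , drop = FALSE]
  ids <- ids[is_margin_gene(models, margin)]
  hits <- annotation_domain_hits(annotations)
  ids <- ids[ids %in% names(hits)]
  ids <- sort(ids)

  cand <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        if (!domains_compatible(hits[[a]], hits[[b]])) next
        r <- tryCatch(profile_correlation(mat[a, ], mat[b, ]),
                      error = function(e) NA_real_)
        if (is.na(r)) next  # constant profile: candidate skipped
        if (r > r_threshold)
          cand[[length(cand) + 1L]] <- list(a = a, b = b, r = r)
      }
    }
  }

  pairs <- data.frame(locus_a = character(0), locus_b = character(0),
                      retained = character(0), dropped = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  if (length(cand)) {
    a <- vapply(cand, `[[`, "", "a")
    b <- vapply(cand, `[[`, "", "b")
    r <- vapply(cand, `[[`, 0, "r")
    ord <- order(-r, a, b)
    used <- character(0)
    starts <- annotations$has_start_codon[!duplicated(annotations$locus_id)]
    names(starts) <- annotations$locus_id[!duplicated(annotations$locus_id)]
    for (k in ord) {
      if (a[k] %in% used || b[k] %in% used) next
      used <- c(used, a[k], b[k])
      keep <- retained_member(a[k], b[k], starts, hits)
      pairs <- rbind(pairs, data.frame(
        locus_a = a[k], locus_b = b[k], retained = keep,
        dropped = setdiff(c(a[k], b[k]), keep), r = r[k],
        stringsAsFactors = FALSE))
    }
    pairs <- pairs[order(pairs$locus_a), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(pairs, class = c("merge_map", "data.frame"))
}

# 5'-member retention rule: start codon, else N-terminally intact shared
# domain (truncation C), else lexicographic
retained_member <- function(a, b, starts, hits) {
  sa <- isTRUE(starts[[a]]); sb <- isTRUE(starts[[b]])
  if (sa && !sb) return(a)
  if (sb && !sa) return(b)
  shared <- intersect(hits[[a]]$domain_id, hits[[b]]$domain_id)
  ca <- any(hits[[a]]$truncation[hits[[a]]$domain_id %in% shared] == "C")
  cb <- any(hits[[b]]$truncation[hits[[b]]$domain_id %in% shared] == "C")
  if (ca && !cb) return(a)
  if (cb && !ca) return(b)
  min(a, b)
}

#' @export
print.merge_map <- function(x, ...) {
  cat(sprintf("Fragment merge map: %d pair(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Collapse fragment pairs in an expression matrix
#'
#' Removes the dropped (3') member of every detected fragment pair, keeping
#' the retained 5' member's row unchanged.
#'
#' @param mat FPKM time-course matrix.
#' @param merge_map A `merge_map` from [detect_fragment_pairs()].
#' @return The matrix with dropped rows removed.
#' @export
collapse_fragments <- function(mat, merge_map) {
  mat <- validate_tc_matrix(mat)
  if (!nrow(merge_map)) return(mat)
  all_ids <- c(merge_map$locus_a, merge_map$locus_b)
  absent <- setdiff(all_ids, rownames(mat))
  if (length(absent))
    stop("merge map references loci absent from the matrix: ",
         paste(absent, collapse = ", "))
  mat[setdiff(rownames(mat), merge_map$dropped), , drop = FALSE]
}
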