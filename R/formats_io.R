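#' Read a time-course FPKM expression matrix from TSV
#'
#' The file is tab-separated with a header row; the first column holds locus
#' ids, the remaining columns the twelve canonical time points (any order on
#' disk; columns are normalized to canonical order). Values must be dense and
#' non-negative.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, loci x 12 time points, rownames = locus ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a locus-id column plus time points")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_tc_matrix(m)
}

#' Write a time-course expression matrix to TSV
#'
#' @param mat Loci x time-points numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  mat <- validate_tc_matrix(mat)
  df <- data.frame(locus_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` features and the `##sequence-region` pragmas (scaffold
#' lengths, needed for the scaffold-margin rule). Coordinates are 1-based
#' inclusive per GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `locus_id`, `scaffold_id`, `start`,
#'   `end`, `strand`, `scaffold_length`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  # rtracklayer does not surface ##sequence-region pragmas; parse them here
  header <- grep("^##sequence-region", readLines(path, warn = FALSE),
                 value = TRUE)
  if (!length(header))
    stop("GFF3 lacks ##sequence-region pragmas (scaffold lengths required)")
  fields <- strsplit(trimws(header), "[ \t]+")
  sl <- vapply(fields, function(f) as.numeric(f[4L]), numeric(1))
  names(sl) <- vapply(fields, `[[`, "", 2L)
  df <- data.frame(
    locus_id = as.character(gr$ID),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$scaffold_length <- unname(sl[df$scaffold_id])
  if (anyNA(df$scaffold_length))
    stop("GFF3 lacks ##sequence-region pragma for scaffold(s): ",
         paste(unique(df$scaffold_id[is.na(df$scaffold_length)]), collapse = ", "))
  bad <- which(df$end > df$scaffold_length | df$start < 1L)
  if (length(bad))
    stop(sprintf("gene '%s' exceeds its scaffold bounds (%d..%d on %d nt)",
                 df$locus_id[bad[1L]], df$start[bad[1L]], df$end[bad[1L]],
                 df$scaffold_length[bad[1L]]))
  if (anyDuplicated(df$locus_id))
    stop("duplicate gene id in GFF3: ",
         df$locus_id[anyDuplicated(df$locus_id)])
  df
}

#' Write gene models to GFF3 (with sequence-region pragmas)
#'
#' @param models Gene-model `data.frame` as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  sl <- tapply(models$scaffold_length, models$scaffold_id, function(x) {
    if (length(unique(x)) != 1L) stop("inconsistent scaffold lengths")
    x[[1L]]
  })
  gr <- GenomicRanges::GRanges(
    seqnames = models$scaffold_id,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand,
    type = "gene",
    ID = models$locus_id,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(sl),
                                    seqlengths = as.integer(sl))
  )
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  rtracklayer::export(gr, tmp, format = "gff3")
  body <- readLines(tmp, warn = FALSE)
  # drop the date/version stamps (byte-stable output) and add the
  # sequence-region pragmas rtracklayer omits
  body <- body[!grepl("^##(source-version|date)", body)]
  pragma <- sprintf("##sequence-region %s 1 %d", names(sl), as.integer(sl))
  writeLines(c(body[1L], pragma, body[-1L]), path)
  invisible(path)
}

.truncation_levels <- c("none", "N", "C")
.localization_levels <- c("C", "M", "S", "O", "NA")

#' Read a per-locus annotation table from TSV
#'
#' Columns: `locus_id`, `defline`, `go_ids` (semicolon-separated, `.` for
#' none), `domain_id` (`.` for none), `truncation` (`none`/`N`/`C`),
#' `has_start_codon` (0/1), `localization` (`C`/`M`/`S`/`O`/`NA`). A locus
#' with several domain hits occupies several rows whose locus-level fields
#' must agree.
#'
#' @param path Path to the TSV file.
#' @return `data.frame`, one row per (locus, domain hit).
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  needed <- c("locus_id", "defline", "go_ids", "domain_id", "truncation",
              "has_start_codon", "localization")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("annotation TSV lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!(df$truncation %in% c(.truncation_levels, ".")))
  if (length(bad))
    stop(sprintf("row %d: invalid truncation '%s' (must be none/N/C)",
                 bad[1L], df$truncation[bad[1L]]))
  bad <- which(!(df$localization %in% .localization_levels))
  if (length(bad))
    stop(sprintf("row %d: invalid localization '%s' (must be C/M/S/O/NA)",
                 bad[1L], df$localization[bad[1L]]))
  df$has_start_codon <- df$has_start_codon %in% c("1", "TRUE", "true")
  df[needed]
}

#' Write an annotation table to TSV
#' @param ann Annotation `data.frame` as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- ann
  out$has_start_codon <- as.integer(out$has_start_codon)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split a semicolon-separated go_ids field ("." = empty) into a character
# vector per locus; collapses multi-row loci
annotation_go_sets <- function(ann) {
  per_locus <- ann[!duplicated(ann$locus_id), c("locus_id", "go_ids")]
  sets <- lapply(per_locus$go_ids, function(g) {
    if (identical(g, ".") || !nzchar(g)) character(0)
    else unique(strsplit(g, ";", fixed = TRUE)[[1L]])
  })
  names(sets) <- per_locus$locus_id
  sets
}

# domain hits per locus: list of data.frames (domain_id, truncation)
annotation_domain_hits <- function(ann) {
  hits <- ann[ann$domain_id != ".", c("locus_id", "domain_id", "truncation")]
  split(hits[c("domain_id", "truncation")], factor(hits$locus_id))
}

#' Read a GO DAG from an OBO file (is_a edges only)
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a` lines.
#' Obsolete terms are dropped. Edges to undefined terms and cycles are
#' rejected.
#'
#' @param path Path to an OBO file.
#' @return Object of class `go_dag`: list with `terms` (data.frame of `id`,
#'   `name`, `namespace`) and `parents` (named list, term -> is_a parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("OBO file contains no [Term] stanzas")
  terms <- list()
  for (s in seq_along(term_starts)) {
    from <- term_starts[s] + 1L
    to <- if (s < length(term_starts)) term_starts[s + 1L] - 1L else length(lines)
    block <- lines[from:to]
    stop_at <- grep("^\\[", block)
    if (length(stop_at)) block <- block[seq_len(stop_at[1L] - 1L)]
    field <- function(key) sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- field("id")
    if (length(id) != 1L) stop("OBO term stanza without a single id (stanza ", s, ")")
    parents <- sub(" *!.*$", "", field("is_a"))
    terms[[id]] <- list(
      id = id,
      name = if (length(field("name"))) field("name")[1L] else id,
      namespace = if (length(field("namespace"))) field("namespace")[1L] else NA_character_,
      parents = parents
    )
  }
  ids <- names(terms)
  parents <- lapply(terms, `[[`, "parents")
  undef <- setdiff(unique(unlist(parents)), ids)
  if (length(undef))
    stop("OBO is_a edge references undefined term(s): ",
         paste(undef, collapse = ", "))
  dag <- structure(list(
    terms = data.frame(
      id = ids,
      name = vapply(terms, `[[`, "", "name"),
      namespace = vapply(terms, `[[`, "", "namespace"),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    parents = parents
  ), class = "go_dag")
  assert_acyclic(dag)
  dag
}

# Kahn topological sort; errors on a cycle
assert_acyclic <- function(dag) {
  ids <- dag$terms$id
  indeg <- vapply(dag$parents, length, 0L)  # edges child -> parent
  children <- split(
    rep(ids, times = indeg),
    unlist(dag$parents, use.names = FALSE)
  )
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stop("OBO is_a graph contains a cycle")
  invisible(TRUE)
}

#' Write a GO DAG to a minimal OBO file
#' @param dag A `go_dag` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c(
      "", "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      paste0("namespace: ", dag$terms$namespace[i]),
      if (length(dag$parents[[id]])) paste0("is_a: ", dag$parents[[id]])
    ), con)
  }
  invisible(path)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d is_a edges (%s)\n",
              nrow(x$terms), sum(lengths(x$parents)),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Read a homology hit table (BLAST outfmt-6 style TSV)
#'
#' Columns `qseqid`, `sseqid`, `evalue`, `bitscore`; ranked per query by
#' ascending e-value with ties broken by descending bit score, then
#' lexicographic subject id.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the four columns plus `rank`.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("qseqid", "sseqid", "evalue", "bitscore")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$evalue < 0)) stop("negative e-value in hit table")
  rank_hits(df[needed])
}

# assign per-query ranks: evalue asc, bitscore desc, sseqid asc
rank_hits <- function(df) {
  ord <- order(df$qseqid, df$evalue, -df$bitscore, df$sseqid)
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$qseqid, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Write a hit table to TSV
#' @param hits Hit-table `data.frame` (rank column, if present, is dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[c("qseqid", "sseqid", "evalue", "bitscore")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
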