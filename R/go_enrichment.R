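#' Propagate GO annotations by the true-path rule
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term (set semantics: a diamond in the DAG contributes each ancestor
#' once).
#'
#' @param direct Named list: gene id -> character vector of directly
#'   annotated GO ids.
#' @param dag A `go_dag` (see [read_obo()]).
#' @return Named list: gene id -> propagated GO id set.
#' @export
propagate_annotations <- function(direct, dag) {
  unknown <- setdiff(unique(unlist(direct)), dag$terms$id)
  if (length(unknown))
    stop("annotation references term(s) absent from the DAG: ",
         paste(unknown, collapse = ", "))
  anc <- dag_ancestors(dag)
  lapply(direct, function(terms) {
    if (!length(terms)) return(character(0))
    unique(c(terms, unlist(anc[terms], use.names = FALSE)))
  })
}

# memoized ancestors (excluding the term itself) for every term
dag_ancestors <- function(dag) {
  anc <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    ps <- dag$parents[[id]]
    res <- if (!length(ps)) character(0)
    else unique(c(ps, unlist(lapply(ps, get_anc), use.names = FALSE)))
    anc[[id]] <- res
    res
  }
  out <- lapply(dag$terms$id, get_anc)
  names(out) <- dag$terms$id
  out
}

#' One-sided over-representation test for a GO term
#'
#' Upper-tail hypergeometric probability of drawing at least `term_in_set`
#' term-annotated genes when sampling `set_size` genes without replacement
#' from a universe of `universe_size` genes of which `term_in_universe`
#' carry the term (equivalent to the one-sided Fisher exact test).
#'
#' @param set_size Number of genes in the study set.
#' @param universe_size Number of genes in the universe.
#' @param term_in_set Term-annotated genes in the set.
#' @param term_in_universe Term-annotated genes in the universe.
#' @return The p-value, in `(0, 1]`.
#' @export
term_test <- function(set_size, universe_size, term_in_set, term_in_universe) {
  if (set_size > universe_size || term_in_universe > universe_size ||
      term_in_set > min(set_size, term_in_universe) ||
      any(c(set_size, universe_size, term_in_set, term_in_universe) < 0))
    stop("inconsistent counts for the hypergeometric test")
  stats::phyper(term_in_set - 1, term_in_universe,
                universe_size - term_in_universe, set_size,
                lower.tail = FALSE)
}

#' GO over-representation analysis of a gene set
#'
#' Classic Fisher (hypergeometric) over-representation on true-path
#' propagated annotations, restricted to the biological_process namespace.
#' No multiple-testing correction is applied; terms with p below `alpha`
#' (default 1e-4) are flagged significant.
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param universe Character vector of gene ids, or `NULL` to use all genes
#'   with at least one propagated BP annotation.
#' @param direct Named list: gene -> direct GO ids.
#' @param dag A `go_dag`.
#' @param alpha Significance threshold on the raw p-value.
#' @param namespace Ontology namespace to test.
#' @return `data.frame` with one row per tested term: `term_id`, `name`,
#'   `universe_count`, `set_count`, `expected`, `p_value`, `significant`;
#'   sorted by ascending p.
#' @export
go_enrich <- function(gene_set, universe = NULL, direct, dag, alpha = 1e-4,
                      namespace = "biological_process") {
  prop <- propagate_annotations(direct, dag)
  bp <- dag$terms$id[dag$terms$namespace == namespace]
  prop <- lapply(prop, intersect, bp)
  annotated <- names(prop)[lengths(prop) > 0L]
  if (is.null(universe)) universe <- annotated
  universe <- intersect(universe, annotated)
  if (!length(universe)) stop("empty annotated universe")
  bad <- setdiff(gene_set, universe)
  gene_set <- intersect(gene_set, universe)
  # term -> count over a gene list
  count_terms <- function(genes) {
    tab <- table(unlist(prop[genes], use.names = FALSE))
    stats::setNames(as.integer(tab), names(tab))
  }
  in_universe <- count_terms(universe)
  in_set <- count_terms(gene_set)
  terms <- names(in_set)
  if (!length(terms)) {
    return(data.frame(term_id = character(0), name = character(0),
                      universe_count = integer(0), set_count = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  }
  p <- vapply(terms, function(tm)
    term_test(length(gene_set), length(universe), in_set[[tm]],
              in_universe[[tm]]), numeric(1))
  out <- data.frame(
    term_id = terms,
    name = dag$terms$name[match(terms, dag$terms$id)],
    universe_count = in_universe[terms],
    set_count = in_set[terms],
    expected = in_universe[terms] * length(gene_set) / length(universe),
    p_value = p,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_size") <- length(gene_set)
  attr(out, "universe_size") <- length(universe)
  attr(out, "outside_universe") <- bad
  out
}
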