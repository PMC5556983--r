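#' Reciprocal-hit validation of a pathway candidate
#'
#' A candidate transcript for an enzymatic step is validated when its best
#' (rank-1) reverse homology hit in each model organism maps to one of the
#' step's template sequences. A candidate absent from a reverse table fails
#' with reason "no reverse hit".
#'
#' @param candidate Candidate locus id.
#' @param step Step definition: list with `step_id`, `templates` (named list
#'   of accepted subject ids per model organism) and `required_domains`.
#' @param reverse_tables Named list of ranked hit tables (see
#'   [read_hit_table()]), one per model organism; names must match
#'   `step$templates`.
#' @param require `"both"` (reciprocity in every organism) or `"either"`.
#' @return List with `pass` (logical) and `reason` (character).
#' @export
validate_reciprocal <- function(candidate, step, reverse_tables,
                                require = c("both", "either")) {
  require <- match.arg(require)
  orgs <- names(step$templates)
  missing <- setdiff(orgs, names(reverse_tables))
  if (length(missing))
    stop("no reverse table for organism(s): ", paste(missing, collapse = ", "))
  ok <- logical(length(orgs)); names(ok) <- orgs
  reasons <- character(0)
  for (org in orgs) {
    tab <- reverse_tables[[org]]
    best <- tab$sseqid[tab$qseqid == candidate & tab$rank == 1L]
    if (!length(best)) {
      reasons <- c(reasons, sprintf("no reverse hit in %s", org))
    } else if (!(best[1L] %in% step$templates[[org]])) {
      reasons <- c(reasons, sprintf("best reverse hit in %s is '%s', not a step template",
                                    org, best[1L]))
    } else ok[[org]] <- TRUE
  }
  pass <- if (require == "both") all(ok) else any(ok)
  list(pass = pass, reason = if (pass) "reciprocal" else paste(reasons, collapse = "; "))
}

#' Domain-structure validation of a pathway candidate
#'
#' The candidate must carry at least one of the step's required domains;
#' truncated hits count (a fragment of the true gene still evidences the
#' domain).
#'
#' @param hits Candidate's domain-hit `data.frame` (`domain_id`,
#'   `truncation`), or `NULL`.
#' @param step Step definition (see [validate_reciprocal()]).
#' @return Logical.
#' @export
validate_domain <- function(hits, step) {
  if (!length(step$required_domains)) stop("step declares no required domain")
  if (is.null(hits) || !nrow(hits)) return(FALSE)
  any(hits$domain_id %in% step$required_domains)
}

#' Reconstruct the candidate list for one enzymatic step
#'
#' Filter chain for pathway reconstruction on a fragmented assembly: forward
#' hits give the candidate list; candidates failing reciprocal validation in
#' the model organisms or lacking the step's required domain are removed;
#' fragment pairs among the survivors (detected within the candidate list)
#' are collapsed to their 5' member, yielding the minimal candidate list.
#' Every input candidate receives exactly one provenance label.
#'
#' @param step Step definition (see [validate_reciprocal()]).
#' @param forward_hits Ranked forward hit table; candidates are its subject
#'   ids for `step$step_id` queries (all subjects if `step_id` absent).
#' @param reverse_tables Named list of ranked reverse hit tables.
#' @param models Gene-model `data.frame`.
#' @param annotations Annotation `data.frame`.
#' @param mat FPKM time-course matrix.
#' @param r_threshold,margin Fragment-pair detection parameters.
#' @param require Reciprocity mode, see [validate_reciprocal()].
#' @return List with `step_id`, `retained` (locus ids), `provenance`
#'   (`data.frame`: `locus_id`, `status` in retained / failed-reciprocal /
#'   failed-domain / collapsed-into-pair, `reason`), and `merge_map`.
#' @export
reconstruct_step <- function(step, forward_hits, reverse_tables, models,
                             annotations, mat, r_threshold = 0.9,
                             margin = 500, require = "both") {
  fw <- forward_hits[forward_hits$qseqid == step$step_id, , drop = FALSE]
  if (!nrow(fw)) fw <- forward_hits
  candidates <- unique(fw$sseqid)
  if (!length(candidates)) {
    return(list(step_id = step$step_id, retained = character(0),
                provenance = data.frame(locus_id = character(0),
                                        status = character(0),
                                        reason = character(0)),
                merge_map = NULL))
  }
  hits <- annotation_domain_hits(annotations)
  status <- reason <- stats::setNames(character(length(candidates)), candidates)
  for (cand in candidates) {
    rec <- validate_reciprocal(cand, step, reverse_tables, require = require)
    if (!rec$pass) {
      status[[cand]] <- "failed-reciprocal"; reason[[cand]] <- rec$reason
    } else if (!validate_domain(hits[[cand]], step)) {
      status[[cand]] <- "failed-domain"
      reason[[cand]] <- paste("lacks required domain(s):",
                              paste(step$required_domains, collapse = ","))
    } else {
      status[[cand]] <- "retained"; reason[[cand]] <- "passed all filters"
    }
  }
  survivors <- candidates[status == "retained"]
  mm <- NULL
  if (length(survivors) >= 2L) {
    mm <- detect_fragment_pairs(mat, models, annotations,
                                r_threshold = r_threshold, margin = margin,
                                candidates = survivors)
    for (i in seq_len(nrow(mm))) {
      status[[mm$dropped[i]]] <- "collapsed-into-pair"
      reason[[mm$dropped[i]]] <- sprintf("3' fragment of pair (%s, %s); %s retained",
                                         mm$locus_a[i], mm$locus_b[i], mm$retained[i])
    }
  }
  list(
    step_id = step$step_id,
    retained = candidates[status == "retained"],
    provenance = data.frame(locus_id = candidates,
                            status = unname(status[candidates]),
                            reason = unname(reason[candidates]),
                            stringsAsFactors = FALSE),
    merge_map = mm
  )
}
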