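#' Select lipase-like candidate loci from annotations
#'
#' A locus is selected when its defline contains the keyword "lipase", or
#' both "hydrolase" and "beta" (case-insensitive), or its GO terms include
#' GO:0016298 (lipase activity), or both GO:0016787 (hydrolase activity) and
#' GO:0016042 (lipid catabolic process).
#'
#' @param annotations Annotation `data.frame` (see [read_annotations()]).
#' @return Character vector of selected locus ids.
#' @export
select_candidates <- function(annotations) {
  per_locus <- annotations[!duplicated(annotations$locus_id), ]
  defline <- tolower(per_locus$defline)
  go <- annotation_go_sets(annotations)[per_locus$locus_id]
  by_name <- grepl("lipase", defline, fixed = TRUE) |
    (grepl("hydrolase", defline, fixed = TRUE) &
       grepl("beta", defline, fixed = TRUE))
  by_go <- vapply(go, function(g)
    "GO:0016298" %in% g || all(c("GO:0016787", "GO:0016042") %in% g),
    logical(1))
  per_locus$locus_id[by_name | by_go]
}

#' Hierarchical clustering of log2 fold-change profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage of
#' the per-locus log2-FC profiles. `NA` cells (below-floor fold changes) are
#' imputed as 0 for the distance computation by default — the mask is kept
#' for display — or dropped pairwise.
#'
#' @param fc A `fragtx_fc` object or a numeric log2-FC matrix (rows =
#'   loci).
#' @param members Optional locus ids to restrict to.
#' @param na_policy `"zero"` (impute 0) or `"pairwise"` (pairwise-complete
#'   Euclidean distance, rescaled to the full profile length).
#' @return List with `tree` ([stats::hclust]), `distances` (a `dist`), and
#'   `profiles` (the matrix used).
#' @export
hcluster_profiles <- function(fc, members = NULL, na_policy = c("zero", "pairwise")) {
  na_policy <- match.arg(na_policy)
  m <- if (inherits(fc, "fragtx_fc")) fc$log2fc else fc
  if (!is.null(members)) {
    absent <- setdiff(members, rownames(m))
    if (length(absent)) stop("profiles missing for: ", paste(absent, collapse = ", "))
    m <- m[members, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least two profiles to cluster")
  d <- if (na_policy == "zero") {
    m0 <- m; m0[is.na(m0)] <- 0
    stats::dist(m0, method = "euclidean")
  } else {
    n <- ncol(m)
    # pairwise-complete squared distance rescaled to full dimension
    dm <- as.matrix(stats::dist(m, method = "euclidean"))
    shared <- (!is.na(m)) %*% t(!is.na(m))
    stats::as.dist(sqrt(dm^2 * n / pmax(shared, 1L)))
  }
  list(tree = stats::hclust(d, method = "complete"), distances = d,
       profiles = m)
}

#' Average silhouette width of a clustering
#'
#' Per point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the
#' mean distance to the other members of its cluster and `b(i)` the smallest
#' mean distance to another cluster. Members of singleton clusters
#' contribute `s = 0`, as does the degenerate `0/0` case (all distances
#' zero).
#'
#' @param assignment Integer cluster labels per point (k >= 2 clusters, all
#'   non-empty).
#' @param distances A `dist` or symmetric distance matrix over the points.
#' @return The mean silhouette width, in `[-1, 1]`.
#' @export
average_silhouette <- function(assignment, distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (length(assignment) != n) stop("assignment/distance size mismatch")
  labs <- unique(assignment)
  if (length(labs) < 2L) stop("silhouette needs at least two clusters")
  sizes <- table(assignment)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, assignment == own]) / (sizes[[as.character(own)]] - 1L)
    b <- min(vapply(setdiff(labs, own), function(cl)
      mean(d[i, assignment == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Cut a dendrogram with silhouette-guided selection of k
#'
#' Cuts the tree at each candidate number of clusters and picks the k with
#' the largest average silhouette width (ties to the smallest k). An
#' explicit `k` overrides the selection — e.g. a four-cluster cut fixed from
#' inspection of the dendrogram — while the silhouettes are still reported.
#'
#' @param clustering Output of [hcluster_profiles()] (or a list with `tree`
#'   and `distances`).
#' @param k_range Candidate cluster counts, default 3..7.
#' @param k Optional fixed number of clusters.
#' @return Object of class `cluster_result`: list with `assignment` (named
#'   integer vector), `chosen_k`, `silhouettes` (named per k), `tree`.
#' @export
cut_and_select <- function(clustering, k_range = 3:7, k = NULL) {
  tree <- clustering$tree
  n <- length(tree$order)
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop("no feasible k in k_range for ", n, " leaves")
  sil <- vapply(k_range, function(kk)
    average_silhouette(stats::cutree(tree, k = kk), clustering$distances),
    numeric(1))
  names(sil) <- k_range
  chosen <- if (is.null(k)) k_range[which.max(sil)] else k
  structure(list(
    assignment = stats::cutree(tree, k = chosen),
    chosen_k = chosen,
    silhouettes = sil,
    tree = tree
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Profile clustering: %d members, k = %d\n",
              length(x$assignment), x$chosen_k))
  cat("Average silhouette by k:\n")
  print(round(x$silhouettes, 3))
  invisible(x)
}

#' Select, cluster and cut a gene family in one call
#'
#' Convenience wrapper: candidate selection by annotation rules, hierarchical
#' clustering of the candidates' log2-FC profiles, silhouette-guided cut.
#'
#' @param fc A `fragtx_fc` object.
#' @param annotations Annotation `data.frame`.
#' @param k_range,k See [cut_and_select()].
#' @inheritParams hcluster_profiles
#' @return A `cluster_result` (with the selected member ids as names of
#'   `assignment`).
#' @export
cluster_gene_family <- function(fc, annotations, k_range = 3:7, k = NULL,
                                na_policy = "zero") {
  members <- intersect(select_candidates(annotations), rownames(fc$log2fc))
  if (length(members) < 2L)
    stop("fewer than two family candidates with expression profiles")
  cl <- hcluster_profiles(fc, members = members, na_policy = na_policy)
  cut_and_select(cl, k_range = k_range, k = k)
}
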