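# reduced synthetic study for fast unit tests
small_config <- function(noise_sd = 0, seed = 1, ...) {
  synth_config(
    n_loci = 120, n_scaffolds = 20, frac_fragment_pairs = 0.1,
    up_counts = c("e-N" = 5, "l-N" = 5, "r+N" = 5),
    down_counts = c("e-N" = 5, "l-N" = 5, "r+N" = 5),
    n_housekeeping = 10, n_profile_clusters = 4,
    cluster_sizes = c(5, 5, 5, 5), noise_sd = noise_sd, seed = seed, ...
  )
}

# canonical 12-column matrix from named profile rows
mk_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- time_points()
  m
}

# small handwritten DAG: root -> (m1, m2) -> leaves, with a diamond at l3
tiny_dag <- function() {
  structure(list(
    terms = data.frame(
      id = c("GO:0000001", "GO:0000002", "GO:0000003",
             "GO:0000004", "GO:0000005", "GO:0000006"),
      name = c("root", "mid1", "mid2", "leaf1", "leaf2", "diamond leaf"),
      namespace = "biological_process",
      stringsAsFactors = FALSE),
    parents = list(
      "GO:0000001" = character(0),
      "GO:0000002" = "GO:0000001",
      "GO:0000003" = "GO:0000001",
      "GO:0000004" = "GO:0000002",
      "GO:0000005" = "GO:0000003",
      "GO:0000006" = c("GO:0000002", "GO:0000003")
    )
  ), class = "go_dag")
}

# brute-force per-point silhouette, straight from the definition
silhouette_oracle <- function(assignment, d) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- which(assignment == assignment[i])
    if (length(mine) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(mine, i)])
    b <- Inf
    for (cl in setdiff(unique(assignment), assignment[i]))
      b <- min(b, mean(d[i, assignment == cl]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Jensen-Shannon distance by direct KL summation (base 2)
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) kl <- kl + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) kl <- kl + 0.5 * q[i] * log2(q[i] / m[i])
  }
  sqrt(kl)
}

# upper-tail hypergeometric by exhaustive subset enumeration
hyper_oracle <- function(set_size, universe_size, term_in_set, term_in_universe) {
  subsets <- utils::combn(universe_size, set_size)
  annotated <- seq_len(term_in_universe)  # wlog the first K elements
  hits <- apply(subsets, 2, function(s) sum(s %in% annotated))
  mean(hits >= term_in_set)
}
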