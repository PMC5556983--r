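#' Configuration for the synthetic nitrogen time-course study
#'
#' Defines the planted structure of a synthetic dataset: fragment pairs at
#' scaffold margins, stage-responsive genes (up/down per stage), stable
#' housekeeping genes, profile clusters within a lipase-like gene family, a
#' designated enriched GO term per up-set, and homology hit tables with a
#' configurable fraction of candidates failing reciprocal validation.
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: 500 loci, 20 fragment pairs, 25 up- and 25 down-regulated
#' genes per stage, 50 housekeeping genes, four profile clusters of 12-13
#' members, an effect size of 2 log2 units and log2-scale Gaussian noise of
#' 0.1.
#'
#' @param n_loci Number of transcript loci.
#' @param n_scaffolds Number of scaffolds (two margin slots each).
#' @param frac_fragment_pairs Fraction of loci that are fragment-pair
#'   members, in `[0, 0.3]`; pair count = `round(frac * n_loci / 2)`.
#' @param up_counts,down_counts Named counts of planted responsive genes per
#'   stage (`e-N`, `l-N`, `r+N`).
#' @param n_housekeeping Number of stable housekeeping genes (half receive a
#'   transient resupply excursion at `R_2`).
#' @param n_profile_clusters Number of planted profile clusters (2..7).
#' @param cluster_sizes Members per cluster (length `n_profile_clusters`).
#' @param noise_sd Standard deviation of additive Gaussian noise on
#'   log2(FPKM).
#' @param baseline_logmean,baseline_logsd Log2-scale mean / sd of the
#'   lognormal baseline FPKM of background loci (the default span covers
#'   more than four orders of magnitude).
#' @param effect_log2fc Planted effect size in log2 units (> 1).
#' @param frac_invalid_candidates Fraction of extra pathway-step candidates
#'   generated to fail reciprocal validation.
#' @param n_steps Number of synthetic enzymatic steps with hit tables.
#' @param seed Integer seed; fully determines the dataset.
#' @return Object of class `synth_config` (validated list).
#' @export
synth_config <- function(n_loci = 500,
                         n_scaffolds = 60,
                         frac_fragment_pairs = 0.08,
                         up_counts = c("e-N" = 25, "l-N" = 25, "r+N" = 25),
                         down_counts = c("e-N" = 25, "l-N" = 25, "r+N" = 25),
                         n_housekeeping = 50,
                         n_profile_clusters = 4,
                         cluster_sizes = c(13, 13, 12, 12),
                         noise_sd = 0.1,
                         baseline_logmean = 3,
                         baseline_logsd = 3,
                         effect_log2fc = 2,
                         frac_invalid_candidates = 0.3,
                         n_steps = 2,
                         seed = 1) {
  cfg <- list(n_loci = n_loci, n_scaffolds = n_scaffolds,
              frac_fragment_pairs = frac_fragment_pairs,
              up_counts = up_counts, down_counts = down_counts,
              n_housekeeping = n_housekeeping,
              n_profile_clusters = n_profile_clusters,
              cluster_sizes = cluster_sizes, noise_sd = noise_sd,
              baseline_logmean = baseline_logmean,
              baseline_logsd = baseline_logsd,
              effect_log2fc = effect_log2fc,
              frac_invalid_candidates = frac_invalid_candidates,
              n_steps = n_steps, seed = seed)
  stages <- names(stage_definition())
  if (frac_fragment_pairs < 0 || frac_fragment_pairs > 0.3)
    stop("frac_fragment_pairs must lie in [0, 0.3]")
  if (!all(stages %in% names(up_counts)) || !all(stages %in% names(down_counts)))
    stop("up_counts/down_counts must name all three stages")
  if (effect_log2fc <= 1)
    stop("effect_log2fc must exceed 1 (planted genes must be recoverable)")
  if (n_profile_clusters < 2 || n_profile_clusters > 7)
    stop("n_profile_clusters must lie in 2..7")
  if (length(cluster_sizes) != n_profile_clusters)
    stop("cluster_sizes must have one entry per profile cluster")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  cfg$n_pairs <- round(frac_fragment_pairs * n_loci / 2)
  planted <- 2 * cfg$n_pairs + sum(up_counts[stages]) +
    sum(down_counts[stages]) + n_housekeeping + sum(cluster_sizes)
  if (planted > n_loci)
    stop(sprintf("planted loci (%d) exceed n_loci (%d)", planted, n_loci))
  structure(cfg, class = "synth_config")
}

# prototype latent log2-FC patterns for profile clusters, by cluster index
cluster_prototype <- function(idx, tps, effect) {
  stages <- stage_definition()
  prof <- stats::setNames(numeric(length(tps)), tps)
  amp <- 1.5 * effect
  switch(((idx - 1L) %% 7L) + 1L,
    { prof[stages[["e-N"]]] <- amp },
    { prof[stages[["l-N"]]] <- amp },
    { prof[stages[["r+N"]]] <- amp },
    { prof[c(stages[["e-N"]], stages[["l-N"]])] <- -amp },
    { prof[stages[["l-N"]]] <- -amp; prof[stages[["r+N"]]] <- amp },
    { prof[stages[["e-N"]]] <- amp; prof[stages[["r+N"]]] <- -amp },
    { prof[unlist(stages)] <- amp * c(1, -1)[(seq_along(unlist(stages)) %% 2) + 1] }
  )
  prof
}

#' Generate a synthetic study with planted ground truth
#'
#' Builds the full input bundle of the pipeline — FPKM time-course matrix,
#' gene models with scaffold coordinates, annotation table, GO DAG, pathway
#' step definitions and homology hit tables — together with the planted
#' truth used as recovery oracle. Fragment-pair members share one latent
#' profile, sit within 500 nt of a scaffold end, and carry complementary
#' C-/N-truncated hits to a shared domain; stage-responsive genes change
#' only in their stage's time points; housekeeping genes are flat under -N;
#' one designated GO term is planted at elevated frequency in each up-set.
#'
#' @param config A [synth_config()].
#' @return Object of class `fragtx_dataset`: list with `matrix`, `models`,
#'   `annotations`, `dag`, `steps`, `hits` (forward + per-organism reverse),
#'   `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  tps <- time_points()
  stages <- stage_definition()
  n <- cfg$n_loci
  ids <- sprintf("XLOC_%06d", seq_len(n))

  ## --- role assignment (sequential blocks, then the rest is background)
  cursor <- 0L
  take <- function(k) {
    out <- ids[cursor + seq_len(k)]
    cursor <<- cursor + k
    out
  }
  pair_a <- take(cfg$n_pairs)     # 5' members
  pair_b <- take(cfg$n_pairs)     # 3' members
  resp <- list()
  for (s in names(stages)) {
    resp[[paste0("up_", stage_key(s))]] <- take(cfg$up_counts[[s]])
    resp[[paste0("down_", stage_key(s))]] <- take(cfg$down_counts[[s]])
  }
  hk <- take(cfg$n_housekeeping)
  clust <- list()
  for (k in seq_len(cfg$n_profile_clusters))
    clust[[k]] <- take(cfg$cluster_sizes[[k]])
  background <- ids[(cursor + 1L):n]

  ## --- latent log2-FC profiles (before noise), baselines
  latent <- matrix(0, n, length(tps), dimnames = list(ids, tps))
  baseline <- stats::rnorm(n, cfg$baseline_logmean, cfg$baseline_logsd)
  names(baseline) <- ids
  # planted loci need headroom above the FPKM floor even when down-regulated
  planted_ids <- c(pair_a, pair_b, unlist(resp), hk, unlist(clust))
  baseline[planted_ids] <- stats::runif(length(planted_ids),
                                        cfg$effect_log2fc + 2, 8)
  eff <- cfg$effect_log2fc
  for (s in names(stages)) {
    latent[resp[[paste0("up_", stage_key(s))]], stages[[s]]] <- eff
    latent[resp[[paste0("down_", stage_key(s))]], stages[[s]]] <- -eff
  }
  # half of the housekeeping genes: transient excursion at R_2 only
  hk_trans <- hk[seq_len(length(hk) %/% 2)]
  latent[hk_trans, "R_2"] <- 1.5
  for (k in seq_along(clust))
    latent[clust[[k]], ] <- matrix(cluster_prototype(k, tps, eff),
                                   length(clust[[k]]), length(tps),
                                   byrow = TRUE)
  # each fragment pair shares one latent profile and one baseline
  if (cfg$n_pairs > 0) {
    pair_stage <- sample(names(stages), cfg$n_pairs, replace = TRUE)
    pair_dir <- sample(c(1, -1), cfg$n_pairs, replace = TRUE)
    for (p in seq_len(cfg$n_pairs)) {
      latent[pair_a[p], stages[[pair_stage[p]]]] <- pair_dir[p] * eff
      latent[pair_b[p], ] <- latent[pair_a[p], ]
      baseline[pair_b[p]] <- baseline[pair_a[p]]
    }
  }

  noise <- matrix(stats::rnorm(n * length(tps), 0, cfg$noise_sd),
                  n, length(tps))
  fpkm <- 2^(baseline + latent + noise)
  dimnames(fpkm) <- list(ids, tps)

  ## --- gene models: pair members at scaffold margins, background interior;
  ##     a few background decoys also at margins to exercise the filters
  scaf_len <- 1e6L
  scaffolds <- sprintf("scaffold_%03d", seq_len(cfg$n_scaffolds))
  n_decoys <- min(length(background), max(4L, n %/% 50L))
  margin_decoys <- background[seq_len(n_decoys)]
  margin_ids <- c(rbind(pair_a, pair_b)[seq_len(2 * cfg$n_pairs)], margin_decoys)
  if (length(margin_ids) > 2L * cfg$n_scaffolds)
    stop("not enough scaffold margins for the planted margin loci")
  models <- data.frame(locus_id = ids, scaffold_id = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = "+", scaffold_length = scaf_len,
                       stringsAsFactors = FALSE)
  rownames(models) <- ids
  for (i in seq_along(margin_ids)) {
    scaf <- scaffolds[ceiling(i / 2)]
    if (i %% 2L == 1L) { s0 <- 101L; e0 <- 1000L }          # left margin
    else { e0 <- scaf_len - 100L; s0 <- e0 - 899L }         # right margin
    models[margin_ids[i], c("scaffold_id", "start", "end")] <-
      list(scaf, s0, e0)
  }
  interior <- setdiff(ids, margin_ids)
  for (i in seq_along(interior)) {
    scaf <- scaffolds[(i - 1L) %% cfg$n_scaffolds + 1L]
    slot <- (i - 1L) %/% cfg$n_scaffolds
    s0 <- 20000L + slot * 2000L
    models[interior[i], c("scaffold_id", "start", "end")] <-
      list(scaf, s0, s0 + 899L)
  }

  ## --- GO DAG: small is_a DAG rooted at biological_process
  root <- "GO:0008150"
  mids <- sprintf("GO:01000%02d", 1:6)
  leaves <- sprintf("GO:02000%02d", 1:40)
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(lapply(mids, function(m) root), mids),
    stats::setNames(lapply(seq_along(leaves), function(i) {
      p <- mids[(i - 1L) %% 6L + 1L]
      if (i %% 7L == 0L) c(p, mids[i %% 6L + 1L]) else p   # some diamonds
    }), leaves)
  )
  all_terms <- c(root, mids, leaves)
  dag <- structure(list(
    terms = data.frame(id = all_terms,
                       name = c("biological_process",
                                paste("process group", 1:6),
                                paste("leaf process", 1:40)),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = parents
  ), class = "go_dag")

  ## --- annotations: deflines, GO ids, domain hits, start codons
  enriched <- stats::setNames(leaves[1:3],
                              paste0("up_", vapply(names(stages), stage_key, "")))
  go_sets <- lapply(ids, function(id)
    sample(leaves[-(1:3)], sample(1:3, 1)))
  names(go_sets) <- ids
  for (s in names(stages)) {
    set_name <- paste0("up_", stage_key(s))
    members <- resp[[set_name]]
    hit <- stats::runif(length(members)) < 0.8
    for (m in members[hit])
      go_sets[[m]] <- union(go_sets[[m]], enriched[[set_name]])
    bg_hit <- stats::runif(n) < 0.05
    for (m in ids[bg_hit & !(ids %in% members)])
      go_sets[[m]] <- union(go_sets[[m]], enriched[[set_name]])
  }
  defline <- rep("hypothetical protein", n)
  names(defline) <- ids
  defline[unlist(resp)] <- "putative stress response protein"
  defline[hk] <- "putative ribosomal protein"
  defline[unlist(clust)] <- "putative triacylglycerol lipase"
  domain_id <- rep(".", n); truncation <- rep(".", n)
  names(domain_id) <- names(truncation) <- ids
  if (cfg$n_pairs > 0) {
    pair_dom <- sprintf("DOM_PAIR_%03d", seq_len(cfg$n_pairs))
    domain_id[pair_a] <- pair_dom; truncation[pair_a] <- "C"   # 5' half
    domain_id[pair_b] <- pair_dom; truncation[pair_b] <- "N"   # 3' half
  }
  # margin decoys: shared domain with NON-complementary truncations
  if (length(margin_decoys) >= 2L) {
    domain_id[margin_decoys] <- "DOM_DECOY"
    truncation[margin_decoys] <- "C"
  }
  domain_id[unlist(clust)] <- "DOM_LIPASE"
  truncation[unlist(clust)] <- "none"
  has_start <- rep(TRUE, n); names(has_start) <- ids
  has_start[pair_b] <- FALSE
  annotations <- data.frame(
    locus_id = ids,
    defline = unname(defline),
    go_ids = unname(vapply(go_sets, function(g)
      if (length(g)) paste(sort(g), collapse = ";") else ".", "")),
    domain_id = unname(domain_id),
    truncation = unname(truncation),
    has_start_codon = unname(has_start),
    localization = sample(.localization_levels, n, replace = TRUE,
                          prob = c(0.3, 0.15, 0.15, 0.3, 0.1)),
    stringsAsFactors = FALSE
  )

  ## --- pathway steps and hit tables
  steps <- list()
  forward <- reverse_a <- reverse_b <- list()
  organisms <- c("A_thaliana", "C_reinhardtii")
  pool <- setdiff(background, margin_decoys)
  pool_cursor <- 0L
  for (k in seq_len(min(cfg$n_steps, cfg$n_pairs))) {
    step_id <- sprintf("step_%02d", k)
    templates <- list(A_thaliana = sprintf("AT%dG%05d", k, k * 1000),
                      C_reinhardtii = sprintf("Cre%02d.g%06d", k, k * 1000))
    req_dom <- sprintf("DOM_PAIR_%03d", k)
    valid_extra <- pool[pool_cursor + 1:2]; pool_cursor <- pool_cursor + 2L
    n_invalid <- max(1L, round(cfg$frac_invalid_candidates * 4))
    invalid <- pool[pool_cursor + seq_len(n_invalid)]
    pool_cursor <- pool_cursor + n_invalid
    no_domain <- pool[pool_cursor + 1L]; pool_cursor <- pool_cursor + 1L
    # valid unpaired candidates carry the required domain (untruncated)
    annotations$domain_id[annotations$locus_id %in% valid_extra] <- req_dom
    annotations$truncation[annotations$locus_id %in% valid_extra] <- "none"
    cands <- c(pair_a[k], pair_b[k], valid_extra, invalid, no_domain)
    forward[[k]] <- data.frame(qseqid = step_id, sseqid = cands,
                               evalue = 10^-(30 - seq_along(cands)),
                               bitscore = 200 - seq_along(cands),
                               stringsAsFactors = FALSE)
    mk_rev <- function(org) {
      good <- c(pair_a[k], pair_b[k], valid_extra, no_domain)
      data.frame(
        qseqid = cands,
        sseqid = ifelse(cands %in% good, templates[[org]], "UNRELATED_GENE"),
        evalue = 1e-40, bitscore = 300, stringsAsFactors = FALSE)
    }
    reverse_a[[k]] <- mk_rev("A_thaliana")
    reverse_b[[k]] <- mk_rev("C_reinhardtii")
    steps[[step_id]] <- list(step_id = step_id, templates = templates,
                             required_domains = req_dom,
                             planted_valid = c(pair_a[k], valid_extra),
                             planted_invalid = c(invalid, no_domain))
  }
  hits <- list(
    forward = rank_hits(do.call(rbind, c(forward, list(
      data.frame(qseqid = character(0), sseqid = character(0),
                 evalue = numeric(0), bitscore = numeric(0)))))),
    A_thaliana = rank_hits(do.call(rbind, c(reverse_a, list(
      data.frame(qseqid = character(0), sseqid = character(0),
                 evalue = numeric(0), bitscore = numeric(0)))))),
    C_reinhardtii = rank_hits(do.call(rbind, c(reverse_b, list(
      data.frame(qseqid = character(0), sseqid = character(0),
                 evalue = numeric(0), bitscore = numeric(0))))))
  )

  ## --- planted truth
  tp_dir <- matrix("none", length(c(unlist(resp), hk)), length(tps) - 1L,
                   dimnames = list(c(unlist(resp), hk), setdiff(tps, "N_0")))
  stage_dir <- data.frame(locus_id = rownames(tp_dir), "e-N" = "none",
                          "l-N" = "none", "r+N" = "none",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(stage_dir) <- stage_dir$locus_id
  for (s in names(stages)) {
    up <- resp[[paste0("up_", stage_key(s))]]
    down <- resp[[paste0("down_", stage_key(s))]]
    tp_dir[up, stages[[s]]] <- "up"
    tp_dir[down, stages[[s]]] <- "down"
    stage_dir[up, s] <- "up"
    stage_dir[down, s] <- "down"
  }
  tp_dir[hk_trans, "R_2"] <- "up"
  cluster_id <- stats::setNames(rep(seq_along(clust), lengths(clust)),
                                unlist(clust))
  truth <- list(
    pairs = data.frame(locus_a = pair_a, locus_b = pair_b, retained = pair_a,
                       stringsAsFactors = FALSE),
    stage_direction = stage_dir,
    timepoint_direction = tp_dir,
    housekeeping = hk,
    cluster_id = cluster_id,
    enriched_terms = as.list(enriched),
    responsive_sets = resp
  )

  structure(list(matrix = fpkm, models = models, annotations = annotations,
                 dag = dag, steps = steps, hits = hits, truth = truth,
                 config = cfg),
            class = "fragtx_dataset")
}

#' @export
print.fragtx_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic nitrogen time-course dataset (seed %d):\n",
                     "  %d loci x %d time points; %d fragment pairs, ",
                     "%d responsive, %d housekeeping, %d clustered loci\n"),
              x$config$seed, nrow(x$matrix), ncol(x$matrix),
              nrow(x$truth$pairs),
              length(unlist(x$truth$responsive_sets)),
              length(x$truth$housekeeping), length(x$truth$cluster_id)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the expression TSV, gene-model GFF3, annotation TSV, OBO, hit-table
#' TSVs, step definitions and planted truth as JSON, plus a manifest listing
#' files and seed.
#'
#' @param dataset A `fragtx_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest (named list), invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_expression(dataset$matrix, p("expression.tsv"))
  write_gene_models(dataset$models, p("models.gff3"))
  write_annotations(dataset$annotations, p("annotations.tsv"))
  write_obo(dataset$dag, p("go.obo"))
  write_hit_table(dataset$hits$forward, p("hits_forward.tsv"))
  for (org in setdiff(names(dataset$hits), "forward"))
    write_hit_table(dataset$hits[[org]], p(sprintf("hits_reverse_%s.tsv", org)))
  jsonlite::write_json(dataset$steps, p("steps.json"), auto_unbox = TRUE,
                       digits = NA)
  truth <- dataset$truth
  truth$cluster_id <- as.list(truth$cluster_id)  # keep locus names in JSON
  truth$timepoint_direction <- data.frame(
    locus_id = rownames(truth$timepoint_direction),
    truth$timepoint_direction, check.names = FALSE,
    stringsAsFactors = FALSE)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  files <- c("expression.tsv", "models.gff3", "annotations.tsv", "go.obo",
             "hits_forward.tsv",
             sprintf("hits_reverse_%s.tsv",
                     setdiff(names(dataset$hits), "forward")),
             "steps.json", "truth.json")
  manifest <- list(seed = dataset$config$seed, n_loci = dataset$config$n_loci,
                   files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
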