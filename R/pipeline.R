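#' Pipeline configuration
#'
#' Bundles the analysis thresholds (defaulting to the study's stated values:
#' responsiveness at |log2-FC| > 1, FPKM reliability floor 1.0, fragment
#' correlation > 0.9, 500 nt scaffold margin, enrichment alpha 1e-4, display
#' cap 4, cluster counts 3..7) with either a synthetic-data configuration or
#' a directory of input files.
#'
#' @param synth A [synth_config()], or `NULL` to read inputs from `input_dir`.
#' @param input_dir Directory holding `expression.tsv`, `models.gff3`,
#'   `annotations.tsv`, `go.obo`, hit tables and `steps.json` (as written by
#'   [write_dataset()]). Ignored when `synth` is given.
#' @param out_dir Output directory.
#' @param fc_threshold Responsiveness threshold (log2 units).
#' @param fpkm_floor FPKM reliability floor.
#' @param pearson_threshold Fragment-pair correlation threshold (< 1).
#' @param margin_nt Scaffold-margin distance (nt).
#' @param alpha Enrichment significance threshold.
#' @param cap Display cap (log2 units).
#' @param k_range Candidate cluster counts.
#' @param seed Seed recorded in the manifest (the synthetic config carries
#'   its own seed).
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            out_dir = tempfile("fragtx_run_"),
                            fc_threshold = 1.0, fpkm_floor = 1.0,
                            pearson_threshold = 0.9, margin_nt = 500,
                            alpha = 1e-4, cap = 4.0, k_range = 3:7,
                            seed = if (!is.null(synth)) synth$seed else 1L) {
  cfg <- list(synth = synth, input_dir = input_dir, out_dir = out_dir,
              fc_threshold = fc_threshold, fpkm_floor = fpkm_floor,
              pearson_threshold = pearson_threshold, margin_nt = margin_nt,
              alpha = alpha, cap = cap, k_range = k_range, seed = seed)
  num <- c(fc_threshold, fpkm_floor, pearson_threshold, margin_nt, alpha, cap)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("pipeline thresholds must be positive")
  if (pearson_threshold >= 1)
    stop("pearson_threshold must be below 1")
  if (alpha >= 1) stop("alpha must be below 1")
  if (is.null(synth) && is.null(input_dir))
    stop("either a synthetic config or an input directory is required")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation (or input loading), fold-change
#' classification, fragment-pair detection and collapse, stage gene sets and
#' Venn partitions, Jensen-Shannon sample clustering, gene-family profile
#' clustering, GO enrichment of the six stage sets, pathway-step candidate
#' validation, and pictogram export; every intermediate artifact is written
#' in a re-loadable format and hashed into the run manifest.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress log lines.
#' @return The run manifest (named list, invisibly): seed, thresholds,
#'   per-file MD5 hashes, and a truth-recovery report when running on
#'   synthetic data.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_line <- function(stage, msg) {
    if (!quiet)
      message(sprintf("[%s] %s: %s",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)

  ## inputs
  if (!is.null(config$synth)) {
    ds <- generate_dataset(config$synth)
    write_dataset(ds, p("inputs"))
    log_line("synth", sprintf("%d loci generated (seed %d)",
                              nrow(ds$matrix), config$synth$seed))
    input_dir <- p("inputs")
  } else input_dir <- config$input_dir
  mat <- read_expression(file.path(input_dir, "expression.tsv"))
  models <- read_gene_models(file.path(input_dir, "models.gff3"))
  ann <- read_annotations(file.path(input_dir, "annotations.tsv"))
  dag <- read_obo(file.path(input_dir, "go.obo"))
  steps <- jsonlite::read_json(file.path(input_dir, "steps.json"),
                               simplifyVector = TRUE)
  rev_files <- list.files(input_dir, "^hits_reverse_.*\\.tsv$")
  reverse_tables <- lapply(file.path(input_dir, rev_files), read_hit_table)
  names(reverse_tables) <- sub("^hits_reverse_(.*)\\.tsv$", "\\1", rev_files)
  forward <- read_hit_table(file.path(input_dir, "hits_forward.tsv"))

  ## fold change
  fc <- fold_change(mat, floor = config$fpkm_floor,
                    threshold = config$fc_threshold)
  fc_df <- data.frame(locus_id = rownames(fc$log2fc), fc$log2fc,
                      check.names = FALSE)
  utils::write.table(fc_df, p("fold_change.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  log_line("fc", sprintf("%d x %d fold changes (%d masked)",
                         nrow(fc$log2fc), ncol(fc$log2fc), sum(fc$na_mask)))

  ## fragments
  mm <- detect_fragment_pairs(mat, models, ann,
                              r_threshold = config$pearson_threshold,
                              margin = config$margin_nt)
  jsonlite::write_json(as.data.frame(mm), p("merge_map.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  collapsed <- collapse_fragments(mat, mm)
  write_expression(collapsed, p("expression_collapsed.tsv"))
  log_line("fragments", sprintf("%d pair(s) collapsed", nrow(mm)))

  ## stage sets and Venn
  resp <- stage_response(collapsed, floor = config$fpkm_floor,
                         threshold = config$fc_threshold)
  utils::write.table(resp, p("stage_response.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  sets <- stage_gene_sets(resp)
  venn <- list(up = venn_partition(sets$up_eN, sets$up_lN, sets$up_rN),
               down = venn_partition(sets$down_eN, sets$down_lN, sets$down_rN))
  jsonlite::write_json(venn, p("venn.json"), auto_unbox = FALSE, digits = NA)
  log_line("stages", sprintf("six sets: %s",
                             paste(names(sets), lengths(sets),
                                   sep = "=", collapse = ", ")))

  ## sample clustering
  jsd <- js_sample_distance(collapsed)
  utils::write.table(data.frame(sample = rownames(jsd), jsd,
                                check.names = FALSE),
                     p("js_distance.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dend <- cluster_samples(jsd)
  jsonlite::write_json(list(merge = dend$merge, height = dend$height,
                            labels = dend$labels),
                       p("sample_dendrogram.json"), digits = NA)

  ## gene-family clustering
  fam <- tryCatch(
    cluster_gene_family(fc, ann, k_range = config$k_range),
    error = function(e) { log_line("cluster", conditionMessage(e)); NULL })
  if (!is.null(fam)) {
    jsonlite::write_json(list(assignment = as.list(fam$assignment),
                              chosen_k = fam$chosen_k,
                              silhouettes = as.list(fam$silhouettes)),
                         p("family_clusters.json"), auto_unbox = TRUE,
                         digits = NA)
    log_line("cluster", sprintf("%d family members, chosen k = %d",
                                length(fam$assignment), fam$chosen_k))
  }

  ## GO enrichment of the six sets
  direct <- annotation_go_sets(ann)
  enr <- lapply(sets, function(gs)
    go_enrich(gs, universe = NULL, direct = direct, dag = dag,
              alpha = config$alpha))
  for (nm in names(enr))
    utils::write.table(enr[[nm]], p(sprintf("enrichment_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("enrich", sprintf("significant terms: %s",
                             paste(names(enr),
                                   vapply(enr, function(e) sum(e$significant), 0L),
                                   sep = "=", collapse = ", ")))

  ## pathway reconstruction
  recon <- lapply(steps, function(st)
    reconstruct_step(st, forward, reverse_tables, models, ann, mat,
                     r_threshold = config$pearson_threshold,
                     margin = config$margin_nt))
  jsonlite::write_json(lapply(recon, function(r)
    list(step_id = r$step_id, retained = r$retained,
         provenance = r$provenance)),
    p("pathway_steps.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  log_line("recon", sprintf("%d step(s) reconstructed", length(recon)))

  ## pictograms for the family members (or the first loci if none)
  loci <- if (!is.null(fam)) names(fam$assignment)
          else utils::head(rownames(collapsed), 20L)
  bounds <- category_boundaries(mat[, "N_0"])
  cats <- categorize(mat[loci, "N_0"], bounds)
  names(cats) <- loci
  locz <- stats::setNames(ann$localization[!duplicated(ann$locus_id)],
                          ann$locus_id[!duplicated(ann$locus_id)])
  fragged <- stats::setNames(rownames(collapsed) %in%
                               c(mm$locus_a, mm$locus_b),
                             rownames(collapsed))
  fragged <- c(fragged, stats::setNames(
    rep(TRUE, length(setdiff(loci, names(fragged)))),
    setdiff(loci, names(fragged))))
  render_pictograms(loci, fc, cats, locz, fragged, p("pictograms"),
                    cap = config$cap, threshold = config$fc_threshold)
  log_line("heatmap", sprintf("%d pictogram rows rendered", length(loci)))

  ## truth-recovery report on synthetic runs
  recovery <- NULL
  if (!is.null(config$synth)) {
    ds_truth <- jsonlite::read_json(file.path(input_dir, "truth.json"),
                                    simplifyVector = TRUE)
    recovery <- truth_recovery(ds_truth, fc, resp, mm,
                               if (!is.null(fam)) fam$assignment,
                               if (!is.null(fam)) fam$chosen_k)
    jsonlite::write_json(recovery, p("truth_recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("recovery", sprintf(
      "timepoint acc %.3f, stage acc %.3f, pair P %.3f / R %.3f",
      recovery$timepoint_accuracy, recovery$stage_accuracy,
      recovery$pair_precision, recovery$pair_recall))
  }

  ## manifest: stable content hashes (log/timestamps excluded)
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  manifest <- list(
    seed = config$seed,
    thresholds = config[c("fc_threshold", "fpkm_floor", "pearson_threshold",
                          "margin_nt", "alpha", "cap")],
    k_range = config$k_range,
    files = hashes,
    recovery = recovery
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log_line("done", sprintf("completed in %.1f s",
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}

# compare pipeline results with planted truth (synthetic runs)
truth_recovery <- function(truth, fc, resp, mm, assignment = NULL,
                           chosen_k = NULL) {
  ## per-time-point classes on the truth loci
  tp <- truth$timepoint_direction
  tp_ids <- tp$locus_id
  tp_cols <- setdiff(names(tp), "locus_id")
  pred <- fc$class[tp_ids, tp_cols, drop = FALSE]
  planted <- as.matrix(tp[tp_cols])
  rownames(planted) <- tp_ids
  tp_acc <- mean(pred == planted, na.rm = FALSE)
  ## per-stage classes
  sd_truth <- truth$stage_direction
  stage_acc <- mean(vapply(names(stage_definition()), function(s) {
    got <- resp[sd_truth$locus_id, paste0("class_", stage_key(s))]
    mean(got == sd_truth[[s]])
  }, numeric(1)))
  ## fragment pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  true_pairs <- key(truth$pairs$locus_a, truth$pairs$locus_b)
  found <- if (nrow(mm)) key(mm$locus_a, mm$locus_b) else character(0)
  tp_n <- sum(found %in% true_pairs)
  precision <- if (length(found)) tp_n / length(found) else NA_real_
  recall <- if (length(true_pairs)) tp_n / length(true_pairs) else NA_real_
  retained_ok <- if (nrow(mm)) {
    m <- match(found, true_pairs)
    mean(mm$retained[!is.na(m)] == truth$pairs$retained[m[!is.na(m)]])
  } else NA_real_
  ## clusters
  ari <- NA_real_
  if (!is.null(assignment)) {
    truth_cl <- unlist(truth$cluster_id)
    common <- intersect(names(assignment), names(truth_cl))
    if (length(common) > 1)
      ari <- adjusted_rand_index(assignment[common], truth_cl[common])
  }
  list(timepoint_accuracy = tp_acc, stage_accuracy = stage_acc,
       pair_precision = precision, pair_recall = recall,
       retained_member_accuracy = retained_ok,
       cluster_ari = ari, chosen_k = chosen_k)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Cluster label vectors over the same items.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
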