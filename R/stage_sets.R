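#' Stage-mean responsiveness per locus
#'
#' For each stage, the mean transcript abundance `A_stage` is the arithmetic
#' mean of the FPKM values of that stage's time points; relative abundance
#' `R_stage = A_stage / FPKM(N_0)`; a gene is responsive in a stage when
#' `|log2 R_stage| > 1`, direction by sign. The FPKM reliability floor is
#' applied analogously to the single-time-point fold change: `log2 R_stage`
#' is `NA` when `FPKM(N_0)` or `A_stage` falls below the floor.
#'
#' @param mat FPKM time-course matrix.
#' @param floor FPKM reliability floor; set `apply_floor = FALSE` to disable.
#' @param threshold Responsiveness threshold in log2 units.
#' @param apply_floor Apply the floor to (`FPKM(N_0)`, `A_stage`)?
#' @return `data.frame` with per-stage columns `A_<stage>`, `log2R_<stage>`,
#'   `class_<stage>` and the locus ids.
#' @export
stage_response <- function(mat, floor = 1.0, threshold = 1.0,
                           apply_floor = TRUE) {
  mat <- validate_tc_matrix(mat)
  stages <- stage_definition()
  ref <- attr(stages, "reference")
  n0 <- mat[, ref]
  out <- data.frame(locus_id = rownames(mat), stringsAsFactors = FALSE)
  for (s in names(stages)) {
    a <- rowMeans(mat[, stages[[s]], drop = FALSE])
    log2r <- log2(a / n0)
    if (apply_floor) log2r[n0 < floor | a < floor] <- NA_real_
    key <- stage_key(s)
    out[[paste0("A_", key)]] <- a
    out[[paste0("log2R_", key)]] <- log2r
    out[[paste0("class_", key)]] <- classify_timepoint(log2r, threshold)
  }
  rownames(out) <- out$locus_id
  out
}

# column-name-safe stage keys: e-N -> eN, l-N -> lN, r+N -> rN
stage_key <- function(stage) c("e-N" = "eN", "l-N" = "lN", "r+N" = "rN")[[stage]]

#' The six stage gene sets (up/down per stage)
#'
#' @param response Output of [stage_response()].
#' @return Named list of six character vectors (`up_eN`, `down_eN`, `up_lN`,
#'   `down_lN`, `up_rN`, `down_rN`) plus attribute `na_loci`, the loci whose
#'   class is `NA` in at least one stage (excluded from all sets there).
#' @export
stage_gene_sets <- function(response) {
  sets <- list()
  na_loci <- character(0)
  for (s in names(stage_definition())) {
    cls <- response[[paste0("class_", stage_key(s))]]
    sets[[paste0("up_", stage_key(s))]] <- response$locus_id[!is.na(cls) & cls == "up"]
    sets[[paste0("down_", stage_key(s))]] <- response$locus_id[!is.na(cls) & cls == "down"]
    na_loci <- union(na_loci, response$locus_id[is.na(cls)])
  }
  attr(sets, "na_loci") <- na_loci
  sets
}

#' Three-set Venn partition
#'
#' Splits the union of three gene sets into the standard seven disjoint
#' regions.
#'
#' @param a,b,c Character vectors (gene ids).
#' @param names Region base names, defaults to the three stages.
#' @return Named list of seven character vectors: the three exclusive
#'   regions, three pairwise intersections, and the triple intersection.
#' @export
venn_partition <- function(a, b, c, names = c("e-N", "l-N", "r+N")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  out <- list(
    u[ina & !inb & !inc],
    u[!ina & inb & !inc],
    u[!ina & !inb & inc],
    u[ina & inb & !inc],
    u[ina & !inb & inc],
    u[!ina & inb & inc],
    u[ina & inb & inc]
  )
  names(out) <- c(names,
                  paste(names[1], names[2], sep = "&"),
                  paste(names[1], names[3], sep = "&"),
                  paste(names[2], names[3], sep = "&"),
                  paste(names, collapse = "&"))
  out
}

#' Jensen-Shannon divergence between two probability distributions
#'
#' Base-2 logarithms, so the divergence — and hence the distance, its square
#' root — lies in `[0, 1]`.
#'
#' @param p,q Non-negative numeric vectors summing to 1.
#' @return The Jensen-Shannon divergence.
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon distance matrix between samples
#'
#' Each sample (column) is normalized to a probability distribution over
#' loci; the pairwise distance is the square root of the Jensen-Shannon
#' divergence (base 2), a metric in `[0, 1]`.
#'
#' @param mat Loci x samples abundance matrix (need not be the canonical
#'   time-course layout).
#' @return Symmetric samples x samples distance matrix.
#' @export
js_sample_distance <- function(mat) {
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("all-zero sample column: cannot normalize")
  p <- sweep(mat, 2, cs, "/")
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- sqrt(js_divergence(p[, i], p[, j]))
  }
  d
}

#' Hierarchical clustering of samples from a distance matrix
#'
#' @param distances Symmetric distance matrix (e.g. [js_sample_distance()]).
#' @param method Linkage, default complete.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_samples <- function(distances, method = "complete") {
  stats::hclust(stats::as.dist(distances), method = method)
}

#' Cell weight from biomass and cell concentration
#'
#' @param biomass_g_per_l Biomass concentration in g L^-1.
#' @param cells_per_ml Cell concentration in cells mL^-1.
#' @return Cell weight in pg per cell.
#' @export
cell_weight <- function(biomass_g_per_l, cells_per_ml) {
  if (any(cells_per_ml <= 0)) stop("cell concentration must be positive")
  # g/L -> pg/mL: 1 g/L = 1e12 pg / 1e3 mL = 1e9 pg/mL
  biomass_g_per_l * 1e9 / cells_per_ml
}

#' Relative volumetric lipid productivity
#'
#' The net volumetric lipid production up to day X (content at day X minus
#' content at day 0) divided by the cultivation time gives the volumetric
#' lipid productivity `P(X)`; values are normalized to day 1.
#'
#' @param contents Numeric vector of volumetric lipid contents (e.g.
#'   mg L^-1), one per entry of `days`.
#' @param days Integer days, must include 0 and 1.
#' @return Named numeric vector of relative productivities `P(X)/P(1)` for
#'   all days X >= 1.
#' @export
relative_volumetric_productivity <- function(contents, days) {
  if (length(contents) != length(days)) stop("contents/days length mismatch")
  if (!all(c(0, 1) %in% days)) stop("days must include day 0 and day 1")
  c0 <- contents[days == 0][1L]
  keep <- days >= 1
  p <- (contents[keep] - c0) / days[keep]
  p1 <- p[days[keep] == 1][1L]
  if (p1 == 0) stop("productivity at day 1 is zero: normalization undefined")
  stats::setNames(p / p1, paste0("day", days[keep]))
}
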