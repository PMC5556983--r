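#' Log2 fold change with the FPKM reliability floor
#'
#' The fold change of a time point versus the reference is only considered
#' reliable when both FPKM values are at least `floor` (default 1.0, the
#' minimum abundance for reliable transcript quantification); below the
#' floor `NA` is returned.
#'
#' @param fpkm_ref Reference (N_0) abundance, FPKM; non-negative.
#' @param fpkm_t Abundance at the time point of interest, FPKM; non-negative.
#' @param floor Reliability floor on both values (FPKM).
#' @return `log2(fpkm_t / fpkm_ref)`, or `NA` where either value is below
#'   the floor. Vectorized.
#' @export
log2_fold_change <- function(fpkm_ref, fpkm_t, floor = 1.0) {
  if (any(fpkm_ref < 0, na.rm = TRUE) || any(fpkm_t < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative")
  out <- log2(fpkm_t / fpkm_ref)
  out[fpkm_ref < floor | fpkm_t < floor] <- NA_real_
  out
}

#' Classify per-time-point responsiveness from log2 fold change
#'
#' A gene is responsive at a time point when its absolute log2-FC exceeds 1
#' (strictly); direction follows the sign. `NA` (below-floor fold changes)
#' propagates.
#'
#' @param log2fc Numeric vector of log2 fold changes (may contain `NA`).
#' @param threshold Responsiveness threshold in log2 units.
#' @return Character vector in `up`/`down`/`none`, `NA` where input is `NA`.
#' @export
classify_timepoint <- function(log2fc, threshold = 1.0) {
  out <- rep(NA_character_, length(log2fc))
  ok <- !is.na(log2fc)
  out[ok & log2fc > threshold] <- "up"
  out[ok & log2fc < -threshold] <- "down"
  out[ok & abs(log2fc) <= threshold] <- "none"
  out
}

#' Cap log2 fold changes for display
#'
#' Fold changes beyond `cap` in magnitude are clamped and flagged as highly
#' regulated, matching the display convention in which |log2-FC| = 4 is the
#' colour-scale saturation point.
#'
#' @param log2fc Numeric vector (finite values; `NA` passes through).
#' @param cap Cap magnitude in log2 units.
#' @return List with `value` (clamped vector) and `highly_regulated`
#'   (logical flag per element; `NA` where input is `NA`).
#' @export
cap_for_display <- function(log2fc, cap = 4.0) {
  flag <- abs(log2fc) > cap
  list(value = pmin(pmax(log2fc, -cap), cap), highly_regulated = flag)
}

#' Full fold-change matrix versus the reference time point
#'
#' Computes log2 fold changes of the eleven non-reference time points versus
#' `N_0`, the below-floor NA mask, and per-cell responsiveness classes.
#'
#' @param mat Loci x 12 time-points FPKM matrix.
#' @param floor FPKM reliability floor.
#' @param threshold Responsiveness threshold (log2 units).
#' @return Object of class `fragtx_fc`: list with `log2fc` (loci x 11
#'   matrix), `na_mask` (logical matrix), `class` (character matrix),
#'   `reference`.
#' @export
fold_change <- function(mat, floor = 1.0, threshold = 1.0) {
  mat <- validate_tc_matrix(mat)
  ref <- attr(stage_definition(), "reference")
  tps <- setdiff(time_points(), ref)
  fc <- vapply(tps, function(tp)
    log2_fold_change(mat[, ref], mat[, tp], floor = floor),
    numeric(nrow(mat)))
  if (nrow(mat) == 1L) fc <- matrix(fc, nrow = 1L, dimnames = list(rownames(mat), tps))
  structure(list(
    log2fc = fc,
    na_mask = is.na(fc),
    class = matrix(classify_timepoint(fc, threshold), nrow = nrow(fc),
                   dimnames = dimnames(fc)),
    reference = ref
  ), class = "fragtx_fc")
}

#' @export
print.fragtx_fc <- function(x, ...) {
  cat(sprintf("Fold-change matrix: %d loci x %d time points vs %s (%d cells masked NA)\n",
              nrow(x$log2fc), ncol(x$log2fc), x$reference, sum(x$na_mask)))
  invisible(x)
}

#' Housekeeping stability criterion
#'
#' A gene counts as stably expressed (housekeeping-like) under starvation
#' when its absolute log2-FC exceeds 1 at no more than one of the -N time
#' points (`N_2` .. `N_96`). Below-floor (`NA`) fold changes do not count as
#' exceedances.
#'
#' @param fc A `fragtx_fc` object, or a named numeric log2-FC vector
#'   covering the -N time points.
#' @param threshold Responsiveness threshold (log2 units).
#' @return Logical; vector over loci when `fc` is a matrix object.
#' @export
is_housekeeping_stable <- function(fc, threshold = 1.0) {
  neg_n <- starvation_time_points()
  if (inherits(fc, "fragtx_fc")) {
    exceed <- abs(fc$log2fc[, neg_n, drop = FALSE]) > threshold
    return(rowSums(exceed, na.rm = TRUE) <= 1L)
  }
  sum(abs(fc[neg_n]) > threshold, na.rm = TRUE) <= 1L
}
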