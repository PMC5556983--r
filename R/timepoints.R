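#' Canonical time points of the nitrogen-availability time course
#'
#' The twelve sampling time points of the study design: the pre-starvation
#' reference `N_0`, seven nitrogen-starvation samples (`N_2` .. `N_96`, hours
#' of -N), and four nitrogen-resupply samples (`R_2` .. `R_14`, hours of +N).
#'
#' @return Character vector of the twelve time-point names in canonical order.
#' @export
time_points <- function() {
  c("N_0", "N_2", "N_4", "N_8", "N_24", "N_48", "N_56", "N_96",
    "R_2", "R_4", "R_8", "R_14")
}

#' Stage definition of the nitrogen time course
#'
#' The three stages of nitrogen availability: early starvation `e-N`
#' (starch accumulation), late starvation `l-N` (lipid hyperaccumulation)
#' and resupply `r+N` (storage degradation). The reference time point `N_0`
#' belongs to no stage.
#'
#' @return Named list with one character vector of time points per stage and
#'   an attribute `reference` naming the reference time point.
#' @export
stage_definition <- function() {
  stages <- list(
    "e-N" = c("N_2", "N_4", "N_8"),
    "l-N" = c("N_24", "N_48", "N_56", "N_96"),
    "r+N" = c("R_2", "R_4", "R_8", "R_14")
  )
  attr(stages, "reference") <- "N_0"
  stages
}

#' Starvation (-N) time points used for the housekeeping stability criterion
#' @return Character vector `N_2` .. `N_96`.
#' @export
starvation_time_points <- function() {
  c("N_2", "N_4", "N_8", "N_24", "N_48", "N_56", "N_96")
}

# Validate a time-course matrix: numeric, non-negative, unique locus ids,
# all canonical columns present; returns the matrix with columns in
# canonical order.
validate_tc_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("expression matrix must have unique locus ids as rownames",
         call. = FALSE)
  tp <- time_points()
  missing <- setdiff(tp, colnames(x))
  if (length(missing))
    stop("expression matrix lacks canonical time point(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(x))
    stop("expression matrix contains missing values; the input FPKM matrix ",
         "must be dense (reliability is expressed by the downstream NA mask)",
         call. = FALSE)
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative FPKM value at locus '%s', time point '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]), call. = FALSE)
  }
  x[, tp, drop = FALSE]
}

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
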